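test_that("generated cohorts are reproducible and respect record invariants", {
  a <- generate_cohort(cohort_config(n = 500, seed = 123))
  b <- generate_cohort(cohort_config(n = 500, seed = 123))
  expect_identical(a, b)
  expect_true(all(a$hcg0 > 0))
  expect_true(all(a$hcg48 > 0))
  expect_true(all(a$prog0 >= 0))
  expect_equal(a$hcg_ratio, a$hcg48 / a$hcg0)
  expect_true(all(a$interval_days == 2L))
  expect_true(all(a$outcome %in% c("FPUL", "IUP", "EP")))
  expect_equal(nrow(a), 500)
  expect_equal(length(unique(a$centre_id)), 8)
})

test_that("default config reproduces the intended outcome mix and medians", {
  d <- generate_cohort(cohort_config(n = 10000, seed = 2025))
  mix <- prop.table(table(d$outcome))[c("FPUL", "IUP", "EP")]
  target <- c(1338, 930, 334) / 2602
  expect_true(all(abs(mix - target) < 0.015))
  expect_gt(median(d$hcg0), 350)
  expect_lt(median(d$hcg0), 750)
  expect_gt(median(d$hcg_ratio), 0.6)
  expect_lt(median(d$hcg_ratio), 1.3)
  # class-conditional ratio structure: FPUL falls, IUP rises, EP plateaus
  med <- tapply(d$hcg_ratio, d$outcome, median)
  expect_lt(med["FPUL"], 0.87)
  expect_gt(med["IUP"], 1.66)
  expect_true(med["EP"] > 0.87 && med["EP"] < 1.66)
})

test_that("missingness injection hits the configured rates and nothing else", {
  cfg <- cohort_config(n = 10000, seed = 77)
  full <- generate_cohort(cfg)
  inj <- inject_missingness(full, cfg)
  rates <- attr(inj, "achieved_rates")

  miss_after_rule <- rates$rate[rates$quantity == "hcg48_missing_after_2day_rule"]
  expect_lt(abs(miss_after_rule - 0.29), 0.03)
  ltfu <- rates$rate[rates$quantity == "ltfu"]
  expect_lt(abs(ltfu - 0.10), 0.02)
  prog <- rates$rate[rates$quantity == "prog0_missing"]
  expect_lt(abs(prog - 0.08), 0.02)

  # the primary rule then yields the same overall hcg48 missingness
  ruled <- apply_missingness_rules(inj, "primary")
  expect_equal(mean(is.na(ruled$hcg48)), miss_after_rule, tolerance = 1e-9)

  # non-targeted fields untouched; true outcomes retained under LTFU
  expect_identical(inj$hcg0, full$hcg0)
  expect_identical(inj$age, full$age)
  expect_identical(inj$true_outcome, full$true_outcome)
  lost <- inj$outcome == "LTFU"
  expect_identical(inj$outcome[!lost], full$outcome[!lost])

  # no missingness when every mechanism is switched off
  cfg0 <- cfg
  cfg0$missingness$step1_compliance <- 1
  cfg0$missingness$prog0_rate <- 0
  cfg0$missingness$hcg48_mar_rate <- 1e-12
  cfg0$missingness$hcg48_mar_bleeding <- 0
  cfg0$missingness$ltfu_rate <- 1e-12
  cfg0$missingness$ltfu_beta_logratio <- 0
  cfg0$missingness$ltfu_beta_bleeding <- 0
  cfg0$missingness$interval_probs <- c(`2` = 1)
  inj0 <- inject_missingness(full, cfg0)
  expect_false(anyNA(inj0$hcg48))
  expect_false(anyNA(inj0$prog0))
  expect_true(all(inj0$outcome != "LTFU"))
})

test_that("infeasible configurations are rejected", {
  cfg <- cohort_config(n = 100)
  cfg$prevalences <- c(FPUL = 0.5, IUP = 0.5, EP = 0.5)
  expect_error(generate_cohort(cfg), class = "pultriage_config_error")
  cfg2 <- cohort_config(n = 100)
  cfg2$biomarkers$EP$ratio["sdlog"] <- -1
  expect_error(generate_cohort(cfg2), class = "pultriage_config_error")
  cfg3 <- cohort_config(n = 100)
  cfg3$missingness$ltfu_rate <- 1.2
  expect_error(inject_missingness(generate_cohort(cohort_config(n = 100)),
                                  cfg3),
               class = "pultriage_config_error")
})

test_that("model-generated cohorts are self-calibrated and self-optimal", {
  cfg <- cohort_config(n = 15000, seed = 31)
  pc <- pul_config()
  d <- generate_from_model("M6P", cfg, pul_cfg = pc)
  # perfect calibration by construction
  fit <- fit_calibration(d)
  expect_lt(abs(fit$slope - 1), 0.06)
  expect_lt(abs(fit$intercept), 0.1)
  # the generating model's discrimination beats a perturbed model's
  auc_true <- auc_binary(d$p_ep, d$outcome == "EP")
  pert <- pc$models$M6P
  set.seed(1)
  pert$beta_ep <- pert$beta_ep + rnorm(length(pert$beta_ep), sd = 0.5)
  scored <- predict_pul_risks(
    d[, c("hcg0", "hcg_ratio", "prog0")], pert, pc)
  auc_pert <- auc_binary(scored$p_ep, d$outcome == "EP")
  expect_gte(auc_true, auc_pert - 0.01)

  # constant-risk generator: no discrimination
  const <- intercept_model(beta_iup = 0.3, beta_ep = -0.4)
  dc <- generate_from_model(const, cohort_config(n = 8000, seed = 32),
                            pul_cfg = pc)
  expect_equal(auc_binary(dc$p_ep, dc$outcome == "EP"), 0.5)
})
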