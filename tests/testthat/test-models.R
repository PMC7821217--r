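test_that("hCG ratio is the plain quotient and rejects non-positive input", {
  expect_equal(compute_hcg_ratio(1000, 870), 0.87)
  expect_equal(compute_hcg_ratio(500, 500), 1)
  expect_equal(compute_hcg_ratio(174, 1534), 1534 / 174)
  expect_error(compute_hcg_ratio(0, 100), class = "pultriage_invalid_measurement")
  expect_error(compute_hcg_ratio(100, -1), class = "pultriage_invalid_measurement")
})

test_that("multinomial prediction softmax-normalises the linear predictors", {
  d <- toy_cohort()
  d$hcg_ratio <- compute_hcg_ratio(d$hcg0, d$hcg48)

  zero <- predict_pul_risks(d, intercept_model())
  expect_equal(unlist(zero[, c("p_fpul", "p_iup", "p_ep")]),
               c(p_fpul = 1 / 3, p_iup = 1 / 3, p_ep = 1 / 3))

  half <- predict_pul_risks(d, intercept_model(beta_iup = log(2)))
  expect_equal(unlist(half[, c("p_fpul", "p_iup", "p_ep")]),
               c(p_fpul = 0.25, p_iup = 0.5, p_ep = 0.25))

  extreme <- predict_pul_risks(d, intercept_model(beta_ep = 100))
  expect_gt(extreme$p_ep, 0.999)
})

test_that("risk triples always sum to one for random coefficients and records", {
  set.seed(41)
  cfg <- pul_config()
  for (rep in 1:25) {
    mod <- pultriage:::new_pul_model(
      "M6P", c("intercept", "log_hcg0", "log_ratio", "sq_log_ratio",
               "log_prog0"),
      rnorm(5, sd = 2), rnorm(5, sd = 2))
    d <- tibble::tibble(hcg0 = exp(runif(20, 3, 10)),
                        hcg_ratio = exp(runif(20, -2, 2)),
                        prog0 = exp(runif(20, -1, 5)))
    p <- predict_pul_risks(d, mod, cfg)
    expect_true(all(abs(p$p_fpul + p$p_iup + p$p_ep - 1) < 1e-9))
    expect_true(all(p$p_fpul >= 0 & p$p_iup >= 0 & p$p_ep >= 0))
  }
})

test_that("missing required predictors are reported by name", {
  d <- tibble::tibble(hcg0 = 500, hcg_ratio = 1.1, prog0 = NA_real_)
  expect_error(predict_pul_risks(d, "M6P"),
               regexp = "prog0", class = "pultriage_missing_predictor")
  expect_error(predict_pul_risks(tibble::tibble(hcg0 = 500), "M6NP"),
               class = "pultriage_missing_predictor")
})

test_that("Step 1 discharges at progesterone <= 2 with the fixed risk triple", {
  cfg <- pul_config()
  step1 <- triage_pul(toy_cohort(prog0 = 1.5), "2ST", cfg)
  expect_equal(step1$label, "low_risk")
  expect_equal(step1$decided_by, "step1_progesterone")
  expect_equal(c(step1$p_fpul, step1$p_iup, step1$p_ep),
               c(0.961, 0.022, 0.017))

  boundary <- triage_pul(toy_cohort(prog0 = 2), "2ST", cfg)
  expect_equal(boundary$decided_by, "step1_progesterone")
  expect_equal(boundary$label, "low_risk")

  # Step-1 rows keep the fixed triple even when the model would be extreme
  no_hcg48 <- tibble::tibble(hcg0 = 500, prog0 = 1, prog_supplement = FALSE)
  s <- triage_pul(no_hcg48, "2ST", cfg)
  expect_equal(s$p_fpul, 0.961)
})

test_that("the EP-risk threshold is inclusive and monotone", {
  expect_equal(classify_high_risk(0.05), "high_risk")
  expect_equal(classify_high_risk(0.049), "low_risk")
  expect_equal(classify_high_risk(0.017), "low_risk")
  expect_error(classify_high_risk(0.2, threshold = 1),
               class = "pultriage_invalid_threshold")
  p <- sort(runif(50))
  labs <- classify_high_risk(p)
  expect_true(all(diff(labs == "high_risk") >= 0))
})

test_that("2ST falls back to M6NP when progesterone is unusable", {
  cfg <- pul_config()
  d <- tibble::tibble(hcg0 = c(500, 500, 500),
                      hcg48 = c(520, 520, 520),
                      prog0 = c(20, NA, 20),
                      prog_supplement = c(FALSE, FALSE, TRUE))
  out <- triage_pul(d, "2ST", cfg)
  expect_equal(out$model_used, c("M6P", "M6NP", "M6NP"))
  expect_true(all(out$decided_by == "model_threshold"))
})

test_that("ratio cut-offs partition (0, Inf) with an inclusive high-risk band", {
  out <- classify_hcg_ratio(c(0.5, 0.87, 1.0, 1.66, 2.0))
  expect_equal(out$predicted_class,
               c("FPUL", "EP_high_risk", "EP_high_risk", "EP_high_risk", "IUP"))
  expect_equal(out$label,
               c("low_risk", "high_risk", "high_risk", "high_risk", "low_risk"))
  expect_error(classify_hcg_ratio(0), class = "pultriage_invalid_measurement")
  # exhaustive and non-overlapping over a dense grid
  grid <- exp(seq(log(0.01), log(50), length.out = 500))
  cls <- classify_hcg_ratio(grid)$predicted_class
  expect_false(anyNA(cls))
  expect_setequal(unique(cls), c("FPUL", "EP_high_risk", "IUP"))
})

test_that("configuration files declaring other units are rejected", {
  path <- system.file("extdata", "pul_models_synthetic.yaml",
                      package = "pultriage")
  raw <- yaml::read_yaml(path)
  raw$units$progesterone <- "ng/ml"
  expect_error(pultriage:::validate_pul_config(raw),
               class = "pultriage_config_error")
})
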