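test_that("protocol rules blank off-schedule hCG and supplemented progesterone", {
  d <- tibble::tibble(
    hcg0 = rep(500, 4),
    hcg48 = c(520, 520, 520, 520),
    interval_days = c(2L, 3L, 1L, NA),
    prog0 = c(10, 10, 10, 10),
    prog_supplement = c(FALSE, FALSE, TRUE, FALSE),
    outcome = "FPUL"
  )
  primary <- apply_missingness_rules(d, "primary")
  expect_equal(is.na(primary$hcg48), c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(is.na(primary$prog0), c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(primary$hcg48_recorded, d$hcg48)  # audit keeps originals
  expect_equal(primary$prog0_recorded, d$prog0)

  window <- apply_missingness_rules(d, "window_1_3")
  expect_equal(is.na(window$hcg48), c(FALSE, FALSE, FALSE, TRUE))
})

make_mar_cohort <- function(n = 600, seed = 100, miss_frac = 0.3) {
  set.seed(seed)
  d <- generate_cohort(cohort_config(n = n, seed = seed))
  # MAR: drop hcg48 with probability rising in hcg0; some LTFU; some prog0
  p_miss <- plogis(qlogis(miss_frac) + 0.5 * scale(log(d$hcg0))[, 1])
  d$hcg48[runif(n) < p_miss] <- NA
  d$prog0[runif(n) < 0.1] <- NA
  d$outcome[runif(n) < 0.08] <- "LTFU"
  d$hcg_ratio <- compute_hcg_ratio(d$hcg0, d$hcg48)
  d
}

test_that("imputation is deterministic and never alters observed cells", {
  d <- make_mar_cohort(400)
  imp1 <- impute_chained(d, m = 3, seed = 42, maxit = 5)
  imp2 <- impute_chained(d, m = 3, seed = 42, maxit = 5)
  expect_identical(imp1$completed, imp2$completed)

  obs_h <- !is.na(d$hcg48)
  obs_p <- !is.na(d$prog0)
  obs_o <- d$outcome != "LTFU"
  for (j in 1:3) {
    cj <- imp1$completed[[j]]
    expect_identical(cj$hcg48[obs_h], d$hcg48[obs_h])
    expect_identical(cj$prog0[obs_p], d$prog0[obs_p])
    expect_identical(cj$outcome[obs_o], d$outcome[obs_o])
    expect_identical(cj$record_id, d$record_id)
    expect_false(anyNA(cj$hcg48))
    expect_false(anyNA(cj$prog0))
    expect_true(all(cj$outcome %in% c("FPUL", "IUP", "EP")))
  }
  # different seeds give different imputations
  imp3 <- impute_chained(d, m = 1, seed = 43, maxit = 5)
  expect_false(identical(imp3$completed[[1]]$hcg48, imp1$completed[[1]]$hcg48))
})

test_that("a cohort with no missing cells passes through unchanged", {
  d <- generate_cohort(cohort_config(n = 150, seed = 9))
  imp <- impute_chained(d, m = 4, seed = 1)
  for (j in 1:4) expect_identical(imp$completed[[j]], d)
})

test_that("MAR imputation recovers the complete-data mean of log hcg48", {
  d <- make_mar_cohort(2500, seed = 321)
  complete <- generate_cohort(cohort_config(n = 2500, seed = 321))
  truth <- mean(log(complete$hcg48))
  imp <- impute_chained(d, m = 5, seed = 7, maxit = 10)
  means <- vapply(imp$completed, function(cj) mean(log(cj$hcg48)), numeric(1))
  vars <- vapply(imp$completed,
                 function(cj) var(log(cj$hcg48)) / nrow(cj), numeric(1))
  pooled <- rubin_pool(means, vars)
  expect_lt(abs(pooled$estimate - truth) / pooled$se, 2)
})

test_that("overwhelming missingness aborts with a diagnostic", {
  d <- make_mar_cohort(200)
  d$prog0 <- NA_real_
  expect_error(impute_chained(d, m = 2), class = "pultriage_imputation_error")
})

test_that("Rubin's rules match hand-computed pooling", {
  rp <- rubin_pool(c(1, 3), c(1, 1))
  expect_equal(rp$estimate, 2)
  expect_equal(rp$between, 2)
  expect_equal(rp$total_var, 1 + 1.5 * 2)

  same <- rubin_pool(rep(1.7, 5), rep(0.04, 5))
  expect_equal(same$between, 0)
  expect_equal(same$total_var, 0.04)

  set.seed(8)
  for (rep in 1:20) {
    m <- sample(2:10, 1)
    est <- rnorm(m); v <- runif(m, 0.1, 1)
    rp <- rubin_pool(est, v)
    expect_gte(rp$total_var, mean(v))   # between term never negative
  }
  expect_warning(rubin_pool(1, 0.5), "Single imputation")
})
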