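# Simulated cohorts with known calibration: outcomes drawn from true risks,
# supplied risks distorted on the logit scale by (shift, scale).
sim_calibration_cohort <- function(n, shift = 0, scale = 1, k_centres = 4,
                                   seed = 1) {
  set.seed(seed)
  true_lp <- rnorm(n, qlogis(0.12), 1.2)
  tibble::tibble(
    p_ep = plogis(shift + scale * true_lp),
    outcome = ifelse(rbinom(n, 1, plogis(true_lp)) == 1, "EP", "FPUL"),
    centre_id = sample(paste0("c", seq_len(k_centres)), n, replace = TRUE)
  )
}

test_that("well-calibrated risks recover intercept 0 and slope 1", {
  d <- sim_calibration_cohort(8000, seed = 11)
  fit <- fit_calibration(d)
  expect_lt(abs(fit$intercept), 0.1)
  expect_lt(abs(fit$slope - 1), 0.08)
  expect_equal(fit$k_centres, 4)
})

test_that("distorted risks are diagnosed in the documented direction", {
  # supplied logits = true logits / 2 -> risks too moderate -> slope ~ 2
  mod <- sim_calibration_cohort(8000, scale = 0.5, seed = 12)
  mod$p_ep <- plogis(qlogis(mod$p_ep))  # no-op, clarity
  fit <- fit_calibration(mod)
  expect_gt(fit$slope, 1.5)
  # risks shifted +1 on the logit scale -> too high -> intercept ~ -1
  hi <- sim_calibration_cohort(8000, shift = 1, seed = 13)
  fit2 <- fit_calibration(hi)
  expect_lt(fit2$intercept, -0.6)
  expect_gt(fit2$intercept, -1.4)
})

test_that("single-centre data fall back to ordinary logistic regression", {
  d <- sim_calibration_cohort(2000, k_centres = 1, seed = 14)
  fit <- fit_calibration(d)
  expect_true("single_centre_fixed_effects" %in% fit$flags)
  expect_lt(abs(fit$slope - 1), 0.25)
})

test_that("recalibrated risks recalibrate to identity", {
  d <- sim_calibration_cohort(6000, shift = 0.8, scale = 0.6, seed = 15)
  fit <- fit_calibration(d)
  fe <- if (inherits(fit$slope_fit, "merMod")) lme4::fixef(fit$slope_fit)
        else coef(fit$slope_fit)
  d2 <- d
  d2$p_ep <- plogis(unname(fe["(Intercept)"]) + fit$slope * qlogis(d$p_ep))
  refit <- fit_calibration(d2)
  expect_lt(abs(refit$slope - 1), 0.1)
  expect_lt(abs(refit$intercept), 0.12)
})

test_that("parameter recovery holds across a grid of true (shift, scale)", {
  set.seed(16)
  errs <- replicate(12, {
    shift <- runif(1, -1, 1)
    scale <- runif(1, 0.6, 1.8)
    d <- sim_calibration_cohort(4000, shift = 0, scale = 1,
                                seed = sample.int(1e6, 1))
    # distort supplied risks: logit' = shift + scale * logit(true p)
    d$p_ep <- plogis(shift + scale * qlogis(d$p_ep))
    fit <- fit_calibration(d)
    # recovered slope should invert the distortion scale
    abs(fit$slope - 1 / scale)
  })
  expect_lt(mean(errs), 0.12)
})

test_that("smooth calibration curve sits on the diagonal when calibrated", {
  d <- sim_calibration_cohort(20000, seed = 17)
  grid <- seq(0.03, 0.5, by = 0.01)
  curve <- smooth_calibration_curve(d, grid = grid)
  inside <- !curve$extrapolated
  expect_lt(max(abs(curve$observed[inside] - curve$risk[inside])), 0.06)
  expect_true(all(curve$observed >= 0 & curve$observed <= 1))
  expect_true(all(diff(curve$risk) > 0))
})

test_that("over-extreme risks put the curve below the diagonal above prevalence", {
  d <- sim_calibration_cohort(20000, seed = 18)
  # double the logit distance from the prevalence: risks above prevalence
  # become too high, risks below it too low
  pivot <- qlogis(mean(d$outcome == "EP"))
  d$p_ep <- plogis(pivot + 2 * (qlogis(d$p_ep) - pivot))
  curve <- smooth_calibration_curve(d, grid = seq(0.3, 0.8, 0.05))
  inside <- !curve$extrapolated
  expect_true(all(curve$observed[inside] < curve$risk[inside]))
})

test_that("constant risks give a flagged single-point curve", {
  d <- tibble::tibble(p_ep = rep(0.1, 200),
                      outcome = rep(c("EP", "FPUL"), c(20, 180)))
  expect_warning(curve <- smooth_calibration_curve(d), "constant")
  expect_equal(nrow(curve), 1)
  expect_true(attr(curve, "degenerate"))
  expect_equal(curve$observed, 0.1, tolerance = 1e-9)
})
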