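#' Calibration intercept and slope for estimated EP risks
#'
#' Assesses the reliability of the estimated risk of ectopic pregnancy by
#' logistic recalibration on the logit of the estimated risk. Two fits are
#' reported, the standard pair of summaries:
#'
#' * the **calibration slope**, the coefficient of `logit(risk)` in
#'   `event ~ logit(risk)`. Slope < 1 means the risks are too extreme
#'   (low risks too low, high risks too high), slope > 1 too moderate.
#' * the **calibration intercept** (calibration-in-the-large), the
#'   intercept of a model with `logit(risk)` as an offset, i.e. with the
#'   slope fixed at 1. Intercept < 0 means risks are on average too high,
#'   intercept > 0 too low.
#'
#' With two or more centres, both models carry independent random
#' intercept (and, for the slope model, random slope) terms by centre,
#' fitted by maximum likelihood with `lme4::glmer`; the fixed effects are
#' reported and the centre-level deviations returned. With a single centre
#' — or if the mixed fit fails to converge even after dropping the random
#' slope — the function falls back to ordinary logistic regression and
#' flags the fallback.
#'
#' @param data Data frame with columns `p_ep` (estimated risk), `outcome`
#'   (final outcome; EP is the event) and optionally `centre_id`.
#' @param risk_col,outcome_col,centre_col Column names, overridable.
#' @param clip Risks are clipped to `[clip, 1 - clip]` before the logit to
#'   guard degenerate configurations.
#' @return A `pul_calibration` object: a list with `intercept`, `slope`,
#'   their standard errors and 95% confidence intervals, `centre_effects`
#'   (tibble of per-centre deviations), `method` flags and the fitted
#'   model objects. Has [tidy()] and [glance()] methods.
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(p_ep = runif(500, 0.01, 0.4),
#'                     centre_id = sample(c("A", "B"), 500, TRUE))
#' d$outcome <- ifelse(rbinom(500, 1, d$p_ep) == 1, "EP", "FPUL")
#' fit <- fit_calibration(d)
#' glance(fit)
#' @export
fit_calibration <- function(data, risk_col = "p_ep", outcome_col = "outcome",
                            centre_col = "centre_id", clip = 1e-6) {
  risks <- data[[risk_col]]
  event <- data[[outcome_col]] == "EP"
  centres <- if (centre_col %in% names(data)) as.character(data[[centre_col]])
             else rep("all", nrow(data))
  keep <- !is.na(risks) & !is.na(event)
  d <- data.frame(y = as.integer(event[keep]),
                  lp = qlogis(pmin(pmax(risks[keep], clip), 1 - clip)),
                  centre = factor(centres[keep]))
  k <- nlevels(droplevels(d$centre))
  d$centre <- droplevels(d$centre)

  flags <- character(0)
  slope_fit <- int_fit <- NULL
  centre_effects <- NULL
  if (k >= 2L) {
    slope_fit <- tryCatch(
      lme4::glmer(y ~ lp + (1 | centre) + (0 + lp | centre), data = d,
                  family = binomial(),
                  control = lme4::glmerControl(calc.derivs = FALSE)),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(slope_fit)) {
      flags <- c(flags, "random_slope_dropped")
      slope_fit <- tryCatch(
        lme4::glmer(y ~ lp + (1 | centre), data = d, family = binomial(),
                    control = lme4::glmerControl(calc.derivs = FALSE)),
        warning = function(w) NULL, error = function(e) NULL)
    }
    int_fit <- tryCatch(
      lme4::glmer(y ~ 1 + (1 | centre) + offset(lp), data = d,
                  family = binomial(),
                  control = lme4::glmerControl(calc.derivs = FALSE)),
      warning = function(w) NULL, error = function(e) NULL)
  } else {
    flags <- c(flags, "single_centre_fixed_effects")
  }
  if (is.null(slope_fit)) {
    if (k >= 2L) flags <- c(flags, "mixed_fit_failed_fixed_effects_used")
    slope_fit <- glm(y ~ lp, data = d, family = binomial())
  }
  if (is.null(int_fit)) {
    int_fit <- glm(y ~ 1 + offset(lp), data = d, family = binomial())
  }

  fixef_of <- function(fit) {
    if (inherits(fit, "merMod")) lme4::fixef(fit) else coef(fit)
  }
  se_of <- function(fit) {
    sqrt(diag(as.matrix(stats::vcov(fit))))
  }
  sl <- unname(fixef_of(slope_fit)["lp"])
  sl_se <- se_of(slope_fit)[["lp"]]
  ic <- unname(fixef_of(int_fit)[["(Intercept)"]])
  ic_se <- se_of(int_fit)[[1]]

  if (inherits(slope_fit, "merMod")) {
    re <- lme4::ranef(slope_fit)$centre
    centre_effects <- tibble::tibble(
      centre = rownames(re),
      intercept_dev = if ("(Intercept)" %in% colnames(re))
        re[["(Intercept)"]] else 0,
      slope_dev = if ("lp" %in% colnames(re)) re[["lp"]] else 0
    )
  }

  structure(list(
    intercept = ic, intercept_se = ic_se,
    intercept_ci = ic + c(-1, 1) * qnorm(0.975) * ic_se,
    slope = sl, slope_se = sl_se,
    slope_ci = sl + c(-1, 1) * qnorm(0.975) * sl_se,
    centre_effects = centre_effects,
    n = nrow(d), k_centres = k, flags = flags,
    slope_fit = slope_fit, intercept_fit = int_fit
  ), class = "pul_calibration")
}

#' @export
print.pul_calibration <- function(x, ...) {
  cat("<pul_calibration> n =", x$n, "records,", x$k_centres, "centre(s)\n")
  cat(sprintf("  intercept %6.3f (95%% CI %.3f to %.3f)  [<0: risks too high]\n",
              x$intercept, x$intercept_ci[1], x$intercept_ci[2]))
  cat(sprintf("  slope     %6.3f (95%% CI %.3f to %.3f)  [<1: risks too extreme]\n",
              x$slope, x$slope_ci[1], x$slope_ci[2]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Smooth calibration curve for estimated EP risks
#'
#' A flexible estimate of the observed event proportion as a function of
#' the estimated risk: logistic regression of the event on a natural cubic
#' spline basis of logit(risk), evaluated on a grid. On a perfectly
#' calibrated cohort the curve lies on the diagonal up to sampling error.
#' Grid points outside the observed risk range are flagged as
#' extrapolation. If the risks are (near-)constant the spline is
#' degenerate; a single-point curve at the overall event rate is returned
#' and flagged.
#'
#' @param data Data frame with `p_ep` and `outcome` columns (EP = event).
#' @param grid Estimated-risk grid; defaults to 50 points spanning the
#'   observed risks.
#' @param df Spline degrees of freedom.
#' @param clip Clipping bound applied before the logit.
#' @return A `pul_calibration_curve` tibble: `risk`, `observed`, `lower`,
#'   `upper`, `extrapolated`, with attribute `degenerate`.
#' @export
smooth_calibration_curve <- function(data, grid = NULL, df = 4, clip = 1e-6) {
  risks <- pmin(pmax(data$p_ep, clip), 1 - clip)
  y <- as.integer(data$outcome == "EP")
  keep <- !is.na(risks) & !is.na(y)
  risks <- risks[keep]; y <- y[keep]
  lp <- qlogis(risks)
  rng <- range(risks)
  degenerate <- diff(range(lp)) < 1e-8
  if (is.null(grid)) {
    grid <- if (degenerate) rng[1] else
      plogis(seq(qlogis(rng[1]), qlogis(rng[2]), length.out = 50))
  }
  grid <- sort(unique(grid))
  if (degenerate) {
    warn("Estimated risks are constant; returning a single-point curve.")
    p <- mean(y)
    se <- sqrt(p * (1 - p) / length(y))
    out <- tibble::tibble(risk = rng[1], observed = p,
                          lower = max(0, p - qnorm(0.975) * se),
                          upper = min(1, p + qnorm(0.975) * se),
                          extrapolated = FALSE)
  } else {
    B <- splines::ns(lp, df = df)
    fit <- glm(y ~ B, family = binomial())
    Bg <- predict(B, qlogis(pmin(pmax(grid, clip), 1 - clip)))
    eta <- cbind(1, Bg) %*% coef(fit)
    V <- stats::vcov(fit)
    se_eta <- sqrt(rowSums((cbind(1, Bg) %*% V) * cbind(1, Bg)))
    out <- tibble::tibble(
      risk = grid,
      observed = plogis(drop(eta)),
      lower = plogis(drop(eta) - qnorm(0.975) * se_eta),
      upper = plogis(drop(eta) + qnorm(0.975) * se_eta),
      extrapolated = grid < rng[1] | grid > rng[2]
    )
  }
  structure(out, degenerate = degenerate,
            class = c("pul_calibration_curve", class(out)))
}
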