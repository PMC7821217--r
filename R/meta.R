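#' Random-effects pooling of centre-specific metrics
#'
#' Combines centre-specific estimates of a validation metric into an
#' overall estimate with a 95% confidence interval and — for three or more
#' centres — a 95% prediction interval that quantifies between-centre
#' heterogeneity (the interval expected to contain a new centre's true
#' metric). The between-centre variance is estimated by REML
#' (via [metafor::rma()]), with DerSimonian-Laird as fallback if REML does
#' not converge. The prediction interval uses the t-based formula with
#' `k - 2` degrees of freedom on the pooled standard error inflated by the
#' between-centre variance; it is undefined (NA, flagged) for fewer than
#' three centres.
#'
#' Probability-scale metrics (AUC, sensitivity, proportions) should be
#' pooled on the logit scale so the back-transformed intervals stay inside
#' (0, 1); calibration intercepts/slopes and Net Benefit on the identity
#' scale.
#'
#' @param estimates Centre estimates, on the metric's natural scale.
#' @param ses Standard errors on that same scale (delta-method transformed
#'   internally when `transform` is not identity).
#' @param transform `"identity"`, `"logit"` or `"log"`.
#' @param labels Optional centre labels.
#' @return A `pul_pooled` object: `estimate`, `ci95`, `pi95`, `tau2`
#'   (transformed scale), `k`, `method`, and `centre_estimates` (tibble).
#'   Has [tidy()] and [glance()] methods.
#' @examples
#' pool_random_effects(c(0.85, 0.90, 0.88), c(0.02, 0.03, 0.025),
#'                     transform = "logit")
#' @export
pool_random_effects <- function(estimates, ses,
                                transform = c("identity", "logit", "log"),
                                labels = NULL) {
  transform <- match.arg(transform)
  stopifnot(length(estimates) == length(ses))
  if (any(ses <= 0, na.rm = TRUE)) {
    abort("Standard errors must be strictly positive.",
          class = "pultriage_invalid_input")
  }
  ok <- is.finite(estimates) & is.finite(ses)
  estimates <- estimates[ok]; ses <- ses[ok]
  labels <- if (is.null(labels)) paste0("centre_", seq_along(estimates))
            else labels[ok]
  k <- length(estimates)
  if (k == 0L) {
    abort("No centres with a defined estimate.",
          class = "pultriage_undefined_metric")
  }
  fwd <- switch(transform, identity = identity, logit = qlogis, log = log)
  bck <- switch(transform, identity = identity, logit = plogis, log = exp)
  deriv <- switch(transform,
                  identity = function(x) rep(1, length(x)),
                  logit = function(x) 1 / (x * (1 - x)),
                  log = function(x) 1 / x)
  yi <- fwd(estimates)
  vi <- (ses * deriv(estimates))^2

  if (k == 1L) {
    ci <- yi + c(-1, 1) * qnorm(0.975) * sqrt(vi)
    return(new_pul_pooled(bck(yi), bck(ci), c(NA, NA), tau2 = NA_real_,
                          k = 1L, method = "single_centre_passthrough",
                          labels, estimates, ses))
  }
  fit <- tryCatch(metafor::rma(yi = yi, vi = vi, method = "REML"),
                  error = function(e) NULL, warning = function(w) NULL)
  method <- "REML"
  if (is.null(fit)) {
    fit <- metafor::rma(yi = yi, vi = vi, method = "DL")
    method <- "DL"
  }
  mu <- as.numeric(fit$beta)
  se_mu <- fit$se
  tau2 <- fit$tau2
  ci <- mu + c(-1, 1) * qnorm(0.975) * se_mu
  if (k >= 3L) {
    pi <- mu + c(-1, 1) * qt(0.975, df = k - 2) * sqrt(tau2 + se_mu^2)
  } else {
    pi <- c(NA_real_, NA_real_)
  }
  new_pul_pooled(bck(mu), bck(ci), bck(pi), tau2, k, method,
                 labels, estimates, ses)
}

new_pul_pooled <- function(estimate, ci95, pi95, tau2, k, method,
                           labels, estimates, ses) {
  structure(list(
    estimate = unname(estimate),
    ci95 = unname(ci95), pi95 = unname(pi95),
    tau2 = tau2, k = k, method = method,
    centre_estimates = tibble::tibble(centre = labels,
                                      estimate = unname(estimates),
                                      se = unname(ses))
  ), class = "pul_pooled")
}

#' @export
print.pul_pooled <- function(x, ...) {
  cat(sprintf("<pul_pooled> %.4f (95%% CI %.4f to %.4f), k = %d, tau2 = %s\n",
              x$estimate, x$ci95[1], x$ci95[2], x$k,
              format(x$tau2, digits = 3)))
  if (all(is.finite(x$pi95))) {
    cat(sprintf("  95%% PI %.4f to %.4f\n", x$pi95[1], x$pi95[2]))
  } else {
    cat("  95% PI undefined (k < 3)\n")
  }
  invisible(x)
}

#' Standard error of a centre-specific AUC
#'
#' Nonparametric (DeLong-type) standard error of the Mann-Whitney AUC,
#' from the empirical variances of the event and non-event placement
#' values. Centres where either class is absent have no defined AUC and
#' should be excluded from pooling.
#'
#' @param risks Estimated risks.
#' @param is_event Logical event indicator.
#' @return Standard error of [auc_binary()] on the same data.
#' @export
centre_auc_se <- function(risks, is_event) {
  keep <- !is.na(risks) & !is.na(is_event)
  risks <- risks[keep]; is_event <- as.logical(is_event[keep])
  x <- risks[is_event]   # events
  y <- risks[!is_event]  # non-events
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L) {
    abort("AUC standard error undefined: single-class centre.",
          class = "pultriage_undefined_metric")
  }
  # placement values: for each event, fraction of non-events it beats
  plc <- function(a, b) {
    sb <- sort(b)
    (findInterval(a, sb, left.open = TRUE) +
       0.5 * (findInterval(a, sb) - findInterval(a, sb, left.open = TRUE))) /
      length(b)
  }
  v10 <- plc(x, y)        # event placements
  v01 <- 1 - plc(y, x)    # non-event placements
  s10 <- if (m > 1) var(v10) else 0
  s01 <- if (n > 1) var(v01) else 0
  sqrt(s10 / m + s01 / n)
}
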