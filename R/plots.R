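#' Plot a decision curve
#'
#' Net Benefit against risk threshold for the model-based strategy and the
#' treat-all / treat-none defaults. A curve dipping below both defaults at
#' a threshold marks the model as harmful there.
#'
#' @param object A `pul_decision_curve` tibble ([decision_curve()],
#'   [pooled_decision_curve()], or the `decision_curves` element of a
#'   validation bundle).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pul_decision_curve <- function(object, ...) {
  d <- object
  if ("centre" %in% names(d)) {
    d <- d[d$centre %in% c("(overall)", "(pooled)"), , drop = FALSE]
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold,
                                       y = .data$net_benefit,
                                       colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Risk threshold for high risk of EP",
                  y = "Net Benefit", colour = NULL) +
    ggplot2::theme_minimal()
  if (all(c("lower", "upper") %in% names(d))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper,
                   fill = .data$strategy),
      alpha = 0.15, colour = NA, show.legend = FALSE)
  }
  p
}

#' Plot a smooth calibration curve
#'
#' Observed event proportion against estimated EP risk with a pointwise
#' 95% band; the dashed diagonal is perfect calibration (points above it
#' mean the estimated risks are too low, below it too high).
#'
#' @param object A `pul_calibration_curve` from
#'   [smooth_calibration_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pul_calibration_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$risk, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Estimated risk of EP", y = "Observed proportion") +
    ggplot2::theme_minimal()
}

#' Forest plot of centre-specific estimates with the pooled summary
#'
#' Mirrors the standard meta-analysis display: one row per centre with a
#' 95% confidence interval, the pooled estimate underneath, and — when
#' defined — the 95% prediction interval as a wider bar capturing
#' between-centre heterogeneity.
#'
#' @param object A `pul_pooled` object from [pool_random_effects()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pul_pooled <- function(object, ...) {
  ce <- object$centre_estimates
  rows <- tibble::tibble(
    label = c(ce$centre, "Pooled"),
    estimate = c(ce$estimate, object$estimate),
    lower = c(ce$estimate - qnorm(0.975) * ce$se, object$ci95[1]),
    upper = c(ce$estimate + qnorm(0.975) * ce$se, object$ci95[2]),
    pooled = c(rep(FALSE, nrow(ce)), TRUE)
  )
  rows$label <- factor(rows$label, levels = rev(rows$label))
  p <- ggplot2::ggplot(rows, ggplot2::aes(x = .data$estimate,
                                          y = .data$label)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper,
                                          shape = .data$pooled),
                             show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = object$estimate,
                        linetype = "dotted", colour = "grey50") +
    ggplot2::labs(x = "Estimate", y = NULL) +
    ggplot2::theme_minimal()
  if (all(is.finite(object$pi95))) {
    p <- p + ggplot2::annotate("errorbarh",
                               xmin = object$pi95[1], xmax = object$pi95[2],
                               y = 1, height = 0.3, colour = "grey30")
  }
  p
}

#' Export forest-plot data for a pooled metric
#'
#' @param object A `pul_pooled` object.
#' @return Tibble with one row per centre plus a pooled row carrying the
#'   confidence and prediction interval.
#' @export
forest_data <- function(object) {
  stopifnot(inherits(object, "pul_pooled"))
  ce <- object$centre_estimates
  dplyr::bind_rows(
    tibble::tibble(centre = ce$centre, estimate = ce$estimate,
                   lower = ce$estimate - qnorm(0.975) * ce$se,
                   upper = ce$estimate + qnorm(0.975) * ce$se,
                   pi_lower = NA_real_, pi_upper = NA_real_,
                   pooled = FALSE),
    tibble::tibble(centre = "(pooled)", estimate = object$estimate,
                   lower = object$ci95[1], upper = object$ci95[2],
                   pi_lower = object$pi95[1], pi_upper = object$pi95[2],
                   pooled = TRUE)
  )
}
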