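#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a calibration fit
#'
#' @param x A `pul_calibration` object.
#' @param ... Unused.
#' @return One row per recalibration parameter with estimate, standard
#'   error and 95% confidence limits.
#' @export
tidy.pul_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se),
    conf.low = c(x$intercept_ci[1], x$slope_ci[1]),
    conf.high = c(x$intercept_ci[2], x$slope_ci[2])
  )
}

#' @rdname tidy.pul_calibration
#' @export
glance.pul_calibration <- function(x, ...) {
  tibble::tibble(
    intercept = x$intercept, slope = x$slope,
    n = x$n, k_centres = x$k_centres,
    flags = paste(x$flags, collapse = ";")
  )
}

#' Tidy a pooled metric
#'
#' @param x A `pul_pooled` object.
#' @param ... Unused.
#' @return One row per centre (`term = centre id`) plus the pooled row.
#' @export
tidy.pul_pooled <- function(x, ...) {
  forest_data(x)
}

#' @rdname tidy.pul_pooled
#' @export
glance.pul_pooled <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate,
    conf.low = x$ci95[1], conf.high = x$ci95[2],
    pi.low = x$pi95[1], pi.high = x$pi95[2],
    tau2 = x$tau2, k = x$k, method = x$method
  )
}
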