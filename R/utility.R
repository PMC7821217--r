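#' Net Benefit of a high-risk classification
#'
#' Net Benefit is the net proportion of true positives: the proportion of
#' true positives minus the proportion of false positives weighted by the
#' threshold odds `t / (1 - t)`. A lower risk threshold expresses lower
#' perceived harm of a false positive, so false positives are discounted
#' more at low thresholds. Treat-none has Net Benefit 0 by construction;
#' treat-all has `pi - (1 - pi) t / (1 - t)` where `pi` is the event
#' prevalence.
#'
#' @param tp,fp True and false positive counts at the stated threshold.
#' @param n Total number of records.
#' @param threshold Risk threshold in (0, 1), vectorised with `tp`/`fp`.
#' @return Net Benefit (proportion scale).
#' @examples
#' net_benefit(tp = 10, fp = 20, n = 100, threshold = 0.05)
#' @export
net_benefit <- function(tp, fp, n, threshold) {
  if (any(threshold <= 0 | threshold >= 1)) {
    abort("Net Benefit threshold must lie strictly inside (0, 1).",
          class = "pultriage_invalid_threshold")
  }
  if (any(tp + fp > n)) {
    abort("tp + fp cannot exceed n.", class = "pultriage_invalid_counts")
  }
  unname(tp / n - (fp / n) * threshold / (1 - threshold))
}

#' Decision curve for the estimated risk of EP
#'
#' Evaluates Net Benefit over a grid of risk thresholds. At each threshold
#' every record is reclassified from its estimated EP risk (the fixed
#' 5% operating label is *not* reused), and the model's Net Benefit is
#' compared with the default strategies of treating everyone as high risk
#' ("treat all") and no one ("treat none"). A strategy with lower Net
#' Benefit than a default at some threshold is harmful there; the output
#' carries a per-threshold harm flag.
#'
#' Records triaged without risk estimates (the hCG ratio cut-off strategy)
#' can be evaluated by passing their fixed labels via `label_col`; the
#' classification is then threshold-invariant, as in the source strategy.
#'
#' @param data Data frame with `p_ep` and `outcome` columns (plus
#'   `centre_id` if `by_centre`).
#' @param thresholds Risk thresholds; default 3% to 10% in 0.5% steps.
#' @param label_col Optional column of fixed `"high_risk"`/`"low_risk"`
#'   labels overriding threshold reclassification.
#' @param by_centre Also return per-centre curves.
#' @return A `pul_decision_curve` tibble: `threshold`, `strategy`
#'   (`model`, `treat_all`, `treat_none`), `net_benefit`, `harmful`
#'   (model rows only), and `centre` (`"(overall)"` or a centre id).
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(p_ep = runif(300, 0, 0.3))
#' d$outcome <- ifelse(rbinom(300, 1, d$p_ep) == 1, "EP", "IUP")
#' decision_curve(d)
#' @export
decision_curve <- function(data, thresholds = seq(0.03, 0.10, by = 0.005),
                           label_col = NULL, by_centre = FALSE) {
  stopifnot(all(thresholds > 0 & thresholds < 1))
  thresholds <- sort(unique(thresholds))
  data <- data[data$outcome %in% .pul_outcomes, , drop = FALSE]
  one_curve <- function(d, centre) {
    event <- d$outcome == "EP"
    n <- nrow(d)
    purrr::map_dfr(thresholds, function(t) {
      high <- if (is.null(label_col)) d$p_ep >= t
              else d[[label_col]] == "high_risk"
      tp <- sum(high & event); fp <- sum(high & !event)
      nb_model <- net_benefit(tp, fp, n, t)
      nb_all <- net_benefit(sum(event), sum(!event), n, t)
      tibble::tibble(
        centre = centre, threshold = t,
        strategy = c("model", "treat_all", "treat_none"),
        net_benefit = c(nb_model, nb_all, 0),
        harmful = c(nb_model < max(nb_all, 0), NA, NA)
      )
    })
  }
  out <- one_curve(data, "(overall)")
  if (by_centre) {
    per <- dplyr::group_split(dplyr::group_by(data, .data$centre_id))
    out <- dplyr::bind_rows(
      out,
      purrr::map_dfr(per, function(d) one_curve(d, as.character(d$centre_id[1])))
    )
  }
  structure(out, class = c("pul_decision_curve", class(out)))
}

# bootstrap SE of a centre's Net Benefit at one threshold: resample the
# 2x2 cell counts (multinomial) — equivalent to resampling records.
nb_bootstrap_se <- function(tp, fp, fn, tn, threshold, B = 2000) {
  n <- tp + fp + fn + tn
  draws <- rmultinom(B, n, c(tp, fp, fn, tn) / n)
  nbs <- draws[1, ] / n - (draws[2, ] / n) * threshold / (1 - threshold)
  sd(nbs)
}

#' Meta-analytically pooled decision curve across centres
#'
#' Computes each centre's Net Benefit at each threshold, attaches a
#' within-centre bootstrap standard error (resampling the classification
#' counts), and pools centres per threshold with the random-effects
#' machinery of [pool_random_effects()] on the identity scale. Centres
#' with an undefined or zero-variance Net Benefit at a threshold are
#' excluded at that threshold and recorded. Treat-all is pooled the same
#' way; treat-none is identically zero.
#'
#' @param data Data frame with `p_ep`, `outcome`, `centre_id`.
#' @param thresholds Risk threshold grid.
#' @param label_col As in [decision_curve()].
#' @param B Bootstrap resamples per centre-threshold.
#' @param seed Seed for the bootstrap.
#' @return A `pul_decision_curve` tibble with `centre = "(pooled)"` rows:
#'   `threshold`, `strategy`, `net_benefit`, `lower`, `upper`,
#'   `k_centres`, plus the per-centre rows.
#' @export
pooled_decision_curve <- function(data, thresholds = seq(0.03, 0.10, by = 0.005),
                                  label_col = NULL, B = 2000, seed = 1L) {
  data <- data[data$outcome %in% .pul_outcomes, , drop = FALSE]
  centres <- unique(as.character(data$centre_id))
  if (length(centres) < 2L) {
    abort("Pooled decision curve needs at least two centres.",
          class = "pultriage_undefined_metric")
  }
  set.seed(seed)
  per_centre <- purrr::map_dfr(centres, function(ct) {
    d <- data[data$centre_id == ct, , drop = FALSE]
    event <- d$outcome == "EP"
    n <- nrow(d)
    purrr::map_dfr(sort(unique(thresholds)), function(t) {
      high <- if (is.null(label_col)) d$p_ep >= t
              else d[[label_col]] == "high_risk"
      counts <- c(tp = sum(high & event), fp = sum(high & !event),
                  fn = sum(!high & event), tn = sum(!high & !event))
      tibble::tibble(
        centre = ct, threshold = t, n = n,
        nb_model = net_benefit(counts["tp"], counts["fp"], n, t),
        se_model = nb_bootstrap_se(counts["tp"], counts["fp"], counts["fn"],
                                   counts["tn"], t, B),
        nb_all = net_benefit(sum(event), sum(!event), n, t),
        se_all = nb_bootstrap_se(sum(event), sum(!event), 0, 0, t, B)
      )
    })
  })
  pool_one <- function(est, se, t, strat) {
    ok <- is.finite(est) & is.finite(se) & se > 0
    if (sum(ok) < 2L) {
      return(tibble::tibble(centre = "(pooled)", threshold = t,
                            strategy = strat, net_benefit = NA_real_,
                            lower = NA_real_, upper = NA_real_,
                            k_centres = sum(ok)))
    }
    pm <- pool_random_effects(est[ok], se[ok], transform = "identity")
    tibble::tibble(centre = "(pooled)", threshold = t, strategy = strat,
                   net_benefit = pm$estimate, lower = pm$ci95[1],
                   upper = pm$ci95[2], k_centres = pm$k)
  }
  pooled <- purrr::map_dfr(sort(unique(per_centre$threshold)), function(t) {
    sl <- per_centre[per_centre$threshold == t, , drop = FALSE]
    dplyr::bind_rows(
      pool_one(sl$nb_model, sl$se_model, t, "model"),
      pool_one(sl$nb_all, sl$se_all, t, "treat_all"),
      tibble::tibble(centre = "(pooled)", threshold = t,
                     strategy = "treat_none", net_benefit = 0,
                     lower = 0, upper = 0, k_centres = nrow(sl))
    )
  })
  centre_rows <- tidyr::pivot_longer(
    per_centre[, c("centre", "threshold", "nb_model", "nb_all")],
    cols = c("nb_model", "nb_all"), names_to = "strategy",
    values_to = "net_benefit")
  centre_rows$strategy <- ifelse(centre_rows$strategy == "nb_model",
                                 "model", "treat_all")
  out <- dplyr::bind_rows(pooled, centre_rows)
  structure(out, class = c("pul_decision_curve", class(out)))
}
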