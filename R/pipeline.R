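#' Read / write a PUL cohort CSV
#'
#' The cohort interchange format is a plain CSV with one row per woman and
#' the fixed header `record_id, centre_id, age, bleeding,
#' prog_supplement, prog0, hcg0, hcg48, interval_days, outcome` (extra
#' columns such as `hcg_ratio` or `true_outcome` are carried through).
#' Empty cells are missing values.
#'
#' @param path File path.
#' @return A cohort tibble.
#' @export
read_pul_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  required <- c("record_id", "centre_id", "prog0", "hcg0", "hcg48",
                "interval_days", "prog_supplement", "outcome")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort file lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pultriage_io_error")
  }
  df$prog_supplement <- as.logical(df$prog_supplement)
  tibble::as_tibble(df)
}

#' @rdname read_pul_cohort
#' @param cohort Cohort tibble.
#' @export
write_pul_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Apply the eligibility filter to a raw cohort
#'
#' Removes records whose presenting hCG is at or below 25 IU/l — the level
#' at which most urine pregnancy tests turn negative, so such records fall
#' outside the triage population. The cut is inclusive: exactly 25 IU/l is
#' excluded.
#'
#' @param data Raw cohort.
#' @return The eligible cohort tibble, with an `exclusions` attribute
#'   (tibble of reason/count).
#' @examples
#' d <- tibble::tibble(hcg0 = c(10, 25, 26, 500))
#' nrow(filter_eligible(d))
#' @export
filter_eligible <- function(data) {
  data <- tibble::as_tibble(data)
  low <- !is.na(data$hcg0) & data$hcg0 <= 25
  bad <- is.na(data$hcg0)
  out <- data[!low & !bad, , drop = FALSE]
  attr(out, "exclusions") <- tibble::tibble(
    reason = c("hcg0 <= 25 IU/l", "hcg0 missing"),
    n = c(sum(low), sum(bad))
  )
  out
}

# centre-level (estimate, se, pooling value) for one metric. The raw
# estimate is reported as-is; the pooling value gets a continuity
# correction at the 0/1 boundary so the logit pooling scale stays usable.
prop_est_se <- function(x, n_den) {
  if (n_den == 0) return(c(NA_real_, NA_real_, NA_real_))
  p <- x / n_den
  pc <- if (x == 0 || x == n_den) (x + 0.5) / (n_den + 1) else p
  c(p, sqrt(pc * (1 - pc) / n_den), pc)
}

centre_metric_rows <- function(d, strategy, has_risks, pdi_boot) {
  event <- d$outcome == "EP"
  high <- d$label == "high_risk"
  cm <- classification_metrics(d$label, d$outcome)
  rows <- list(
    pct_low_risk = prop_est_se(cm$tn + cm$fn, cm$n),
    sensitivity = prop_est_se(cm$tp, cm$tp + cm$fn),
    fpr = prop_est_se(cm$fp, cm$fp + cm$tn),
    ppv = prop_est_se(cm$tp, cm$tp + cm$fp),
    npv = prop_est_se(cm$tn, cm$tn + cm$fn)
  )
  if (has_risks) {
    rows$auc_ep <- tryCatch({
      a <- auc_binary(d$p_ep, event)
      c(a, centre_auc_se(d$p_ep, event), a)
    }, error = function(e) rep(NA_real_, 3))
    rows$auc_fpul_iup <- tryCatch({
      sub <- d[d$outcome %in% c("FPUL", "IUP"), , drop = FALSE]
      cr <- sub$p_fpul / (sub$p_fpul + sub$p_iup)
      a <- auc_conditional_pair(d, "FPUL", "IUP")
      c(a, centre_auc_se(cr, sub$outcome == "FPUL"), a)
    }, error = function(e) rep(NA_real_, 3))
    rows$pdi <- tryCatch({
      est <- pdi(d)
      boots <- vapply(seq_len(pdi_boot), function(b) {
        idx <- sample.int(nrow(d), replace = TRUE)
        tryCatch(pdi(d[idx, , drop = FALSE]), error = function(e) NA_real_)
      }, numeric(1))
      c(est, sd(boots, na.rm = TRUE), est)
    }, error = function(e) rep(NA_real_, 3))
  }
  tibble::tibble(
    strategy = strategy,
    metric = names(rows),
    estimate = unname(vapply(rows, `[`, numeric(1), 1)),
    se = unname(vapply(rows, `[`, numeric(1), 2)),
    pool_est = unname(vapply(rows, `[`, numeric(1), 3))
  )
}

nb_rows <- function(d, strategy, thresholds, has_risks, nb_boot,
                    include_treat_all = FALSE) {
  event <- d$outcome == "EP"
  n <- nrow(d)
  purrr::map_dfr(thresholds, function(t) {
    high <- if (has_risks) d$p_ep >= t else d$label == "high_risk"
    tp <- sum(high & event); fp <- sum(high & !event)
    fn <- sum(!high & event); tn <- sum(!high & !event)
    out <- tibble::tibble(
      strategy = strategy,
      metric = sprintf("nb_%.3f", t),
      estimate = net_benefit(tp, fp, n, t),
      se = nb_bootstrap_se(tp, fp, fn, tn, t, nb_boot)
    )
    if (include_treat_all) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        strategy = "treat_all",
        metric = sprintf("nb_%.3f", t),
        estimate = net_benefit(sum(event), sum(!event), n, t),
        se = nb_bootstrap_se(sum(event), sum(!event), 0, 0, t, nb_boot)
      ))
    }
    out$pool_est <- out$estimate
    out
  })
}

# Rubin-pool per centre on the pooling scale, then meta-analyse centres.
pool_metric_tbl <- function(tbl, transform) {
  fwd <- switch(transform, identity = identity, logit = qlogis, log = log)
  bck <- switch(transform, identity = identity, logit = plogis, log = exp)
  deriv <- switch(transform,
                  identity = function(x) rep(1, length(x)),
                  logit = function(x) 1 / (x * (1 - x)),
                  log = function(x) 1 / x)
  per_centre <- tbl |>
    dplyr::filter(is.finite(.data$pool_est), is.finite(.data$se),
                  .data$se > 0, is.finite(fwd(.data$pool_est))) |>
    dplyr::group_by(.data$centre) |>
    dplyr::group_modify(function(g, key) {
      rp <- suppressWarnings(
        rubin_pool(fwd(g$pool_est), (g$se * deriv(g$pool_est))^2))
      tibble::tibble(estimate_t = rp$estimate, se_t = rp$se,
                     raw = mean(g$estimate), m = rp$m)
    }) |>
    dplyr::ungroup()
  per_centre <- per_centre[is.finite(per_centre$estimate_t) &
                             is.finite(per_centre$se_t) &
                             per_centre$se_t > 0, , drop = FALSE]
  if (nrow(per_centre) == 0L) return(NULL)
  pm <- pool_random_effects(per_centre$estimate_t, per_centre$se_t,
                            transform = "identity",
                            labels = per_centre$centre)
  list(
    pooled = tibble::tibble(
      estimate = bck(pm$estimate),
      lower = bck(pm$ci95[1]), upper = bck(pm$ci95[2]),
      pi_lower = bck(pm$pi95[1]), pi_upper = bck(pm$pi95[2]),
      tau2 = pm$tau2, k_centres = pm$k, method = pm$method
    ),
    centres = tibble::tibble(
      centre = per_centre$centre,
      estimate = per_centre$raw,
      pooled_scale_estimate = bck(per_centre$estimate_t),
      se_transformed = per_centre$se_t
    )
  )
}

#' Run the full external-validation pipeline on a cohort
#'
#' Orchestrates the complete analysis: eligibility filtering (presenting
#' hCG > 25 IU/l), protocol missingness rules, multiple imputation by
#' chained equations (women lost to follow-up are imputed alongside the
#' rest), per-imputation triage and metric computation per centre, Rubin
#' pooling across imputations within centre, and random-effects
#' meta-analysis across centres with 95% confidence and prediction
#' intervals. Calibration intercept and slope (mixed-effects, all centres
#' jointly) and decision curves over the 3-10% threshold range are
#' computed alongside.
#'
#' Analysis modes mirror the study design: `"primary"` drops the
#' lost-to-follow-up records after imputation, `"include_ltfu"` keeps
#' them with imputed outcomes, and `"window_1_3"` relaxes the two-day
#' second-sample rule to 1-3 days before imputing.
#'
#' @param cohort Raw cohort tibble ([simulate_pul_cohort()] or
#'   [read_pul_cohort()]).
#' @param strategies Subset of `c("2ST", "M6P", "M6NP", "M4", "ratio")`.
#' @param config A [pul_config()].
#' @param mode Analysis mode, see above.
#' @param m Number of imputations (study scale 100; desk scale 5).
#' @param seed Integer seed controlling imputation and bootstrap draws.
#' @param threshold EP high-risk threshold for the classification metrics.
#' @param dca_thresholds Decision-curve threshold grid.
#' @param nb_boot,pdi_boot Bootstrap resamples for Net Benefit / PDI
#'   standard errors.
#' @param maxit Imputation burn-in iterations.
#' @param calibrate Fit the mixed-effects calibration models (the slowest
#'   stage); disable for quick classification-only runs.
#' @param exclusions Optional tibble `(centre, metric)` of centre-metric
#'   pairs to drop before meta-analysis (e.g. a centre whose progesterone
#'   assay floor makes Step-1 proportions meaningless).
#' @return A `pul_validation` bundle: tibbles `metrics` (pooled, with CI,
#'   PI, tau2), `centre_metrics`, `calibration`, `decision_curves`,
#'   `exclusion_log`, and `settings`.
#' @export
run_validation <- function(cohort,
                           strategies = c("2ST", "M6P", "M6NP", "M4", "ratio"),
                           config = pul_config(),
                           mode = c("primary", "include_ltfu", "window_1_3"),
                           m = 100, seed = 1L,
                           threshold = config$threshold,
                           dca_thresholds = seq(0.03, 0.10, by = 0.005),
                           nb_boot = 2000, pdi_boot = 200, maxit = 20,
                           calibrate = TRUE, exclusions = NULL) {
  mode <- match.arg(mode)
  strategies <- match.arg(strategies, several.ok = TRUE)
  t0 <- Sys.time()
  stage <- function(msg) message(sprintf("[pultriage +%5.1fs] %s",
                                         as.numeric(Sys.time() - t0,
                                                    units = "secs"), msg))
  stage("eligibility filter")
  eligible <- filter_eligible(cohort)
  excl <- attr(eligible, "exclusions")

  stage("missingness rules")
  rule_mode <- if (mode == "window_1_3") "window_1_3" else "primary"
  ruled <- apply_missingness_rules(eligible, mode = rule_mode)
  originally_ltfu <- ruled$outcome == "LTFU" | is.na(ruled$outcome)

  stage(sprintf("multiple imputation (m = %d)", m))
  imp <- impute_chained(ruled, m = m, seed = seed, maxit = maxit)

  set.seed(seed + 10000L)
  strategy_has_risks <- function(s) s != "ratio"
  centre_tbl <- list(); calib_tbl <- list()
  for (j in seq_len(m)) {
    stage(sprintf("imputation %d/%d: triage + metrics", j, m))
    dat <- imp$completed[[j]]
    analysis <- if (mode == "include_ltfu") dat
                else dat[!originally_ltfu, , drop = FALSE]
    for (s in strategies) {
      dec <- triage_pul(analysis, s, config, threshold)
      has_risks <- strategy_has_risks(s)
      per_centre <- dec |>
        dplyr::group_by(.data$centre_id) |>
        dplyr::group_modify(function(g, key) {
          dplyr::bind_rows(
            centre_metric_rows(g, s, has_risks, pdi_boot),
            nb_rows(g, s, dca_thresholds, has_risks, nb_boot,
                    include_treat_all = s == strategies[1])
          )
        }) |>
        dplyr::ungroup() |>
        dplyr::rename(centre = "centre_id") |>
        dplyr::mutate(imputation = j)
      centre_tbl[[length(centre_tbl) + 1L]] <- per_centre
      if (has_risks && calibrate) {
        cal <- fit_calibration(dec)
        calib_tbl[[length(calib_tbl) + 1L]] <- tibble::tibble(
          strategy = s, imputation = j,
          term = c("intercept", "slope"),
          estimate = c(cal$intercept, cal$slope),
          se = c(cal$intercept_se, cal$slope_se),
          flags = paste(cal$flags, collapse = ";")
        )
      }
    }
  }
  centre_tbl <- dplyr::bind_rows(centre_tbl)

  if (!is.null(exclusions)) {
    centre_tbl <- dplyr::anti_join(centre_tbl, exclusions,
                                   by = c("centre", "metric"))
  }

  stage("Rubin pooling + meta-analysis")
  metric_scale <- function(metric) {
    if (grepl("^nb_", metric)) "identity" else "logit"
  }
  keys <- dplyr::distinct(centre_tbl, .data$strategy, .data$metric)
  pooled_rows <- list(); centre_rows <- list()
  for (i in seq_len(nrow(keys))) {
    s <- keys$strategy[i]; mt <- keys$metric[i]
    sl <- centre_tbl[centre_tbl$strategy == s & centre_tbl$metric == mt, ]
    pm <- tryCatch(pool_metric_tbl(sl, metric_scale(mt)),
                   error = function(e) NULL)
    if (is.null(pm)) next
    pooled_rows[[length(pooled_rows) + 1L]] <-
      dplyr::mutate(pm$pooled, strategy = s, metric = mt, .before = 1)
    centre_rows[[length(centre_rows) + 1L]] <-
      dplyr::mutate(pm$centres, strategy = s, metric = mt, .before = 1)
  }
  metrics <- dplyr::bind_rows(pooled_rows)
  centre_metrics <- dplyr::bind_rows(centre_rows)

  calibration <- NULL
  if (length(calib_tbl) > 0) {
    calibration <- dplyr::bind_rows(calib_tbl) |>
      dplyr::group_by(.data$strategy, .data$term) |>
      dplyr::group_modify(function(g, key) {
        suppressWarnings(rubin_pool(g$estimate, g$se^2))
      }) |>
      dplyr::ungroup()
  }

  dcurves <- metrics |>
    dplyr::filter(grepl("^nb_", .data$metric)) |>
    dplyr::mutate(threshold = as.numeric(sub("^nb_", "", .data$metric))) |>
    dplyr::select("strategy", "threshold", net_benefit = "estimate",
                  "lower", "upper", "k_centres")
  if (nrow(dcurves) > 0) {
    tn <- dplyr::distinct(dcurves, .data$threshold)
    dcurves <- dplyr::bind_rows(
      dcurves,
      tibble::tibble(strategy = "treat_none", threshold = tn$threshold,
                     net_benefit = 0, lower = 0, upper = 0,
                     k_centres = NA_integer_))
    ta <- dcurves[dcurves$strategy == "treat_all", ]
    dcurves <- dcurves |>
      dplyr::left_join(
        dplyr::select(ta, "threshold", nb_all = "net_benefit"),
        by = "threshold") |>
      dplyr::mutate(harmful = dplyr::if_else(
        .data$strategy %in% c("treat_all", "treat_none"), NA,
        .data$net_benefit < pmax(.data$nb_all, 0))) |>
      dplyr::select(-"nb_all")
  }
  metrics <- metrics[!grepl("^nb_", metrics$metric) |
                       metrics$metric == sprintf("nb_%.3f", threshold), ]

  stage("done")
  structure(list(
    metrics = metrics,
    centre_metrics = centre_metrics,
    calibration = calibration,
    decision_curves = structure(dcurves,
                                class = c("pul_decision_curve",
                                          class(dcurves))),
    exclusion_log = excl,
    settings = list(mode = mode, m = m, seed = seed, threshold = threshold,
                    strategies = strategies, nb_boot = nb_boot,
                    pdi_boot = pdi_boot, maxit = maxit)
  ), class = "pul_validation")
}

#' @export
print.pul_validation <- function(x, ...) {
  cat("<pul_validation>", x$settings$mode, "analysis, m =", x$settings$m,
      "imputations\n")
  cat("  strategies:", paste(x$settings$strategies, collapse = ", "), "\n")
  key <- x$metrics[x$metrics$metric %in%
                     c("auc_ep", "sensitivity", "fpr", "pct_low_risk"), ]
  print(as.data.frame(key[, c("strategy", "metric", "estimate",
                              "lower", "upper")]), row.names = FALSE,
        digits = 3)
  invisible(x)
}

#' Side-by-side strategy comparison
#'
#' Summarises a validation bundle as one row per strategy with the
#' headline metrics (EP AUC, sensitivity, false-positive rate, predictive
#' values, percentage triaged low risk, Net Benefit at the operating
#' threshold) and a harm flag marking strategies whose Net Benefit at the
#' operating threshold falls below the better default strategy.
#'
#' @param bundle A [run_validation()] result.
#' @return A tibble, one row per strategy, ordered by EP AUC then Net
#'   Benefit.
#' @export
compare_strategies <- function(bundle) {
  stopifnot(inherits(bundle, "pul_validation"))
  nb_name <- sprintf("nb_%.3f", bundle$settings$threshold)
  wanted <- c("auc_ep", "sensitivity", "fpr", "ppv", "npv",
              "pct_low_risk", nb_name)
  wide <- bundle$metrics |>
    dplyr::filter(.data$metric %in% wanted,
                  .data$strategy != "treat_all") |>
    dplyr::select("strategy", "metric", "estimate") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "estimate")
  if (nb_name %in% names(wide)) {
    names(wide)[names(wide) == nb_name] <- "net_benefit"
    ta <- bundle$metrics[bundle$metrics$strategy == "treat_all" &
                           bundle$metrics$metric == nb_name, ]
    nb_default <- if (nrow(ta) > 0) max(ta$estimate, 0) else 0
    wide$harmful <- wide$net_benefit < nb_default
  }
  dplyr::arrange(wide, dplyr::desc(dplyr::coalesce(.data$auc_ep, -Inf)),
                 dplyr::desc(dplyr::coalesce(.data$net_benefit, -Inf)))
}
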