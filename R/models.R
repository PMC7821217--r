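#' Serum hCG ratio
#'
#' The hCG ratio is the serum beta-hCG measured about 48 hours after
#' presentation divided by the beta-hCG at presentation. A ratio below 1
#' means falling levels (typical of a failing PUL), a ratio well above 1
#' means a doubling-type rise (typical of an intrauterine pregnancy), and a
#' plateau near 1 raises the suspicion of ectopic pregnancy.
#'
#' @param hcg0 Beta-hCG at presentation, IU/l, strictly positive.
#' @param hcg48 Beta-hCG at the second visit, IU/l, strictly positive.
#' @return `hcg48 / hcg0`, vectorised. `NA` inputs propagate.
#' @examples
#' compute_hcg_ratio(1000, 870)
#' @export
compute_hcg_ratio <- function(hcg0, hcg48) {
  bad <- (!is.na(hcg0) & hcg0 <= 0) | (!is.na(hcg48) & hcg48 <= 0)
  if (any(bad)) {
    abort("hCG measurements must be strictly positive.",
          class = "pultriage_invalid_measurement")
  }
  hcg48 / hcg0
}

eval_basis <- function(model, data) {
  need <- model_required_fields(model)
  for (f in c("hcg0", need)) {
    if (!f %in% names(data)) {
      abort(sprintf("Model %s requires predictor '%s', absent from data.",
                    model$name, f),
            class = "pultriage_missing_predictor")
    }
  }
  X <- vapply(model$basis, function(t) .pul_terms[[t]](data),
              numeric(nrow(data)))
  X <- matrix(X, nrow = nrow(data),
              dimnames = list(NULL, model$basis))
  done <- complete.cases(as.data.frame(X))
  if (any(!is.finite(X[done, , drop = FALSE]))) {
    abort(sprintf("Non-finite basis value for model %s (check for zero or negative biomarker values).",
                  model$name),
          class = "pultriage_numeric_domain")
  }
  X
}

softmax3 <- function(eta_iup, eta_ep) {
  m <- pmax(0, eta_iup, eta_ep)
  e0 <- exp(-m)
  e1 <- exp(eta_iup - m)
  e2 <- exp(eta_ep - m)
  s <- e0 + e1 + e2
  cbind(p_fpul = e0 / s, p_iup = e1 / s, p_ep = e2 / s)
}

#' Estimate PUL outcome probabilities from a multinomial risk model
#'
#' Evaluates one of the configured multinomial logistic models (M4, M6P or
#' M6NP) for every row of a cohort and appends the estimated probabilities
#' of the three final outcomes: failing PUL (FPUL, the reference category),
#' intrauterine pregnancy (IUP) and ectopic pregnancy (EP, which includes
#' persistent PUL). Linear predictors for IUP and EP are formed from the
#' model's basis terms and softmax-normalised, so the three probabilities
#' always sum to one.
#'
#' @param data A cohort data frame with columns `hcg0` and, as the model
#'   requires, `hcg_ratio` and `prog0`. If `hcg_ratio` is absent but
#'   `hcg48` is present it is derived on the fly.
#' @param model Model name (`"M4"`, `"M6P"`, `"M6NP"`) or a `pul_model`
#'   object.
#' @param config A [pul_config()] holding the model coefficients.
#' @param on_missing `"error"` (default) aborts naming the first field with
#'   a missing value among required predictors; `"na"` returns `NA`
#'   probabilities for those rows (the triage wrapper uses this to apply
#'   its fallback rules).
#' @return `data` as a tibble with `p_fpul`, `p_iup`, `p_ep` and
#'   `model_used` columns appended.
#' @examples
#' cohort <- tibble::tibble(hcg0 = c(500, 1200), hcg_ratio = c(0.4, 1.1),
#'                          prog0 = c(3, 25))
#' predict_pul_risks(cohort, "M6P")
#' @export
predict_pul_risks <- function(data, model = "M6P", config = pul_config(),
                              on_missing = c("error", "na")) {
  on_missing <- match.arg(on_missing)
  mod <- if (inherits(model, "pul_model")) model else config$models[[model]]
  if (is.null(mod)) {
    abort(sprintf("Unknown model '%s'; configured models: %s.", model,
                  paste(names(config$models), collapse = ", ")),
          class = "pultriage_config_error")
  }
  data <- tibble::as_tibble(data)
  if (!"hcg_ratio" %in% names(data) && "hcg48" %in% names(data)) {
    data$hcg_ratio <- compute_hcg_ratio(data$hcg0, data$hcg48)
  }
  X <- eval_basis(mod, data)
  ok <- complete.cases(as.data.frame(X))
  if (any(!ok) && on_missing == "error") {
    miss <- c("hcg0", model_required_fields(mod))
    field <- miss[vapply(miss, function(f) anyNA(data[[f]]), logical(1))][1]
    abort(sprintf("Model %s: missing values in required predictor '%s'.",
                  mod$name, field),
          class = "pultriage_missing_predictor")
  }
  p <- matrix(NA_real_, nrow(data), 3,
              dimnames = list(NULL, c("p_fpul", "p_iup", "p_ep")))
  if (any(ok)) {
    eta_iup <- drop(X[ok, , drop = FALSE] %*% mod$beta_iup)
    eta_ep <- drop(X[ok, , drop = FALSE] %*% mod$beta_ep)
    p[ok, ] <- softmax3(eta_iup, eta_ep)
  }
  data$p_fpul <- unname(p[, "p_fpul"])
  data$p_iup <- unname(p[, "p_iup"])
  data$p_ep <- unname(p[, "p_ep"])
  data$model_used <- ifelse(ok, mod$name, NA_character_)
  data
}

#' Classify an estimated EP risk as high or low
#'
#' A PUL is flagged high risk of ectopic pregnancy when the estimated EP
#' probability reaches the decision threshold; the default threshold of 5%
#' accepts up to 19 false positives per true positive, the trade-off
#' implied by the threshold odds.
#'
#' @param p_ep Estimated probability of EP, vectorised.
#' @param threshold Risk threshold in (0, 1); the comparison is inclusive
#'   (`p_ep >= threshold` is high risk).
#' @return Character vector, `"high_risk"` or `"low_risk"`.
#' @examples
#' classify_high_risk(c(0.049, 0.05, 0.4))
#' @export
classify_high_risk <- function(p_ep, threshold = 0.05) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    abort("threshold must be a single probability strictly inside (0, 1).",
          class = "pultriage_invalid_threshold")
  }
  ifelse(p_ep >= threshold, "high_risk", "low_risk")
}

#' Classify a PUL from fixed hCG ratio cut-offs
#'
#' The ratio-cut-off rule classifies without any risk estimation: a ratio
#' below 0.87 (a fall of more than 13%) is called FPUL, a ratio above 1.66
#' (a rise of more than 66%) is called IUP, and anything inside the band
#' — a plateau — is flagged high risk of EP. Both band ends are inclusive:
#' the complementary rules use strict inequalities.
#'
#' @param ratio hCG ratio, strictly positive, vectorised.
#' @param cutoffs Length-2 numeric `(lower, upper)` band.
#' @return A tibble with `predicted_class` (`"FPUL"`, `"EP_high_risk"`,
#'   `"IUP"`) and `label` (`"high_risk"` / `"low_risk"`).
#' @examples
#' classify_hcg_ratio(c(0.5, 1, 2))
#' @export
classify_hcg_ratio <- function(ratio, cutoffs = c(0.87, 1.66)) {
  if (any(!is.na(ratio) & ratio <= 0)) {
    abort("hCG ratio must be strictly positive.",
          class = "pultriage_invalid_measurement")
  }
  cls <- dplyr::case_when(
    is.na(ratio) ~ NA_character_,
    ratio < cutoffs[1] ~ "FPUL",
    ratio > cutoffs[2] ~ "IUP",
    TRUE ~ "EP_high_risk"
  )
  tibble::tibble(
    predicted_class = cls,
    label = dplyr::if_else(cls == "EP_high_risk", "high_risk", "low_risk")
  )
}

#' Triage a PUL cohort with one of the evaluated strategies
#'
#' Applies one of five triage approaches to every record and returns the
#' decisions with full provenance:
#'
#' * `"2ST"` — the two-step triage strategy. Step 1 classifies a record as
#'   low risk when the presenting progesterone is at most 2 nmol/l (and no
#'   progesterone supplements are taken), assigning the fixed risk triple
#'   (0.961, 0.022, 0.017) for (FPUL, IUP, EP) taken from the model's
#'   development data. All remaining records are triaged by the M6P risk
#'   model at the EP threshold; records for which M6P is inapplicable
#'   (progesterone missing or supplemented) fall back to M6NP, and the
#'   output records which model decided each row.
#' * `"M6P"`, `"M6NP"`, `"M4"` — the named model alone, with the same
#'   M6P-to-M6NP fallback for `"M6P"`.
#' * `"ratio"` — fixed hCG ratio cut-offs (no risk estimates).
#'
#' @param data Cohort data frame (columns `hcg0`, and as needed `hcg48` or
#'   `hcg_ratio`, `prog0`, `prog_supplement`).
#' @param strategy One of `"2ST"`, `"M6P"`, `"M6NP"`, `"M4"`, `"ratio"`.
#' @param config A [pul_config()].
#' @param threshold EP high-risk threshold; defaults to the configured 5%.
#' @return `data` with appended columns `p_fpul`, `p_iup`, `p_ep`,
#'   `label`, `decided_by` (`"step1_progesterone"`, `"model_threshold"` or
#'   `"ratio_cutoff"`), `model_used` and, for the ratio strategy,
#'   `predicted_class`.
#' @examples
#' cohort <- tibble::tibble(hcg0 = c(600, 900), hcg48 = c(250, 950),
#'                          prog0 = c(1.5, 30), prog_supplement = FALSE)
#' triage_pul(cohort, "2ST")[, c("p_ep", "label", "decided_by")]
#' @export
triage_pul <- function(data, strategy = c("2ST", "M6P", "M6NP", "M4", "ratio"),
                       config = pul_config(), threshold = config$threshold) {
  strategy <- match.arg(strategy)
  data <- tibble::as_tibble(data)
  if (!"hcg_ratio" %in% names(data) && "hcg48" %in% names(data)) {
    data$hcg_ratio <- compute_hcg_ratio(data$hcg0, data$hcg48)
  }
  n <- nrow(data)
  supp <- if ("prog_supplement" %in% names(data)) {
    !is.na(data$prog_supplement) & data$prog_supplement
  } else rep(FALSE, n)
  prog_ok <- if ("prog0" %in% names(data)) {
    !is.na(data$prog0) & !supp
  } else rep(FALSE, n)

  if (strategy == "ratio") {
    if (!"hcg_ratio" %in% names(data)) {
      abort("Ratio cut-off triage requires hcg48 (or hcg_ratio).",
            class = "pultriage_missing_predictor")
    }
    cls <- classify_hcg_ratio(data$hcg_ratio, config$ratio_cutoffs)
    data$p_fpul <- NA_real_
    data$p_iup <- NA_real_
    data$p_ep <- NA_real_
    data$predicted_class <- cls$predicted_class
    data$label <- cls$label
    data$decided_by <- ifelse(is.na(cls$label), NA_character_, "ratio_cutoff")
    data$model_used <- NA_character_
    return(data)
  }

  step1 <- rep(FALSE, n)
  if (strategy == "2ST") {
    step1 <- prog_ok & data$prog0 <= config$step1$progesterone_cutoff
  }

  # model-based step (all rows except Step-1 discharges)
  if (!"hcg_ratio" %in% names(data)) data$hcg_ratio <- NA_real_
  model_name <- switch(strategy, `2ST` = "M6P", strategy)
  if (model_name == "M6P" && !"prog0" %in% names(data)) {
    model_name <- "M6NP"  # progesterone never measured: full fallback
  }
  out <- predict_pul_risks(data, model_name, config, on_missing = "na")
  if (model_name == "M6P" && strategy %in% c("2ST", "M6P")) {
    # fallback: progesterone unusable -> M6NP (the study spreadsheet's rule)
    fb <- !step1 & (!prog_ok)
    if (any(fb)) {
      alt <- predict_pul_risks(data[fb, , drop = FALSE], "M6NP", config,
                               on_missing = "na")
      out$p_fpul[fb] <- alt$p_fpul
      out$p_iup[fb] <- alt$p_iup
      out$p_ep[fb] <- alt$p_ep
      out$model_used[fb] <- alt$model_used
    }
  }
  if (any(step1)) {
    out$p_fpul[step1] <- unname(config$step1$risks["p_fpul"])
    out$p_iup[step1] <- unname(config$step1$risks["p_iup"])
    out$p_ep[step1] <- unname(config$step1$risks["p_ep"])
    out$model_used[step1] <- NA_character_
  }
  out$label <- classify_high_risk(out$p_ep, threshold)
  out$label[step1] <- "low_risk"
  out$decided_by <- dplyr::case_when(
    step1 ~ "step1_progesterone",
    !is.na(out$p_ep) ~ "model_threshold",
    TRUE ~ NA_character_
  )
  out
}
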