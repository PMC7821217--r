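#' Binary AUC by the Mann-Whitney concordance probability
#'
#' The area under the ROC curve for a binary outcome, computed as the
#' probability that a randomly drawn event carries a higher estimated risk
#' than a randomly drawn non-event, with ties counting one half. Computed
#' from midranks, so it is exact and O(n log n).
#'
#' @param risks Numeric vector of estimated risks (any monotone score).
#' @param is_event Logical vector, `TRUE` for events.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_binary(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))
#' @export
auc_binary <- function(risks, is_event) {
  stopifnot(length(risks) == length(is_event))
  keep <- !is.na(risks) & !is.na(is_event)
  risks <- risks[keep]
  is_event <- as.logical(is_event[keep])
  n1 <- sum(is_event)
  n0 <- sum(!is_event)
  if (n1 == 0L || n0 == 0L) {
    abort("AUC undefined: need at least one event and one non-event.",
          class = "pultriage_undefined_metric")
  }
  r <- rank(risks, ties.method = "average")
  (sum(r[is_event]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pairwise AUC between two outcome categories by the conditional-risk method
#'
#' For discriminating, say, FPUL from IUP with a three-category risk model,
#' each record's score is its risk of the first category conditional on the
#' outcome being one of the two: `p_a / (p_a + p_b)`. The AUC of that score
#' over the records whose observed outcome is in `{cat_a, cat_b}` is the
#' conditional-risk pairwise AUC.
#'
#' @param data Data frame with columns `p_fpul`, `p_iup`, `p_ep` and
#'   `outcome`.
#' @param cat_a,cat_b Outcome category names; `cat_a` plays the event role.
#' @return AUC in \[0, 1\].
#' @export
auc_conditional_pair <- function(data, cat_a = "FPUL", cat_b = "IUP") {
  pcol <- function(cat) switch(cat, FPUL = "p_fpul", IUP = "p_iup",
                               EP = "p_ep")
  sub <- data[data$outcome %in% c(cat_a, cat_b), , drop = FALSE]
  pa <- sub[[pcol(cat_a)]]
  pb <- sub[[pcol(cat_b)]]
  denom <- pa + pb
  if (any(!is.na(denom) & denom == 0)) {
    abort("Conditional risk undefined: p_a + p_b = 0 for some record.",
          class = "pultriage_numeric_domain")
  }
  auc_binary(pa / denom, sub$outcome == cat_a)
}

#' Polytomous discrimination index (PDI)
#'
#' A three-category generalisation of the AUC: draw one record from each
#' outcome category and ask, for category i, whether the category-i record
#' has the highest estimated risk of outcome i among the three (ties split
#' equally among the tied records). The PDI is the average of the three
#' category-specific triplet proportions; 1/3 is chance level, 1 is perfect.
#'
#' Computed by sort/count aggregation over the three category-specific risk
#' vectors, O(n log n); an exhaustive O(n^3) triplet enumeration is kept in
#' the test-suite as the oracle.
#'
#' @param data Data frame with columns `p_fpul`, `p_iup`, `p_ep` and
#'   `outcome` (values in FPUL/IUP/EP).
#' @return PDI in \[0, 1\].
#' @export
pdi <- function(data) {
  data <- data[data$outcome %in% .pul_outcomes, , drop = FALSE]
  ns <- table(factor(data$outcome, .pul_outcomes))
  if (any(ns == 0L)) {
    abort("PDI undefined: every outcome category needs at least one record.",
          class = "pultriage_undefined_metric")
  }
  pcols <- c(FPUL = "p_fpul", IUP = "p_iup", EP = "p_ep")
  per_cat <- vapply(.pul_outcomes, function(cat) {
    p <- data[[pcols[[cat]]]]
    x <- p[data$outcome == cat]                 # own-category records
    others <- setdiff(.pul_outcomes, cat)
    y <- p[data$outcome == others[1]]
    z <- p[data$outcome == others[2]]
    .pdi_component(x, y, z)
  }, numeric(1))
  mean(per_cat)
}

# P(x beats both y and z, fractional ties) over all (x, y, z) triplets
.pdi_component <- function(x, y, z) {
  cy_lt <- .count_less_equal(x, y)
  cz_lt <- .count_less_equal(x, z)
  contrib <- cy_lt$lt * cz_lt$lt +
    0.5 * (cy_lt$eq * cz_lt$lt + cy_lt$lt * cz_lt$eq) +
    (1 / 3) * cy_lt$eq * cz_lt$eq
  sum(contrib) / (length(x) * length(y) * length(z))
}

# for each value of x: how many entries of v are strictly less / exactly equal
.count_less_equal <- function(x, v) {
  sv <- sort(v)
  lt <- findInterval(x, sv, left.open = TRUE)   # v < x  (just below x)
  le <- findInterval(x, sv)                     # v <= x
  list(lt = lt, eq = le - lt)
}

#' Classification metrics for a triage strategy
#'
#' Cross-tabulates high/low-risk labels against the final outcome with
#' ectopic pregnancy as the positive class, and reports the percentage
#' classified low risk, sensitivity, false-positive rate, positive and
#' negative predictive value. Metrics with an empty denominator are
#' reported as `NA` (undefined), never coerced to 0.
#'
#' @param label Character vector of `"high_risk"` / `"low_risk"` labels.
#' @param outcome Final outcomes; records whose outcome is not one of
#'   FPUL/IUP/EP are dropped.
#' @return A one-row tibble: `n`, `tp`, `fp`, `tn`, `fn`, `pct_low_risk`,
#'   `sensitivity`, `fpr`, `ppv`, `npv`.
#' @examples
#' classification_metrics(rep(c("high_risk", "low_risk"), c(30, 70)),
#'                        rep(c("EP", "FPUL", "EP", "IUP"), c(10, 20, 10, 60)))
#' @export
classification_metrics <- function(label, outcome) {
  keep <- outcome %in% .pul_outcomes & !is.na(label)
  label <- label[keep]
  event <- outcome[keep] == "EP"
  high <- label == "high_risk"
  tp <- sum(high & event)
  fp <- sum(high & !event)
  fn <- sum(!high & event)
  tn <- sum(!high & !event)
  n <- tp + fp + fn + tn
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  tibble::tibble(
    n = n, tp = tp, fp = fp, tn = tn, fn = fn,
    pct_low_risk = div(tn + fn, n),
    sensitivity = div(tp, tp + fn),
    fpr = div(fp, fp + tn),
    ppv = div(tp, tp + fp),
    npv = div(tn, tn + fn)
  )
}
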