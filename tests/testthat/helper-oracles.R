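# Independent brute-force oracles, kept deliberately naive.

# AUC by exhaustive event/non-event pair counting, ties worth 1/2.
oracle_auc <- function(risks, is_event) {
  ev <- risks[is_event]
  ne <- risks[!is_event]
  total <- 0
  for (a in ev) for (b in ne) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(ev) * length(ne))
}

# PDI by exhaustive enumeration of all (FPUL, IUP, EP) triplets: for
# category i the triplet scores 1 if the category-i record has the
# strictly highest risk of outcome i, with ties split equally.
oracle_pdi <- function(data) {
  idx <- split(seq_len(nrow(data)), data$outcome)
  pcols <- c(FPUL = "p_fpul", IUP = "p_iup", EP = "p_ep")
  cats <- c("FPUL", "IUP", "EP")
  sums <- setNames(numeric(3), cats)
  n_trip <- 0
  for (a in idx$FPUL) for (b in idx$IUP) for (c in idx$EP) {
    n_trip <- n_trip + 1
    trip <- c(a, b, c)
    for (i in seq_along(cats)) {
      p <- data[[pcols[cats[i]]]][trip]
      mx <- max(p)
      tied <- sum(p == mx)
      if (p[i] == mx) sums[cats[i]] <- sums[cats[i]] + 1 / tied
    }
  }
  mean(sums / n_trip)
}

# random simplex-constrained risk triples
random_triples <- function(n, rounded = FALSE) {
  g <- matrix(stats::rgamma(3 * n, shape = 1), ncol = 3)
  p <- g / rowSums(g)
  if (rounded) p <- round(p, 1) / pmax(rowSums(round(p, 1)), 1e-12)
  tibble::tibble(p_fpul = p[, 1], p_iup = p[, 2], p_ep = p[, 3])
}

# minimal complete cohort for triage tests
toy_cohort <- function(prog0 = 10, hcg0 = 500, hcg48 = 500,
                       supplement = FALSE) {
  tibble::tibble(hcg0 = hcg0, hcg48 = hcg48, prog0 = prog0,
                 prog_supplement = supplement)
}

# intercept-only coefficient set for controlled softmax outputs
intercept_model <- function(name = "M6NP", beta_iup = 0, beta_ep = 0) {
  pultriage:::new_pul_model(name, "intercept", beta_iup, beta_ep)
}
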