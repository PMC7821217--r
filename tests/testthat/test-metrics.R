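test_that("binary AUC matches hand-checked examples", {
  expect_equal(auc_binary(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_binary(rep(0.3, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_equal(auc_binary(c(0.1, 0.4, 0.35, 0.8),
                          c(FALSE, FALSE, TRUE, TRUE)), 0.75)
  expect_error(auc_binary(c(0.1, 0.2), c(TRUE, TRUE)),
               class = "pultriage_undefined_metric")
})

test_that("binary AUC equals exhaustive pair counting on random cohorts", {
  set.seed(2024)
  for (rep in 1:100) {
    n <- sample(4:30, 1)
    risks <- sample(round(runif(n), sample(c(1, 2, 6), 1)))  # force ties
    ev <- runif(n) < 0.4
    if (!any(ev) || all(ev)) next
    expect_equal(auc_binary(risks, ev), oracle_auc(risks, ev))
  }
})

test_that("AUC is invariant to record order and agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(7)
  risks <- runif(200)
  ev <- runif(200) < 0.3
  perm <- sample(200)
  expect_equal(auc_binary(risks, ev), auc_binary(risks[perm], ev[perm]))
  ref <- as.numeric(pROC::auc(pROC::roc(ev, risks, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_binary(risks, ev), ref, tolerance = 1e-12)
})

test_that("conditional-risk pairwise AUC restricts and normalises correctly", {
  d <- tibble::tibble(
    p_fpul = c(0.8, 0.6, 0.7, 0.2),
    p_iup = 1 - c(0.8, 0.6, 0.7, 0.2),
    p_ep = 0,
    outcome = c("FPUL", "FPUL", "IUP", "IUP")
  )
  expect_equal(auc_conditional_pair(d, "FPUL", "IUP"), 0.75)

  uniform <- tibble::tibble(p_fpul = 1 / 3, p_iup = 1 / 3, p_ep = 1 / 3,
                            outcome = rep(c("FPUL", "IUP"), 5))
  expect_equal(auc_conditional_pair(uniform), 0.5)

  zero <- tibble::tibble(p_fpul = 0, p_iup = 0, p_ep = 1,
                         outcome = c("FPUL", "IUP"))
  expect_error(auc_conditional_pair(zero), class = "pultriage_numeric_domain")
})

test_that("PDI hits its closed-form anchors", {
  same <- dplyr::bind_cols(random_triples(1)[rep(1, 9), ],
                           tibble::tibble(outcome = rep(c("FPUL", "IUP", "EP"), 3)))
  expect_equal(pdi(same), 1 / 3)

  dominant <- tibble::tibble(
    p_fpul = c(0.9, 0.1, 0.1), p_iup = c(0.05, 0.8, 0.1),
    p_ep = c(0.05, 0.1, 0.8), outcome = c("FPUL", "IUP", "EP"))
  expect_equal(pdi(dominant), 1)

  expect_error(pdi(dominant[1:2, ]), class = "pultriage_undefined_metric")
})

test_that("PDI equals exhaustive triplet enumeration on random cohorts", {
  set.seed(99)
  for (rep in 1:100) {
    counts <- sample(1:8, 3, replace = TRUE)
    d <- random_triples(sum(counts), rounded = rep %% 2 == 0)
    d$outcome <- rep(c("FPUL", "IUP", "EP"), counts)
    d <- d[sample(nrow(d)), ]
    expect_equal(pdi(d), oracle_pdi(d), tolerance = 1e-12)
  }
})

test_that("classification metrics count with EP as the positive class", {
  lab <- rep(c("high_risk", "low_risk"), c(30, 70))
  out <- rep(c("EP", "FPUL", "EP", "IUP"), c(10, 20, 10, 60))
  cm <- classification_metrics(lab, out)
  expect_equal(cm$tp, 10); expect_equal(cm$fp, 20)
  expect_equal(cm$fn, 10); expect_equal(cm$tn, 60)
  expect_equal(cm$ppv, 1 / 3)
  expect_equal(cm$npv, 6 / 7)
  expect_equal(cm$pct_low_risk, 0.7)
  expect_equal(cm$sensitivity, 0.5)
  expect_equal(cm$fpr, 0.25)
})

test_that("empty denominators yield undefined metrics, not zero", {
  cm <- classification_metrics(rep("low_risk", 5),
                               c("FPUL", "FPUL", "IUP", "EP", "EP"))
  expect_true(is.na(cm$ppv))
  expect_equal(cm$fpr, 0)
  expect_equal(cm$sensitivity, 0)
  # LTFU records are dropped from the table
  cm2 <- classification_metrics(rep("high_risk", 3), c("EP", "LTFU", "FPUL"))
  expect_equal(cm2$n, 2)
})
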