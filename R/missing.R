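#' Apply the protocol's missingness rules to a raw cohort
#'
#' Two rules from the study protocol turn recorded values into analysis
#' missing values:
#'
#' * a second hCG value is only usable when the sample was taken two
#'   calendar days after the first, so `hcg48` is set missing when
#'   `interval_days != 2`. In the sensitivity mode mirroring the model's
#'   development procedure, samples taken 1-3 days after the first are
#'   retained (`window_1_3`).
#' * progesterone is unreliable under progesterone supplementation, so
#'   `prog0` is set missing when `prog_supplement` is `TRUE`.
#'
#' The overwritten values are preserved in audit columns
#' (`hcg48_recorded`, `prog0_recorded`) and `hcg_ratio` is kept in step
#' with `hcg48`.
#'
#' @param data Raw cohort with `hcg48`, `interval_days`, `prog0`,
#'   `prog_supplement`.
#' @param mode `"primary"` (2-day rule) or `"window_1_3"`.
#' @return The cohort tibble with rules applied and audit columns added.
#' @export
apply_missingness_rules <- function(data, mode = c("primary", "window_1_3")) {
  mode <- match.arg(mode)
  data <- tibble::as_tibble(data)
  data$hcg48_recorded <- data$hcg48
  data$prog0_recorded <- data$prog0
  bad_interval <- if (mode == "primary") {
    !is.na(data$hcg48) & (is.na(data$interval_days) | data$interval_days != 2L)
  } else {
    !is.na(data$hcg48) &
      (is.na(data$interval_days) | !data$interval_days %in% 1:3)
  }
  data$hcg48[bad_interval] <- NA_real_
  supp <- !is.na(data$prog_supplement) & data$prog_supplement
  data$prog0[supp] <- NA_real_
  if ("hcg_ratio" %in% names(data)) {
    data$hcg_ratio <- compute_hcg_ratio(data$hcg0, data$hcg48)
  }
  data
}

#' Multiple imputation by chained equations for a PUL cohort
#'
#' Fills the missing values the analysis has to live with — presenting
#' progesterone, second hCG, and the final outcome of women lost to
#' follow-up — under a missing-at-random assumption, producing `m`
#' completed datasets. Continuous biomarkers are imputed on the log scale
#' by predictive mean matching (type-1 matching with a posterior draw of
#' the regression coefficients, 5 donors); the three-category outcome by a
#' multinomial logistic model with a draw from the predicted category
#' probabilities. Centre enters every imputation model as a fixed effect;
#' age and vaginal-bleeding category are used as auxiliary predictors when
#' present. Chains are burned in for `maxit` iterations.
#'
#' Observed cells are never modified: completed datasets differ from the
#' input only in originally-missing cells. The same `seed` always yields
#' the identical imputation set.
#'
#' @param data Cohort after [apply_missingness_rules()]; must contain
#'   `hcg0` and `outcome` (with `"LTFU"` marking the lost-to-follow-up
#'   records whose outcome is to be imputed).
#' @param m Number of imputations. The study-scale default is 100;
#'   desk-scale analyses use 5.
#' @param seed Integer seed.
#' @param maxit Burn-in iterations per chain.
#' @param donors PMM donor pool size.
#' @return A `pul_imputation` object: list with `m`, `completed` (list of
#'   tibbles), `seed` and `method_log`.
#' @export
impute_chained <- function(data, m = 100, seed = 1L, maxit = 20, donors = 5) {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  vars <- list(
    prog0 = list(kind = "lognum"),
    hcg48 = list(kind = "lognum"),
    outcome = list(kind = "cat")
  )
  miss <- list(
    prog0 = if ("prog0" %in% names(data)) is.na(data$prog0) else rep(FALSE, n),
    hcg48 = if ("hcg48" %in% names(data)) is.na(data$hcg48) else rep(FALSE, n),
    outcome = is.na(data$outcome) | data$outcome == "LTFU"
  )
  for (v in names(miss)) {
    if (mean(miss[[v]]) > 0.95) {
      abort(sprintf("Variable '%s' is >95%% missing; imputation aborted.", v),
            class = "pultriage_imputation_error")
    }
  }
  method_log <- list(
    prog0 = "pmm on log(prog0), 5 donors",
    hcg48 = "pmm on log(hcg48), 5 donors",
    outcome = "multinomial logistic draw (FPUL/IUP/EP)",
    predictors = "log(hcg0), other imputed variables, centre, age, bleeding where present",
    maxit = maxit, m = m, seed = seed
  )
  if (!any(unlist(miss))) {
    method_log$note <- "no missing cells; completed datasets equal the input"
    return(structure(list(m = m, completed = rep(list(data), m),
                          seed = seed, method_log = method_log),
                     class = "pul_imputation"))
  }

  # working frame of transformed predictors
  base_W <- data.frame(log_hcg0 = log(data$hcg0))
  if ("centre_id" %in% names(data) &&
      length(unique(data$centre_id)) > 1L) {
    base_W$centre <- factor(data$centre_id)
  }
  if ("age" %in% names(data)) {
    a <- data$age
    a[is.na(a)] <- median(a, na.rm = TRUE)
    base_W$age <- a
  }
  if ("bleeding" %in% names(data)) {
    b <- as.character(data$bleeding)
    mode_b <- names(sort(table(b), decreasing = TRUE))[1]
    b[is.na(b)] <- mode_b
    base_W$bleeding <- factor(b)
  }

  draw_beta <- function(fit) {
    bhat <- coef(fit)
    V <- stats::vcov(fit)
    L <- chol(V + diag(1e-10, nrow(V)))
    drop(bhat + t(L) %*% rnorm(length(bhat)))
  }
  pmm_impute <- function(y, ry, X) {
    # y on model scale; ry TRUE where observed; X numeric design matrix
    fit <- stats::lm.fit(X[ry, , drop = FALSE], y[ry])
    keep <- !is.na(fit$coefficients)
    Xk <- X[, keep, drop = FALSE]
    lmf <- stats::lm(y[ry] ~ Xk[ry, , drop = FALSE] - 1)
    bhat <- coef(lmf)
    bstar <- draw_beta(lmf)
    yhat_obs <- drop(Xk[ry, , drop = FALSE] %*% bhat)
    yhat_mis <- drop(Xk[!ry, , drop = FALSE] %*% bstar)
    yobs <- y[ry]
    vapply(yhat_mis, function(ym) {
      d <- abs(yhat_obs - ym)
      pool <- order(d)[seq_len(min(donors, length(d)))]
      yobs[sample(pool, 1L)]
    }, numeric(1))
  }

  one_imputation <- function(j) {
    set.seed(seed + j)
    cur <- data
    # initialise missing cells by draws from the observed margins
    for (v in c("prog0", "hcg48")) {
      if (any(miss[[v]])) {
        obs <- cur[[v]][!miss[[v]]]
        cur[[v]][miss[[v]]] <- sample(obs, sum(miss[[v]]), replace = TRUE)
      }
    }
    out_cur <- factor(ifelse(miss$outcome, NA, as.character(data$outcome)),
                      levels = .pul_outcomes)
    if (any(miss$outcome)) {
      obs <- out_cur[!miss$outcome]
      out_cur[miss$outcome] <- sample(obs, sum(miss$outcome), replace = TRUE)
    }
    for (it in seq_len(maxit)) {
      W <- base_W
      W$log_prog0 <- if ("prog0" %in% names(cur)) log(pmax(cur$prog0, 1e-6))
                     else NULL
      W$log_hcg48 <- log(cur$hcg48)
      W$outcome <- out_cur
      if (any(miss$prog0)) {
        X <- stats::model.matrix(~ ., W[setdiff(names(W), "log_prog0")])
        cur$prog0 <- exp_impute(cur$prog0, log(pmax(cur$prog0, 1e-6)),
                                !miss$prog0, X, pmm_impute)
        W$log_prog0 <- log(pmax(cur$prog0, 1e-6))
      }
      if (any(miss$hcg48)) {
        X <- stats::model.matrix(~ ., W[setdiff(names(W), "log_hcg48")])
        cur$hcg48 <- exp_impute(cur$hcg48, log(cur$hcg48), !miss$hcg48,
                                X, pmm_impute)
        W$log_hcg48 <- log(cur$hcg48)
      }
      if (any(miss$outcome)) {
        Wo <- W[setdiff(names(W), "outcome")]
        Wo$.y <- out_cur
        fit <- nnet::multinom(.y ~ ., data = Wo[!miss$outcome, , drop = FALSE],
                              trace = FALSE, maxit = 200)
        pr <- predict(fit, newdata = Wo[miss$outcome, , drop = FALSE],
                      type = "probs")
        pr <- matrix(pr, ncol = 3,
                     dimnames = list(NULL, fit$lev))
        draws <- apply(pr, 1, function(p) sample(fit$lev, 1L, prob = p))
        out_cur[miss$outcome] <- factor(draws, levels = .pul_outcomes)
      }
    }
    cur$outcome <- as.character(out_cur)
    if ("hcg_ratio" %in% names(cur)) {
      cur$hcg_ratio <- compute_hcg_ratio(cur$hcg0, cur$hcg48)
    }
    cur
  }
  completed <- lapply(seq_len(m), one_imputation)
  structure(list(m = m, completed = completed, seed = seed,
                 method_log = method_log),
            class = "pul_imputation")
}

# impute on the log scale; observed entries pass through untouched
exp_impute <- function(y_nat, ylog, ry, X, pmm) {
  y_nat[!ry] <- exp(pmm(ylog, ry, X))
  y_nat
}

#' @export
print.pul_imputation <- function(x, ...) {
  cat("<pul_imputation> m =", x$m, "completed datasets, seed", x$seed, "\n")
  cat("  methods:", x$method_log$prog0, "|", x$method_log$outcome, "\n")
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines one scalar estimate per completed dataset into a single
#' estimate with a variance that accounts for both within- and
#' between-imputation uncertainty: total variance equals the mean
#' within-imputation variance plus `(1 + 1/m)` times the between-imputation
#' variance. Confidence intervals use the standard multiple-imputation
#' t reference distribution.
#'
#' @param estimates One estimate per imputation.
#' @param variances Squared standard errors, one per imputation.
#' @return A one-row tibble: `estimate`, `within`, `between`, `total_var`,
#'   `se`, `df`, `lower`, `upper`, `m`.
#' @examples
#' rubin_pool(c(1, 3), c(1, 1))
#' @export
rubin_pool <- function(estimates, variances) {
  stopifnot(length(estimates) == length(variances))
  m <- length(estimates)
  if (m == 1L) {
    warn("Single imputation: no between-imputation variance available.")
    se <- sqrt(variances)
    return(tibble::tibble(estimate = estimates, within = variances,
                          between = 0, total_var = variances, se = se,
                          df = Inf,
                          lower = estimates - qnorm(0.975) * se,
                          upper = estimates + qnorm(0.975) * se, m = 1L))
  }
  qbar <- mean(estimates)
  ubar <- mean(variances)
  b <- var(estimates)
  total <- ubar + (1 + 1 / m) * b
  se <- sqrt(total)
  df <- if (b > 0) (m - 1) * (1 + ubar / ((1 + 1 / m) * b))^2 else Inf
  tcrit <- if (is.finite(df)) qt(0.975, df) else qnorm(0.975)
  tibble::tibble(estimate = qbar, within = ubar, between = b,
                 total_var = total, se = se, df = df,
                 lower = qbar - tcrit * se, upper = qbar + tcrit * se, m = m)
}
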