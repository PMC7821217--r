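#' Default configuration for the synthetic PUL cohort generator
#'
#' Encodes the statistical structure the validation pipeline assumes a
#' multicentre PUL cohort to have: an outcome mix of roughly 51% failing
#' PUL, 36% intrauterine and 13% ectopic pregnancy among followed-up
#' women; lognormal biomarkers within outcome class (presenting hCG with a
#' wide spread around a median near 500 IU/l; hCG ratio typically below
#' 0.87 for FPUL, above 1.66 for IUP and plateauing near 1 for EP;
#' progesterone low for FPUL and high for IUP); eight centres of unequal
#' size; and the protocol-driven missingness pattern — no second sample
#' for most women discharged at Step 1, sporadic non-attendance elsewhere,
#' off-schedule second samples, unmeasured or supplemented progesterone,
#' and loss to follow-up that skews toward falling hCG. Under the default
#' configuration roughly 29% of second hCG values end up missing after the
#' two-day rule and about 10% of women are lost to follow-up.
#'
#' Location/scale values are moment-style approximations chosen to land
#' the generated medians and missingness rates in the ranges above; they
#' are a test-bed emulation, not estimates from any patient data.
#'
#' @param n Cohort size.
#' @param seed Integer seed.
#' @return A `pul_cohort_config` list; override elements before passing to
#'   [generate_cohort()].
#' @export
cohort_config <- function(n = 2899, seed = 20260101) {
  structure(list(
    n = n,
    seed = seed,
    centre_props = c(centre_1 = 0.22, centre_2 = 0.18, centre_3 = 0.15,
                     centre_4 = 0.14, centre_5 = 0.10, centre_6 = 0.08,
                     centre_7 = 0.07, centre_8 = 0.06),
    # softmax tilt of the EP prevalence per centre (log-odds shifts)
    centre_ep_tilt = c(0.15, -0.1, 0.05, -0.05, 0.1, -0.15, 0, -0.4),
    prevalences = c(FPUL = 1338 / 2602, IUP = 930 / 2602, EP = 334 / 2602),
    biomarkers = list(
      FPUL = list(hcg0 = c(meanlog = log(450), sdlog = 1.50),
                  ratio = c(meanlog = log(0.50), sdlog = 0.50),
                  prog0 = c(meanlog = 1.50, sdlog = 1.20)),
      IUP  = list(hcg0 = c(meanlog = log(600), sdlog = 1.40),
                  ratio = c(meanlog = log(2.10), sdlog = 0.30),
                  prog0 = c(meanlog = 3.60, sdlog = 0.60)),
      EP   = list(hcg0 = c(meanlog = log(550), sdlog = 1.30),
                  ratio = c(meanlog = 0.00, sdlog = 0.45),
                  prog0 = c(meanlog = 2.80, sdlog = 0.80))
    ),
    cor_hcg_prog = 0.2,
    age = c(mean = 32, sd = 6, min = 14, max = 50),
    bleeding_probs = c(none = 0.25, minimal = 0.28, moderate = 0.22,
                       soaked = 0.125, clots = 0.125),
    prog_supplement_rate = 0.02,
    missingness = list(
      prog0_rate = 0.06,        # progesterone simply not measured
      step1_compliance = 0.25,  # P(second sample | prog0 <= 2)
      hcg48_mar_rate = 0.10,    # base non-attendance among the rest
      hcg48_mar_bleeding = 0.10,
      ltfu_rate = 0.102,
      ltfu_beta_logratio = -0.4,
      ltfu_beta_bleeding = 0.10,
      interval_probs = c(`1` = 0.045, `2` = 0.857, `3` = 0.060, `4` = 0.038)
    )
  ), class = "pul_cohort_config")
}

validate_cohort_config <- function(config) {
  if (abs(sum(config$prevalences) - 1) > 1e-9) {
    abort("Outcome prevalences must sum to 1.",
          class = "pultriage_config_error")
  }
  if (abs(sum(config$centre_props) - 1) > 1e-9) {
    abort("Centre proportions must sum to 1.",
          class = "pultriage_config_error")
  }
  sc <- unlist(lapply(config$biomarkers, function(b)
    c(b$hcg0["sdlog"], b$ratio["sdlog"], b$prog0["sdlog"])))
  if (any(sc <= 0)) {
    abort("Biomarker scale parameters must be positive.",
          class = "pultriage_config_error")
  }
  rates <- unlist(config$missingness[c("prog0_rate", "step1_compliance",
                                       "hcg48_mar_rate", "ltfu_rate")])
  if (any(rates < 0 | rates > 1)) {
    abort("Missingness rates must lie in [0, 1].",
          class = "pultriage_config_error")
  }
  invisible(config)
}

centre_sizes_from_props <- function(n, props) {
  raw <- n * props
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    bump <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[bump] <- sizes[bump] + 1
  }
  sizes
}

#' Generate a complete multi-centre synthetic PUL cohort
#'
#' Draws a cohort with fully observed measurements and known (latent) true
#' outcomes. Each record gets a centre, a final outcome drawn from the
#' configured prevalences (with mild centre-specific tilts of the EP
#' log-odds), and outcome-conditional lognormal biomarkers: presenting
#' hCG, the 48-hour ratio (the second hCG is derived as `hcg0 * ratio`),
#' and presenting progesterone correlated with hCG on the log scale.
#' Every record starts with a two-day sampling interval and no missing
#' values; pass the result through [inject_missingness()] to emulate a
#' realistically incomplete cohort.
#'
#' @param config A [cohort_config()].
#' @param seed Overrides `config$seed` when given.
#' @return A cohort tibble: `record_id`, `centre_id`, `age`, `bleeding`,
#'   `prog_supplement`, `prog0`, `hcg0`, `hcg48`, `hcg_ratio`,
#'   `interval_days`, `outcome` and `true_outcome` (identical here;
#'   `outcome` becomes `"LTFU"` where follow-up is lost).
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 200))
#' dplyr::count(cohort, outcome)
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  validate_cohort_config(config)
  set.seed(seed %||% config$seed)
  n <- config$n
  sizes <- centre_sizes_from_props(n, config$centre_props)
  centre <- rep(names(config$centre_props), sizes)

  # outcome with centre-tilted EP log-odds
  base <- config$prevalences
  tilt <- rep(config$centre_ep_tilt, sizes)
  l_ep <- qlogis(base["EP"]) + tilt
  p_ep <- plogis(l_ep)
  rest <- (1 - p_ep) / (base["FPUL"] + base["IUP"])
  pmat <- cbind(FPUL = base["FPUL"] * rest, IUP = base["IUP"] * rest,
                EP = p_ep)
  u <- runif(n)
  cum1 <- pmat[, 1]; cum2 <- pmat[, 1] + pmat[, 2]
  outcome <- ifelse(u < cum1, "FPUL", ifelse(u < cum2, "IUP", "EP"))

  hcg0 <- prog0 <- ratio <- numeric(n)
  for (cls in .pul_outcomes) {
    idx <- outcome == cls
    m <- sum(idx)
    if (m == 0) next
    b <- config$biomarkers[[cls]]
    z1 <- rnorm(m); z2 <- rnorm(m)
    rho <- config$cor_hcg_prog
    hcg0[idx] <- exp(b$hcg0["meanlog"] + b$hcg0["sdlog"] * z1)
    prog0[idx] <- exp(b$prog0["meanlog"] +
                        b$prog0["sdlog"] * (rho * z1 + sqrt(1 - rho^2) * z2))
    ratio[idx] <- exp(rnorm(m, b$ratio["meanlog"], b$ratio["sdlog"]))
  }
  age <- round(pmin(pmax(rnorm(n, config$age["mean"], config$age["sd"]),
                         config$age["min"]), config$age["max"]))
  bleeding <- sample(names(config$bleeding_probs), n, replace = TRUE,
                     prob = config$bleeding_probs)
  tibble::tibble(
    record_id = sprintf("r%05d", seq_len(n)),
    centre_id = centre,
    age = age,
    bleeding = bleeding,
    prog_supplement = runif(n) < config$prog_supplement_rate,
    prog0 = prog0,
    hcg0 = hcg0,
    hcg48 = hcg0 * ratio,
    hcg_ratio = ratio,
    interval_days = 2L,
    outcome = outcome,
    true_outcome = outcome
  )
}

#' Inject protocol-driven and random missingness into a cohort
#'
#' Emulates how an implemented two-step triage protocol generates missing
#' data:
#'
#' * records with presenting progesterone at or below 2 nmol/l are
#'   discharged at Step 1, so only a minority (`step1_compliance`) still
#'   get a second hCG sample;
#' * among the remainder, a fraction miss the second sample at random
#'   given presentation characteristics (bleeding category);
#' * second samples that are taken land on a 1-4 day interval, and only
#'   2-day samples survive the primary analysis rule;
#' * progesterone is unmeasured at a configured rate (supplement users
#'   keep their recorded but unreliable value — [apply_missingness_rules()]
#'   blanks it);
#' * the final outcome is lost to follow-up at a configured rate with a
#'   missing-at-random tilt toward falling hCG (low ratio) and heavier
#'   bleeding; `true_outcome` is retained for oracle checks.
#'
#' Non-targeted fields are never altered. Achieved rates are attached as
#' the `achieved_rates` attribute.
#'
#' @param cohort Output of [generate_cohort()].
#' @param config The same [cohort_config()].
#' @param seed Overrides `config$seed + 1` when given.
#' @return The cohort tibble with missingness applied.
#' @export
inject_missingness <- function(cohort, config = cohort_config(), seed = NULL) {
  validate_cohort_config(config)
  set.seed(seed %||% (config$seed + 1L))
  mc <- config$missingness
  n <- nrow(cohort)
  out <- cohort

  bleed_score <- match(out$bleeding, names(config$bleeding_probs)) - 3

  # second-sample attendance
  low_prog <- out$prog0 <= 2
  p_noshow <- ifelse(low_prog, 1 - mc$step1_compliance,
                     plogis(qlogis(mc$hcg48_mar_rate) +
                              mc$hcg48_mar_bleeding * bleed_score))
  noshow <- runif(n) < p_noshow
  out$hcg48[noshow] <- NA_real_
  out$hcg_ratio[noshow] <- NA_real_
  out$interval_days[noshow] <- NA_integer_
  sampled <- !noshow
  out$interval_days[sampled] <- as.integer(sample(
    names(mc$interval_probs), sum(sampled), replace = TRUE,
    prob = mc$interval_probs))

  # unmeasured progesterone (beyond supplement users)
  prog_missing <- runif(n) < mc$prog0_rate
  out$prog0[prog_missing] <- NA_real_

  # loss to follow-up, MAR given ratio and bleeding
  lr <- log(cohort$hcg_ratio)
  lr_c <- lr - mean(lr)
  p_ltfu <- plogis(qlogis(mc$ltfu_rate) + mc$ltfu_beta_logratio * lr_c +
                     mc$ltfu_beta_bleeding * bleed_score)
  ltfu <- runif(n) < p_ltfu
  out$outcome[ltfu] <- "LTFU"

  attr(out, "achieved_rates") <- tibble::tibble(
    quantity = c("hcg48_absent", "hcg48_missing_after_2day_rule",
                 "prog0_missing", "ltfu"),
    rate = c(mean(noshow),
             mean(noshow | is.na(out$interval_days) | out$interval_days != 2L),
             mean(prog_missing | out$prog_supplement),
             mean(ltfu))
  )
  out
}

#' Simulate a realistic incomplete multi-centre PUL cohort
#'
#' Convenience wrapper: [generate_cohort()] followed by
#' [inject_missingness()].
#'
#' @param n Cohort size.
#' @param config Optional [cohort_config()]; `n` and `seed` override its
#'   entries.
#' @param seed Integer seed.
#' @return A cohort tibble, see [generate_cohort()].
#' @examples
#' cohort <- simulate_pul_cohort(500, seed = 7)
#' attr(cohort, "achieved_rates")
#' @export
simulate_pul_cohort <- function(n = 2899, config = NULL, seed = 1L) {
  config <- config %||% cohort_config(n = n, seed = seed)
  config$n <- n
  config$seed <- seed
  cohort <- generate_cohort(config)
  inject_missingness(cohort, config)
}

#' Generate a cohort whose outcomes follow a model's own risks
#'
#' Draws biomarkers from the configured mixture, evaluates the given risk
#' model, and samples each record's outcome from the model's estimated
#' probabilities. By construction the model is perfectly calibrated on
#' such a cohort and no other model can beat its discrimination (beyond
#' simulation error), which makes these cohorts the oracle inputs for the
#' calibration and discrimination self-consistency checks.
#'
#' @param model Model name or `pul_model` passed to [predict_pul_risks()].
#' @param config A [cohort_config()] (biomarker mixture and centres).
#' @param seed Integer seed.
#' @param pul_cfg A [pul_config()] with the coefficients.
#' @return A complete cohort tibble with the model's risk columns and the
#'   sampled `outcome`.
#' @export
generate_from_model <- function(model = "M6P", config = cohort_config(),
                                seed = NULL, pul_cfg = pul_config()) {
  cohort <- generate_cohort(config, seed = seed)
  cohort$outcome <- NULL
  cohort$true_outcome <- NULL
  scored <- predict_pul_risks(cohort, model, pul_cfg)
  u <- runif(nrow(scored))
  scored$outcome <- ifelse(u < scored$p_fpul, "FPUL",
                           ifelse(u < scored$p_fpul + scored$p_iup,
                                  "IUP", "EP"))
  scored
}
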