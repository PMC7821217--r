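#' Load a PUL model coefficient configuration
#'
#' The multinomial risk models (M4, M6P, M6NP) are defined entirely by
#' configuration: an ordered basis of term descriptors plus one coefficient
#' vector per non-reference outcome (reference category FPUL). Keeping the
#' coefficients as data means a transcription error is fixable without
#' touching code, and alternative model versions can be evaluated by
#' swapping files.
#'
#' The configuration file also carries the fixed Step-1 risk triple of the
#' two-step triage strategy, the progesterone cut-off, the default high-risk
#' threshold for the estimated risk of ectopic pregnancy (EP), and the hCG
#' ratio cut-off band. Units are declared in the file and must be IU/l for
#' hCG and nmol/l for progesterone; a file declaring other units is
#' rejected rather than converted.
#'
#' The configuration shipped with the package
#' (`pul_models_synthetic.yaml`) carries *synthetic* coefficient values:
#' the originally published coefficient vectors are not redistributable
#' here, so the shipped vectors were estimated once on large
#' simulated development cohorts and are stand-ins with the same structure
#' and qualitatively similar behaviour, not the published models. The fixed
#' Step-1 triple (0.961, 0.022, 0.017), thresholds and cut-offs are the
#' published operating points.
#'
#' @param path Path to a YAML configuration. Defaults to the synthetic
#'   configuration shipped in `inst/extdata/`.
#' @return A `pul_config` list with elements `models` (named list of
#'   `pul_model` objects), `step1` (progesterone cut-off and fixed risk
#'   triple), `threshold` (EP high-risk threshold), `ratio_cutoffs`
#'   (lower/upper band ends) and `units`.
#' @examples
#' cfg <- pul_config()
#' names(cfg$models)
#' cfg$step1$risks
#' @export
pul_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pul_models_synthetic.yaml",
                        package = "pultriage", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  validate_pul_config(raw)
}

validate_pul_config <- function(raw) {
  units <- raw$units
  if (is.null(units) || !identical(units$hcg, "IU/l") ||
      !identical(units$progesterone, "nmol/l")) {
    abort(paste0(
      "Model configuration must declare units hcg: 'IU/l' and ",
      "progesterone: 'nmol/l'; no unit conversion is performed."
    ), class = "pultriage_config_error")
  }
  s1 <- raw$step1
  risks <- unlist(s1$risks[c("fpul", "iup", "ep")])
  if (length(risks) != 3L || abs(sum(risks) - 1) > 1e-9) {
    abort("step1 risks must be a (fpul, iup, ep) triple summing to 1.",
          class = "pultriage_config_error")
  }
  models <- lapply(names(raw$models), function(nm) {
    m <- raw$models[[nm]]
    new_pul_model(nm, m$basis, as.numeric(m$beta_iup), as.numeric(m$beta_ep))
  })
  names(models) <- names(raw$models)
  structure(list(
    models = models,
    step1 = list(
      progesterone_cutoff = as.numeric(s1$progesterone_cutoff),
      risks = c(p_fpul = unname(risks[1]), p_iup = unname(risks[2]),
                p_ep = unname(risks[3]))
    ),
    threshold = as.numeric(raw$thresholds$ep_high_risk),
    ratio_cutoffs = c(lower = as.numeric(raw$ratio_cutoffs$lower),
                      upper = as.numeric(raw$ratio_cutoffs$upper)),
    units = units,
    provenance = raw$provenance %||% "unspecified"
  ), class = "pul_config")
}

# Recognised basis terms. Each maps a record to one column of the design
# matrix; the coefficient engine is generic over this list.
.pul_terms <- list(
  intercept    = function(d) rep(1, nrow(d)),
  log_hcg0     = function(d) log(d$hcg0),
  log_ratio    = function(d) log(d$hcg_ratio),
  sq_log_ratio = function(d) log(d$hcg_ratio)^2,
  log_prog0    = function(d) log(d$prog0),
  prog0        = function(d) d$prog0
)

.term_requires <- function(term) {
  switch(term,
    log_hcg0 = "hcg0",
    log_ratio = , sq_log_ratio = "hcg_ratio",
    log_prog0 = , prog0 = "prog0",
    character(0)
  )
}

new_pul_model <- function(name, basis, beta_iup, beta_ep) {
  basis <- as.character(basis)
  unknown <- setdiff(basis, names(.pul_terms))
  if (length(unknown) > 0) {
    abort(paste0("Unknown basis term(s): ", paste(unknown, collapse = ", ")),
          class = "pultriage_config_error")
  }
  if (length(beta_iup) != length(basis) || length(beta_ep) != length(basis)) {
    abort(sprintf("Model %s: coefficient vectors must match basis length %d.",
                  name, length(basis)), class = "pultriage_config_error")
  }
  uses_prog <- any(vapply(basis, function(t) "prog0" %in% .term_requires(t),
                          logical(1)))
  if (name %in% c("M4", "M6NP") && uses_prog) {
    abort(sprintf("Model %s must not contain a progesterone term.", name),
          class = "pultriage_config_error")
  }
  if (name == "M6P" && !uses_prog) {
    abort("Model M6P must contain at least one progesterone term.",
          class = "pultriage_config_error")
  }
  structure(list(name = name, basis = basis,
                 beta_iup = beta_iup, beta_ep = beta_ep,
                 reference = "FPUL"),
            class = "pul_model")
}

#' @export
print.pul_model <- function(x, ...) {
  cat("<pul_model>", x$name, "\n")
  cat("  reference category:", x$reference, "\n")
  tab <- data.frame(term = x$basis, beta_iup = x$beta_iup,
                    beta_ep = x$beta_ep)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
print.pul_config <- function(x, ...) {
  cat("<pul_config> models:", paste(names(x$models), collapse = ", "), "\n")
  cat("  step1: progesterone <=", x$step1$progesterone_cutoff,
      "nmol/l ->", sprintf("(%.3f, %.3f, %.3f)", x$step1$risks[1],
                           x$step1$risks[2], x$step1$risks[3]), "\n")
  cat("  EP high-risk threshold:", x$threshold, "\n")
  cat("  hCG ratio band: [", x$ratio_cutoffs["lower"], ",",
      x$ratio_cutoffs["upper"], "]\n")
  cat("  coefficient provenance:", x$provenance, "\n")
  invisible(x)
}

# required record fields for a model, beyond hcg0
model_required_fields <- function(model) {
  unique(unlist(lapply(model$basis, .term_requires)))
}
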