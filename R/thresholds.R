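#' Glucose concentration giving a target fractional inhibition of ACTH
#'
#' Closed-form inversion of the sigmoidal Imax model:
#' `G = IC50_A(gir) * (r / (1 - r))^(1/gamma_A)` with
#' `r = target / Imax_A`, where `IC50_A(gir)` carries the exponential GIR
#' covariate effect. Targets at or above `Imax_A` are unattainable (`NA`).
#'
#' @param target fractional inhibition in (0, 1).
#' @param gir individual GIR_20-60min (mg/kg-LBM/min), vectorized.
#' @param p a [hormone_params()] set.
#' @return Glucose (mmol/L), or `NA` where unattainable.
#' @examples
#' glucose_for_acth_inhibition(0.9, gir = 12.0)  # ~3.1 (insulin-sensitive)
#' glucose_for_acth_inhibition(0.9, gir = 4.5)   # ~3.5 (insulin-resistant)
#' @export
glucose_for_acth_inhibition <- function(target, gir, p = hormone_params()) {
  if (target <= 0 || target >= 1) stop("'target' must lie in (0, 1)")
  r <- target / p$imax_a
  if (r >= 1) return(rep(NA_real_, length(gir)))
  ic50 <- covariate_ic50(p$ic50_a, p$theta_gir_a, gir, p$gir_ref)
  ic50 * (r / (1 - r))^(1 / p$gamma_a)
}

#' Glucose at which the ACTH response is half-maximal
#'
#' Secretion halfway between its fully suppressed and unsuppressed
#' asymptotes occurs exactly at `Ge = IC50_A(gir)`; the 50%-response
#' glucose is therefore the covariate-adjusted potency itself.
#'
#' @inheritParams glucose_for_acth_inhibition
#' @return Glucose (mmol/L).
#' @examples
#' glucose_for_acth_half_response(12.0)  # ~2.7
#' glucose_for_acth_half_response(4.5)   # ~3.0
#' @export
glucose_for_acth_half_response <- function(gir, p = hormone_params()) {
  covariate_ic50(p$ic50_a, p$theta_gir_a, gir, p$gir_ref)
}

#' Insulin concentration giving a target fractional inhibition of glucagon
#'
#' Solves `frac * H_G(g) + (1 - frac) * I / (I + IC50_I(gir)) = target`
#' for `I` at a given glucose level. The insulin share required beyond the
#' glucose contribution is `need = target - frac * H_G(g)`; the target is
#' unattainable (`NA`) when `need >= 1 - frac`, and 0 is returned when the
#' glucose contribution alone already reaches the target.
#'
#' @param target fractional inhibition in (0, 1).
#' @param g plasma glucose (mmol/L), `>= 0`.
#' @param gir individual GIR_20-60min (mg/kg-LBM/min), vectorized.
#' @param p a [hormone_params()] set.
#' @return Insulin (uU/mL), `NA` where unattainable.
#' @examples
#' insulin_for_glucagon_inhibition(0.9, g = 5.0, gir = 8.13)  # ~17.9
#' insulin_for_glucagon_inhibition(0.9, g = 2.0, gir = 8.13)  # NA
#' @export
insulin_for_glucagon_inhibition <- function(target, g, gir,
                                            p = hormone_params()) {
  if (target <= 0 || target >= 1) stop("'target' must lie in (0, 1)")
  if (g < 0) stop("'g' must be non-negative")
  need <- target - p$frac * hill(g, p$ic50_g, p$gamma_g)
  cap <- 1 - p$frac
  ic50 <- covariate_ic50(p$ic50_i, p$theta_gir_i, gir, p$gir_ref)
  if (need >= cap) return(rep(NA_real_, length(gir)))
  if (need <= 0) return(rep(0, length(gir)))
  x <- need / cap
  ic50 * x / (1 - x)
}

#' Fasting suppression of glucagon and ACTH across a population
#'
#' Evaluates the glucagon inhibition (by fasting glucose and insulin) and
#' the ACTH inhibition (by fasting glucose; at steady state the delayed
#' glucose equals plasma glucose) for each realized individual, and
#' summarizes the population spread. Individuals with missing fasting
#' values are excluded (reported in attribute `excluded`).
#'
#' @param covariates covariate data.frame (e.g. [sample_covariates()]) with
#'   `gir`, `fasting_glucose`, `fasting_insulin`.
#' @param p a [hormone_params()] set.
#' @param bsv apply between-subject variability (log-normal draws).
#' @param seed integer seed for the BSV draws.
#' @return List: `individual` (per-subject suppression fractions) and
#'   `summary` (median and 5th/95th percentiles per hormone).
#' @examples
#' fs <- fasting_suppression(sample_covariates(50, seed = 1), seed = 2)
#' fs$summary
#' @export
fasting_suppression <- function(covariates, p = hormone_params(),
                                bsv = TRUE, seed = NULL) {
  old_rng <- save_rng(seed)
  on.exit(restore_rng(old_rng), add = TRUE)
  ok <- !(is.na(covariates$fasting_glucose) |
            is.na(covariates$fasting_insulin))
  excluded <- which(!ok)
  if (length(excluded))
    message(length(excluded),
            " individual(s) excluded for missing fasting values")
  cc <- covariates[ok, ]
  res <- data.frame(id = cc$id, glucagon = NA_real_, acth = NA_real_)
  for (i in seq_len(nrow(cc))) {
    eta <- if (bsv) setNames(rnorm(length(p$bsv)), names(p$bsv)) else NULL
    ind <- realize_individual(p, as.list(cc[i, ]), eta = eta, id = cc$id[i])
    res$glucagon[i] <- glucagon_inhibition(ind$fasting_glucose,
                                           ind$fasting_insulin, ind)
    res$acth[i] <- acth_inhibition(ind$fasting_glucose, ind)
  }
  qs <- function(x) quantile(x, c(0.05, 0.5, 0.95), names = FALSE)
  summary <- data.frame(hormone = c("glucagon", "acth"),
                        p5 = c(qs(res$glucagon)[1], qs(res$acth)[1]),
                        median = c(qs(res$glucagon)[2], qs(res$acth)[2]),
                        p95 = c(qs(res$glucagon)[3], qs(res$acth)[3]))
  out <- list(individual = res, summary = summary)
  attr(out, "excluded") <- excluded
  out
}
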