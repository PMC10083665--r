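#' Exponential covariate effect of insulin sensitivity on a potency
#'
#' `ic50_ref * exp(theta * (gir - gir_ref))`. With a negative slope the
#' potency parameter decreases (the hormone becomes easier to suppress) as
#' insulin sensitivity (GIR) increases. Identity at `gir = gir_ref`.
#'
#' @param ic50_ref potency at the reference GIR, `> 0`.
#' @param theta fractional change per mg/kg-LBM/min (e.g. -0.157 for the
#'   insulin potency on glucagon, -0.0155 for the glucose potency on ACTH).
#' @param gir individual GIR_20-60min (mg/kg-LBM/min), vectorized.
#' @param gir_ref reference GIR (default 8.13).
#' @return Adjusted potency, strictly positive.
#' @examples
#' covariate_ic50(5.51, -0.157, 10.8)  # 3.62
#' @export
covariate_ic50 <- function(ic50_ref, theta, gir, gir_ref = 8.13) {
  if (ic50_ref <= 0) stop("'ic50_ref' must be positive")
  ic50_ref * exp(theta * (gir - gir_ref))
}

#' Log-scale variance of a log-normal random effect from its CV
#'
#' For a log-normal parameter reported as a coefficient of variation (on
#' the fraction scale), the variance of the underlying normal deviate is
#' `log(1 + cv^2)`.
#'
#' @param cv coefficient of variation, fraction `>= 0` (vectorized).
#' @return Log-scale variance(s).
#' @examples
#' cv_to_variance(0.932)  # 0.6252
#' @export
cv_to_variance <- function(cv) {
  if (any(cv < 0)) stop("'cv' must be non-negative")
  log(1 + cv^2)
}

#' Fasting insulin-resistance index (HOMA-IR)
#'
#' `glucose * insulin / 22.5` with glucose in mmol/L and insulin in uU/mL.
#'
#' @param fasting_glucose mmol/L, `> 0`.
#' @param fasting_insulin uU/mL, `> 0`.
#' @return Dimensionless index (vectorized).
#' @examples
#' homa_ir(5.4, 17.5)  # 4.2
#' @export
homa_ir <- function(fasting_glucose, fasting_insulin) {
  if (any(fasting_glucose <= 0) || any(fasting_insulin <= 0))
    stop("fasting values must be positive")
  fasting_glucose * fasting_insulin / 22.5
}

#' Draw standard-normal random-effect deviates
#'
#' Between-subject deviates (`eta`) for every parameter with declared BSV
#' and between-occasion deviates (`kappa`) for every parameter with declared
#' BOV, reproducible given the seed.
#'
#' @param p a [hormone_params()] set (declares which parameters vary).
#' @param n number of subjects.
#' @param n_occ occasions per subject (a new `kappa` is drawn per occasion).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return List with matrix `eta` (`n` x BSV parameters), array `kappa`
#'   (`n` x `n_occ` x BOV parameters) and the `seed`.
#' @export
draw_random_effects <- function(p, n, n_occ = 1, seed = NULL) {
  old_rng <- save_rng(seed)
  on.exit(restore_rng(old_rng), add = TRUE)
  eta <- matrix(rnorm(n * length(p$bsv)), n, length(p$bsv),
                dimnames = list(NULL, names(p$bsv)))
  kappa <- array(rnorm(n * n_occ * length(p$bov)),
                 dim = c(n, n_occ, length(p$bov)),
                 dimnames = list(NULL, NULL, names(p$bov)))
  list(eta = eta, kappa = kappa, seed = seed)
}

#' Realize individual parameters from typicals, covariates and random effects
#'
#' Applies the exponential GIR covariate model to the insulin potency on
#' glucagon and the glucose potency on ACTH, then multiplies each parameter
#' with declared between-subject variability by `exp(omega * eta)` (and the
#' baselines additionally by `exp(omega_bov * kappa)`), where
#' `omega = sqrt(log(1 + CV^2))` (the log-normal parameterization; set
#' `cv_as_sd = TRUE` to use the CV directly as the log-scale SD instead).
#' All other parameters pass through unchanged. With all deviates zero and
#' `gir = gir_ref` the typical values are returned.
#'
#' @param p a [hormone_params()] set.
#' @param cov one covariate record: a list/one-row data.frame with at least
#'   `gir`, `fasting_glucose`, `fasting_insulin`.
#' @param eta named standard-normal deviates for BSV parameters (missing
#'   names default to 0; names without declared BSV are an error).
#' @param kappa named standard-normal deviates for BOV parameters.
#' @param id,occ identifiers stored on the result.
#' @param cv_as_sd interpret the declared CVs directly as log-scale SDs.
#' @return An `individual_params` list: the structural fields of `p` with
#'   `ic50_i` and `ic50_a` covariate-adjusted and random effects applied,
#'   plus `id`, `occ`, `gir`, `fasting_glucose` and `fasting_insulin`.
#' @examples
#' p <- hormone_params()
#' ind <- realize_individual(p, list(gir = 8.13, fasting_glucose = 5.3,
#'                                   fasting_insulin = 10.4))
#' ind$ic50_i  # typical value: zero draws at reference GIR
#' @export
realize_individual <- function(p, cov, eta = NULL, kappa = NULL,
                               id = 1L, occ = 1L, cv_as_sd = FALSE) {
  if (is.null(cov$gir) || is.null(cov$fasting_glucose) ||
      is.null(cov$fasting_insulin))
    stop("'cov' must provide gir, fasting_glucose and fasting_insulin")
  ind <- unclass(p)
  ind$ic50_i <- covariate_ic50(p$ic50_i, p$theta_gir_i, cov$gir, p$gir_ref)
  ind$ic50_a <- covariate_ic50(p$ic50_a, p$theta_gir_a, cov$gir, p$gir_ref)
  omega <- function(cv) if (cv_as_sd) cv else sqrt(cv_to_variance(cv))
  if (!is.null(eta)) {
    bad <- setdiff(names(eta), names(p$bsv))
    if (length(bad))
      stop("random effect on parameter(s) without declared BSV: ",
           paste(bad, collapse = ", "))
    for (nm in names(eta))
      ind[[nm]] <- ind[[nm]] * exp(omega(p$bsv[[nm]]) * eta[[nm]])
  }
  if (!is.null(kappa)) {
    bad <- setdiff(names(kappa), names(p$bov))
    if (length(bad))
      stop("occasion effect on parameter(s) without declared BOV: ",
           paste(bad, collapse = ", "))
    for (nm in names(kappa))
      ind[[nm]] <- ind[[nm]] * exp(omega(p$bov[[nm]]) * kappa[[nm]])
  }
  ind$id <- id
  ind$occ <- occ
  ind$gir <- cov$gir
  ind$fasting_glucose <- cov$fasting_glucose
  ind$fasting_insulin <- cov$fasting_insulin
  class(ind) <- c("individual_params", "list")
  ind
}

# Table 1 "All data" marginals used by the Gaussian-copula covariate sampler.
# Log-normal scale parameters are matched to the printed median and IQR
# (sigma = log(q75/q25) / (2 * 0.6745)); age, body fat and waist/hip are
# normal with the same IQR matching, truncated to plausible adult ranges.
.cov_marginals <- list(
  gir   = list(type = "lnorm", med = 8.13, sigma = log(10.8 / 4.46) / 1.349),
  bmi   = list(type = "lnorm", med = 37.3, sigma = log(41.3 / 26.5) / 1.349),
  fasting_glucose = list(type = "lnorm", med = 5.3,
                         sigma = log(5.6 / 4.8) / 1.349),
  fasting_insulin = list(type = "lnorm", med = 10.4,
                         sigma = log(22.0 / 5.50) / 1.349),
  age   = list(type = "norm", med = 40, sigma = 20 / 1.349,
               lo = 20, hi = 60),
  body_fat = list(type = "norm", med = 37.0, sigma = 19.5 / 1.349,
                  lo = 15, hi = 55),
  waist_hip = list(type = "norm", med = 0.90, sigma = 0.12 / 1.349,
                   lo = 0.7, hi = 1.1),
  hba1c = list(type = "lnorm", med = 34, sigma = log(34.8 / 32) / 1.349)
)

# Latent (Gaussian) correlation structure. The GIR-BMI and GIR-insulin
# entries are set so that the implied Spearman correlations reproduce the
# reported -56% (BMI vs GIR) and -69% (HOMA-IR vs GIR; HOMA-IR is derived
# from the fasting glucose and insulin marginals).
.cov_corr <- local({
  nm <- c("gir", "bmi", "fasting_glucose", "fasting_insulin", "age",
          "body_fat", "waist_hip", "hba1c")
  R <- diag(8); dimnames(R) <- list(nm, nm)
  set_r <- function(R, a, b, r) { R[a, b] <- r; R[b, a] <- r; R }
  R <- set_r(R, "gir", "bmi", -0.578)
  R <- set_r(R, "gir", "fasting_insulin", -0.72)
  R <- set_r(R, "gir", "fasting_glucose", -0.20)
  R <- set_r(R, "gir", "body_fat", -0.50)
  R <- set_r(R, "gir", "waist_hip", -0.30)
  R <- set_r(R, "gir", "age", -0.10)
  R <- set_r(R, "gir", "hba1c", -0.10)
  R <- set_r(R, "bmi", "fasting_insulin", 0.55)
  R <- set_r(R, "bmi", "fasting_glucose", 0.25)
  R <- set_r(R, "bmi", "body_fat", 0.80)
  R <- set_r(R, "bmi", "waist_hip", 0.50)
  R <- set_r(R, "bmi", "hba1c", 0.15)
  R <- set_r(R, "fasting_glucose", "fasting_insulin", 0.30)
  R <- set_r(R, "fasting_glucose", "hba1c", 0.35)
  R <- set_r(R, "fasting_glucose", "age", 0.10)
  R <- set_r(R, "fasting_glucose", "body_fat", 0.20)
  R <- set_r(R, "fasting_glucose", "waist_hip", 0.15)
  R <- set_r(R, "fasting_insulin", "body_fat", 0.50)
  R <- set_r(R, "fasting_insulin", "waist_hip", 0.35)
  R <- set_r(R, "fasting_insulin", "hba1c", 0.15)
  R <- set_r(R, "age", "body_fat", 0.10)
  R <- set_r(R, "age", "waist_hip", 0.25)
  R <- set_r(R, "age", "hba1c", 0.20)
  R <- set_r(R, "body_fat", "waist_hip", 0.30)
  R <- set_r(R, "body_fat", "hba1c", 0.10)
  R <- set_r(R, "waist_hip", "hba1c", 0.10)
  R
})

#' Sample a synthetic covariate population
#'
#' Gaussian-copula sample whose marginal medians and IQRs match the pooled
#' cohort summary (GIR median 8.13, IQR 4.46-10.8 mg/kg-LBM/min; BMI median
#' 37.3 kg/m2; fasting glucose 5.3 mmol/L; fasting insulin 10.4 uU/mL) and
#' whose rank correlations reproduce the reported BMI-GIR (-0.56) and
#' HOMA-IR-GIR (-0.69) associations. HOMA-IR is derived from the sampled
#' fasting glucose and insulin; sex is drawn with the cohort's 7/45
#' male/female ratio.
#'
#' @param n number of individuals, `>= 1`.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param overrides optional named list of covariate vectors (length `n` or
#'   1) that replace sampled columns, e.g. `list(gir = runif(n, 3, 14))`.
#' @param corr optional replacement latent correlation matrix (must be
#'   positive definite; checked).
#' @return A data.frame with one row per individual: `id`, `gir`, `bmi`,
#'   `homa_ir`, `sex`, `age`, `fasting_glucose`, `fasting_insulin`,
#'   `body_fat`, `waist_hip`, `hba1c`.
#' @examples
#' cc <- sample_covariates(6, seed = 1)
#' cc$gir
#' @export
sample_covariates <- function(n, seed = NULL, overrides = NULL, corr = NULL) {
  if (n < 1) stop("'n' must be >= 1")
  old_rng <- save_rng(seed)
  on.exit(restore_rng(old_rng), add = TRUE)
  R <- if (is.null(corr)) .cov_corr else corr
  L <- tryCatch(chol(R),
                error = function(e) stop("correlation matrix is not ",
                                         "positive definite", call. = FALSE))
  z <- matrix(rnorm(n * ncol(R)), n, ncol(R)) %*% L
  colnames(z) <- colnames(R)
  out <- data.frame(id = seq_len(n))
  for (nm in colnames(z)) {
    m <- .cov_marginals[[nm]]
    x <- if (m$type == "lnorm") m$med * exp(m$sigma * z[, nm])
         else m$med + m$sigma * z[, nm]
    if (!is.null(m$lo)) x <- pmin(pmax(x, m$lo), m$hi)
    out[[nm]] <- x
  }
  out$sex <- ifelse(runif(n) < 7 / 52, "M", "F")
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(out))
    if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
    for (nm in names(overrides)) out[[nm]] <- rep_len(overrides[[nm]], n)
  }
  out$homa_ir <- homa_ir(out$fasting_glucose, out$fasting_insulin)
  out[c("id", "gir", "bmi", "homa_ir", "sex", "age", "fasting_glucose",
        "fasting_insulin", "body_fat", "waist_hip", "hba1c")]
}

#' Impute missing covariates by the population median
#'
#' Numeric covariate columns have `NA`s replaced by the column median; the
#' affected columns are reported in an attribute `imputed`.
#'
#' @param cov a covariate data.frame.
#' @return The data.frame with imputations applied.
#' @export
impute_covariates <- function(cov) {
  done <- character()
  for (nm in names(cov)) {
    if (is.numeric(cov[[nm]]) && anyNA(cov[[nm]])) {
      cov[[nm]][is.na(cov[[nm]])] <- median(cov[[nm]], na.rm = TRUE)
      done <- c(done, nm)
    }
  }
  attr(cov, "imputed") <- done
  cov
}
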