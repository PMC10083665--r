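#' Population parameter set of the final clamp hormone model
#'
#' Container for all fixed effects, variability magnitudes and residual-error
#' terms of the glucagon, ACTH and cortisol sub-models. Defaults are the
#' typical values of the final population model; potencies `ic50_i` and
#' `ic50_a` are defined at the reference insulin sensitivity
#' `gir_ref = 8.13` mg/kg-LBM/min.
#'
#' Units: glucose mmol/L, insulin uU/mL (= mU/L), glucagon and ACTH pmol/L,
#' cortisol nmol/L, time minutes. Rates are 1/min. Between-subject (`bsv`)
#' and between-occasion (`bov`) variabilities are coefficients of variation
#' on the fraction scale; covariate slopes `theta_gir_*` are fractional
#' change per mg/kg-LBM/min.
#'
#' @param ... named replacements for any default element (unknown names are
#'   an error).
#'
#' @return An object of class `hormone_params`: a named list with elements
#' \describe{
#'   \item{gn0, kout_g}{glucagon baseline (pmol/L) and removal rate (1/min)}
#'   \item{frac}{fraction of glucagon inhibition attributed to glucose in
#'     the absence of insulin, in (0, 1]}
#'   \item{ic50_g, gamma_g}{glucose potency (mmol/L) and Hill factor on
#'     glucagon secretion}
#'   \item{ic50_i, theta_gir_i}{insulin potency on glucagon (uU/mL) at
#'     `gir_ref`, and the exponential GIR effect on it}
#'   \item{sigma_g}{proportional residual SD of glucagon (fraction)}
#'   \item{acth0, kout_a}{ACTH baseline (pmol/L) and removal rate (1/min)}
#'   \item{t_half}{half-life of the effect-compartment delay of glucose on
#'     ACTH (min)}
#'   \item{imax_a}{maximal fractional inhibition of ACTH secretion by
#'     glucose, in (0, 1]}
#'   \item{ic50_a, gamma_a, theta_gir_a}{glucose potency on ACTH (mmol/L) at
#'     `gir_ref`, Hill factor, and the exponential GIR effect}
#'   \item{sigma_a}{proportional residual SD of ACTH}
#'   \item{cort0, kout_c}{cortisol baseline (nmol/L) and removal rate (1/min)}
#'   \item{emax_c, ec50_c, gamma_c}{maximal ACTH effect on cortisol
#'     secretion (fold), ACTH potency (pmol/L) and Hill factor}
#'   \item{sigma_c}{proportional residual SD of cortisol}
#'   \item{f_add}{multiplicative residual-error inflation for BLQ records}
#'   \item{gir_ref}{reference GIR (mg/kg-LBM/min)}
#'   \item{k_pool}{extravascular transfer rate used by the pool model
#'     variants (1/min; exploration parameter, not part of the final model)}
#'   \item{bsv, bov}{named CV vectors of between-subject and
#'     between-occasion variability}
#' }
#'
#' @examples
#' p <- hormone_params()
#' p$ic50_a
#' hormone_params(ic50_g = 3.2)$ic50_g
#' @export
hormone_params <- function(...) {
  p <- list(
    # glucagon sub-model
    gn0 = 8.35, kout_g = 0.0612, frac = 0.750,
    ic50_g = 2.91, gamma_g = 5.26,
    ic50_i = 5.51, theta_gir_i = -0.157, sigma_g = 0.338,
    # ACTH sub-model
    acth0 = 2.94, kout_a = 0.0709, t_half = 8.68,
    imax_a = 0.941, ic50_a = 2.85, gamma_a = 20.9,
    theta_gir_a = -0.0155, sigma_a = 0.381,
    # cortisol sub-model
    cort0 = 207, kout_c = 0.0608, emax_c = 41.8,
    ec50_c = 6.90, gamma_c = 1.29, sigma_c = 0.293,
    # shared
    f_add = 2.01, gir_ref = 8.13, k_pool = 0.1,
    bsv = c(gn0 = 0.396, ic50_g = 0.234, ic50_i = 0.932,
            acth0 = 0.294, ic50_a = 0.0776, cort0 = 0.251),
    bov = c(gn0 = 0.200, acth0 = 0.081)
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_params(p)
  structure(p, class = "hormone_params")
}

validate_params <- function(p) {
  pos <- c("gn0", "kout_g", "ic50_g", "gamma_g", "ic50_i", "sigma_g",
           "acth0", "kout_a", "t_half", "ic50_a", "gamma_a", "sigma_a",
           "cort0", "kout_c", "emax_c", "ec50_c", "gamma_c", "sigma_c",
           "f_add", "gir_ref", "k_pool")
  for (nm in pos)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0)
      stop("parameter '", nm, "' must be a positive finite scalar")
  for (nm in c("frac", "imax_a"))
    if (p[[nm]] <= 0 || p[[nm]] > 1)
      stop("parameter '", nm, "' must lie in (0, 1]")
  if (any(p$bsv < 0) || any(p$bov < 0)) stop("CVs must be non-negative")
  invisible(p)
}

#' @export
print.hormone_params <- function(x, ...) {
  cat("<hormone_params> final-model typicals (reference GIR =", x$gir_ref,
      "mg/kg-LBM/min)\n")
  num <- vapply(x[!(names(x) %in% c("bsv", "bov"))], identity, numeric(1))
  print(num)
  cat("BSV (CV):\n"); print(x$bsv)
  cat("BOV (CV):\n"); print(x$bov)
  invisible(x)
}

#' Structural model variant
#'
#' Describes which structural alternative of the hormone sub-models to use.
#' The final published configuration is the default: turnover models for all
#' three hormones, an effect-compartment delay only on the glucose signal
#' driving ACTH, no Hill factor on the insulin term, additive combination of
#' the glucose and insulin inhibition of glucagon, and cortisol secretion
#' stimulated by a `1 + Emax*H(ACTH)` fold term.
#'
#' @param structure `"turnover"` (final), `"pool_synthesis"` (extravascular
#'   pool with effects on synthesis) or `"pool_secretion"` (effects on the
#'   first-order secretion from the pool).
#' @param delay logical; pass the glucose signal driving ACTH through the
#'   effect compartment (final: `TRUE`).
#' @param hill_on_insulin logical; put a Hill factor on the insulin term of
#'   the glucagon inhibition (final: `FALSE`; the exponent is then taken
#'   from `gamma_i` if present, default 1).
#' @param glucagon_form `"additive"` (final; `frac*H_G + (1-frac)*H_I`) or
#'   `"multiplicative"` (the rejected `1 - (1-H_G)(1-H_I)` alternative,
#'   which has no `frac` parameter).
#' @param cortisol_plus_one logical; `TRUE` (default) uses the
#'   `1 + Emax*H` stimulation fold, `FALSE` the pure `Emax*H` form.
#'
#' @return A classed list `model_variant`.
#' @examples
#' model_variant()                       # final model
#' model_variant(structure = "pool_secretion")
#' @export
model_variant <- function(structure = c("turnover", "pool_synthesis",
                                        "pool_secretion"),
                          delay = TRUE, hill_on_insulin = FALSE,
                          glucagon_form = c("additive", "multiplicative"),
                          cortisol_plus_one = TRUE) {
  structure(list(structure = match.arg(structure),
                 delay = isTRUE(delay),
                 hill_on_insulin = isTRUE(hill_on_insulin),
                 glucagon_form = match.arg(glucagon_form),
                 cortisol_plus_one = isTRUE(cortisol_plus_one)),
            class = "model_variant")
}
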