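#' Sigmoidal Hill function
#'
#' `s^gamma / (s^gamma + s50^gamma)`, evaluated in a numerically stable form
#' so that very steep factors (gamma > 20) neither overflow nor lose the
#' exact half-point `hill(s50, s50, gamma) = 0.5`.
#'
#' @param s driver concentration(s), `>= 0` (vectorized).
#' @param s50 potency (concentration giving half-maximal effect), `> 0`.
#' @param gamma Hill (sigmoidicity) factor, `> 0`.
#' @return Fraction(s) in `[0, 1)`; 0 at `s = 0`, monotone non-decreasing.
#' @examples
#' hill(2.85, 2.85, 20.9)  # exactly 0.5
#' hill(5.0, 2.85, 20.9)   # ~0.999992
#' @export
hill <- function(s, s50, gamma) {
  if (!is.numeric(s50) || length(s50) != 1L || !is.finite(s50) || s50 <= 0)
    stop("'s50' must be a positive finite scalar")
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0)
    stop("'gamma' must be a positive finite scalar")
  if (any(s < 0)) stop("'s' must be non-negative")
  # 1 / (1 + (s50/s)^gamma); log(0) = -Inf handles s = 0 without branching
  1 / (1 + exp(gamma * (log(s50) - log(s))))
}

#' Fractional inhibition of glucagon secretion by glucose and insulin
#'
#' The additive inhibition of the final glucagon sub-model:
#' `frac * H(G; IC50_G, gamma_G) + (1 - frac) * I / (I + IC50_I)`, where
#' `frac` is the fractional effect attributed to glucose in the absence of
#' insulin and the insulin term carries no Hill factor. The rejected
#' multiplicative alternative `1 - (1 - H_G)(1 - H_I)` is available through
#' the `variant` argument.
#'
#' @param g plasma glucose (mmol/L), `>= 0` (vectorized).
#' @param i plasma insulin (uU/mL), `>= 0` (vectorized).
#' @param p a [hormone_params()] set or the individual parameters returned by
#'   [realize_individual()]; `p$ic50_i` is used as-is, i.e. it must already
#'   be covariate-adjusted for a non-reference individual.
#' @param variant a [model_variant()].
#' @return Fraction(s) in `[0, 1)`, monotone in both drivers.
#' @examples
#' p <- hormone_params()
#' glucagon_inhibition(2.91, 0, p)        # frac/2 = 0.375
#' glucagon_inhibition(5.0, 5.51, p)      # glucose term + (1-frac)/2
#' @export
glucagon_inhibition <- function(g, i, p, variant = model_variant()) {
  if (any(g < 0) || any(i < 0)) stop("concentrations must be non-negative")
  hg <- hill(g, p$ic50_g, p$gamma_g)
  gamma_i <- if (variant$hill_on_insulin) {
    if (is.null(p$gamma_i)) 1 else p$gamma_i
  } else 1
  hi <- hill(i, p$ic50_i, gamma_i)
  if (variant$glucagon_form == "additive")
    p$frac * hg + (1 - p$frac) * hi
  else
    1 - (1 - hg) * (1 - hi)
}

#' Fractional inhibition of ACTH secretion by (delayed) glucose
#'
#' `Imax_A * H(Ge; IC50_A, gamma_A)`. The supremum is `Imax_A`, not 1: even
#' at high glucose a residual ACTH secretion remains.
#'
#' @param ge (effect-compartment-delayed) glucose (mmol/L), `>= 0`
#'   (vectorized).
#' @param p parameter set; `p$ic50_a` must be covariate-adjusted for a
#'   non-reference individual.
#' @return Fraction(s) in `[0, imax_a)`.
#' @examples
#' acth_inhibition(2.85, hormone_params())  # imax_a / 2 = 0.4705
#' @export
acth_inhibition <- function(ge, p) {
  if (any(ge < 0)) stop("'ge' must be non-negative")
  p$imax_a * hill(ge, p$ic50_a, p$gamma_a)
}

#' Fold-stimulation of cortisol secretion by ACTH
#'
#' `1 + Emax_C * H(ACTH; EC50_C, gamma_C)` (default), a stimulation factor
#' multiplying the zero-order cortisol secretion; equals 1 in the absence of
#' ACTH. With `cortisol_plus_one = FALSE` in the variant the pure
#' `Emax_C * H` form is returned instead.
#'
#' @param a plasma ACTH (pmol/L), `>= 0` (vectorized).
#' @param p parameter set.
#' @param variant a [model_variant()].
#' @return Fold-change(s) `>= 1` (default form).
#' @examples
#' cortisol_stimulation(6.90, hormone_params())  # 1 + Emax/2 = 21.9
#' @export
cortisol_stimulation <- function(a, p, variant = model_variant()) {
  if (any(a < 0)) stop("'a' must be non-negative")
  h <- hill(a, p$ec50_c, p$gamma_c)
  if (variant$cortisol_plus_one) 1 + p$emax_c * h else p$emax_c * h
}

#' Effect-compartment response to a step in the driving signal
#'
#' Closed-form solution of the first-order delay `dSe/dt =
#' (ln 2 / t_half) * (S - Se)` for a step input `S: s_from -> s_to` at
#' `t = 0` with `Se(0) = s_from`:
#' `s_from + (s_to - s_from) * (1 - 2^(-t / t_half))`.
#'
#' @param s_from,s_to signal level before and after the step.
#' @param t time since the step (min), `>= 0` (vectorized).
#' @param t_half half-life of the delay (min), `> 0`.
#' @return Delayed signal `Se(t)`.
#' @examples
#' effect_compartment_step(5, 2.7, 8.68, 8.68)  # 3.85, by definition
#' @export
effect_compartment_step <- function(s_from, s_to, t, t_half) {
  if (!is.numeric(t_half) || length(t_half) != 1L || !is.finite(t_half) ||
      t_half <= 0)
    stop("'t_half' must be a positive finite scalar")
  if (any(t < 0)) stop("'t' must be non-negative")
  s_from + (s_to - s_from) * (1 - 2^(-t / t_half))
}

#' Zero-order secretion rate from steady-state closure at baseline
#'
#' The secretion rate is not an independent parameter: it is derived from
#' the baseline concentration, the removal rate, and the fasting value of
#' the secretion modifier so that `dC/dt = 0` at `t = 0` under fasting
#' glucose/insulin. For an inhibited hormone (modifier is a fractional
#' inhibition `in [0, 1)`) this gives `c0 * kdeg / (1 - modifier0)`; for a
#' stimulated hormone (modifier is a fold `>= 1` or `> 0`) it gives
#' `c0 * kdeg / modifier0`.
#'
#' @param c0 baseline concentration, `> 0`.
#' @param kdeg first-order removal rate (1/min), `> 0`.
#' @param modifier0 fasting value of the inhibition fraction or the
#'   stimulation fold.
#' @param kind `"inhibition"` or `"stimulation"`.
#' @return Secretion rate (concentration units per min).
#' @examples
#' baseline_secretion(8.35, 0.0612, 0)           # c0 * kdeg
#' baseline_secretion(207, 0.0608, 11.44, "stimulation")
#' @export
baseline_secretion <- function(c0, kdeg, modifier0,
                               kind = c("inhibition", "stimulation")) {
  kind <- match.arg(kind)
  if (c0 <= 0 || kdeg <= 0) stop("'c0' and 'kdeg' must be positive")
  if (kind == "inhibition") {
    if (modifier0 < 0 || modifier0 >= 1)
      stop("degenerate baseline: fasting inhibition must lie in [0, 1)")
    c0 * kdeg / (1 - modifier0)
  } else {
    if (modifier0 <= 0)
      stop("degenerate baseline: fasting stimulation fold must be positive")
    c0 * kdeg / modifier0
  }
}
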