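# build deSolve parms: closures of the secretion rates at fasting conditions
make_rhs_parms <- function(p, forcing, variant) {
  funs <- forcing_funs(forcing)
  gf <- p$fasting_glucose
  insf <- p$fasting_insulin
  inh0_g <- glucagon_inhibition(gf, insf, p, variant)
  inh0_a <- acth_inhibition(gf, p)
  stim0 <- cortisol_stimulation(p$acth0, p, variant)
  list(p = p, variant = variant, gfun = funs$glucose, ifun = funs$insulin,
       inh0_g = inh0_g, inh0_a = inh0_a, stim0 = stim0,
       ksecr_g = baseline_secretion(p$gn0, p$kout_g, inh0_g),
       ksecr_a = baseline_secretion(p$acth0, p$kout_a, inh0_a),
       ksecr_c = baseline_secretion(p$cort0, p$kout_c, stim0, "stimulation"))
}

rhs_init_state <- function(p, parms) {
  v <- parms$variant
  if (v$structure == "turnover") {
    c(gn = p$gn0, ge = p$fasting_glucose, acth = p$acth0, cort = p$cort0)
  } else if (v$structure == "pool_synthesis") {
    c(gn = p$gn0, gn_ex = p$kout_g * p$gn0 / p$k_pool,
      ge = p$fasting_glucose,
      acth = p$acth0, acth_ex = p$kout_a * p$acth0 / p$k_pool,
      cort = p$cort0, cort_ex = p$kout_c * p$cort0 / p$k_pool)
  } else {
    c(gn = p$gn0,
      gn_ex = p$gn0 * p$kout_g / (p$k_pool * (1 - parms$inh0_g)),
      ge = p$fasting_glucose,
      acth = p$acth0,
      acth_ex = p$acth0 * p$kout_a / (p$k_pool * (1 - parms$inh0_a)),
      cort = p$cort0,
      cort_ex = p$cort0 * p$kout_c / (p$k_pool * parms$stim0))
  }
}

#' ODE right-hand side of the hormone sub-models
#'
#' deSolve-compatible derivative function for the coupled glucagon, delayed
#' glucose, ACTH and cortisol states under a glucose/insulin forcing
#' profile. Turnover structure uses one plasma state per hormone; the pool
#' structures add an extravascular state each, with the glucose/insulin (or
#' ACTH) effect placed on the zero-order synthesis or on the first-order
#' secretion from the pool. Normally called through [simulate_individual()].
#'
#' @param t time (min).
#' @param state named state vector (see [simulate_individual()]).
#' @param parms internal parameter list built from an individual parameter
#'   set, a [make_forcing()] profile and a [model_variant()].
#' @return `list(derivatives)` as required by [deSolve::ode()].
#' @export
hormone_rhs <- function(t, state, parms) {
  p <- parms$p
  v <- parms$variant
  G <- parms$gfun(t)
  I <- parms$ifun(t)
  inh_g <- glucagon_inhibition(G, I, p, v)
  ke <- log(2) / p$t_half
  dge <- ke * (G - state[["ge"]])
  sig <- if (v$delay) state[["ge"]] else G
  inh_a <- acth_inhibition(sig, p)
  stim <- cortisol_stimulation(state[["acth"]], p, v)
  if (v$structure == "turnover") {
    list(c(gn = parms$ksecr_g * (1 - inh_g) - p$kout_g * state[["gn"]],
           ge = dge,
           acth = parms$ksecr_a * (1 - inh_a) - p$kout_a * state[["acth"]],
           cort = parms$ksecr_c * stim - p$kout_c * state[["cort"]]))
  } else if (v$structure == "pool_synthesis") {
    list(c(gn = p$k_pool * state[["gn_ex"]] - p$kout_g * state[["gn"]],
           gn_ex = parms$ksecr_g * (1 - inh_g) - p$k_pool * state[["gn_ex"]],
           ge = dge,
           acth = p$k_pool * state[["acth_ex"]] - p$kout_a * state[["acth"]],
           acth_ex = parms$ksecr_a * (1 - inh_a) -
             p$k_pool * state[["acth_ex"]],
           cort = p$k_pool * state[["cort_ex"]] - p$kout_c * state[["cort"]],
           cort_ex = parms$ksecr_c * stim - p$k_pool * state[["cort_ex"]]))
  } else {  # pool_secretion: constant synthesis, modulated transfer
    kg <- p$k_pool * (1 - inh_g)
    ka <- p$k_pool * (1 - inh_a)
    kc <- p$k_pool * stim
    list(c(gn = kg * state[["gn_ex"]] - p$kout_g * state[["gn"]],
           gn_ex = p$gn0 * p$kout_g - kg * state[["gn_ex"]],
           ge = dge,
           acth = ka * state[["acth_ex"]] - p$kout_a * state[["acth"]],
           acth_ex = p$acth0 * p$kout_a - ka * state[["acth_ex"]],
           cort = kc * state[["cort_ex"]] - p$kout_c * state[["cort"]],
           cort_ex = p$cort0 * p$kout_c - kc * state[["cort_ex"]]))
  }
}

#' Simulate one individual's hormone trajectories under a clamp forcing
#'
#' Integrates the glucagon, ACTH (with effect-compartment-delayed glucose)
#' and cortisol sub-models for one individual under an imposed
#' glucose/insulin forcing profile, starting from the fasting steady state.
#' Method `"lsoda"` (default) uses the stiff-capable adaptive integrator of
#' \pkg{deSolve} with tight tolerances; `"grid"` uses the package's exact
#' piecewise-linear exponential-integrator on a uniform fine grid (the same
#' engine the estimation routines use; the two agree to well below 0.1%).
#'
#' @param p individual parameters from [realize_individual()] (typicals can
#'   be used by realizing with zero random effects).
#' @param forcing a [make_forcing()] profile (or any list with `time`,
#'   `glucose`, `insulin`, `insulin_time`, `t_end`, `dialect`).
#' @param times sorted output times (min) within the forcing support.
#' @param variant a [model_variant()].
#' @param method `"lsoda"` or `"grid"`.
#' @param rtol,atol integrator tolerances (lsoda).
#' @param h grid step (min; grid method).
#' @return data.frame with `time`, `glucagon`, `acth`, `cortisol`, the
#'   forcing `glucose`/`insulin` and the delayed glucose `ge`.
#' @examples
#' p <- realize_individual(hormone_params(),
#'        list(gir = 8.13, fasting_glucose = 5.3, fasting_insulin = 10.4))
#' fp <- make_forcing(clamp_design("almby"),
#'        list(fasting_glucose = 5.3, fasting_insulin = 10.4), jitter_sd = 0)
#' sim <- simulate_individual(p, fp, seq(0, 195, 15))
#' @export
simulate_individual <- function(p, forcing, times,
                                variant = model_variant(),
                                method = c("lsoda", "grid"),
                                rtol = 1e-8, atol = 1e-10, h = 0.5) {
  method <- match.arg(method)
  if (is.unsorted(times)) stop("'times' must be sorted")
  if (min(times) < 0 || max(times) > forcing$t_end + 1e-9)
    stop("interpolation range: 'times' outside the forcing support [0, ",
         forcing$t_end, "]")
  parms <- make_rhs_parms(p, forcing, variant)
  if (method == "lsoda") {
    y0 <- rhs_init_state(p, parms)
    tt <- sort(unique(c(0, times)))
    sol <- tryCatch(
      deSolve::ode(y = y0, times = tt, func = hormone_rhs, parms = parms,
                   method = "lsoda", rtol = rtol, atol = atol),
      error = function(e)
        stop("integrator failure (", conditionMessage(e), ") with ic50_g=",
             signif(p$ic50_g, 4), ", ic50_i=", signif(p$ic50_i, 4),
             ", ic50_a=", signif(p$ic50_a, 4), ", t_half=",
             signif(p$t_half, 4), call. = FALSE))
    sol <- as.data.frame(sol)
    ix <- match(times, sol$time)
    funs <- forcing_funs(forcing)
    data.frame(time = times, glucagon = sol$gn[ix], acth = sol$acth[ix],
               cortisol = sol$cort[ix], glucose = funs$glucose(times),
               insulin = funs$insulin(times), ge = sol$ge[ix])
  } else {
    grid <- seq(0, forcing$t_end, by = h)
    funs <- forcing_funs(forcing)
    G <- funs$glucose(grid)
    I <- funs$insulin(grid)
    pr <- predict_grid(p, G, I, h, variant)
    at <- function(x) approx(grid, x, xout = times, rule = 2)$y
    data.frame(time = times, glucagon = at(pr$glucagon), acth = at(pr$acth),
               cortisol = at(pr$cortisol), glucose = funs$glucose(times),
               insulin = funs$insulin(times), ge = at(pr$ge))
  }
}
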