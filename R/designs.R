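#' Clamp study designs
#'
#' Built-in presets for the three hypoglycemic clamp arms and the
#' hyperglycemic clamp arm that the synthetic data emulate:
#' \describe{
#'   \item{`abrahamsson`}{normoglycemia 5.0 mmol/L for 110 min, hypoglycemia
#'     2.7 mmol/L for 105 min, 30-min recovery; insulin infused until
#'     recovery.}
#'   \item{`almby`}{normoglycemia 5.0 for 60 min, hypoglycemia 2.7 for
#'     105 min, 30-min recovery.}
#'   \item{`lundqvist_hypo`}{normoglycemia 5.0 for 60 min, stepwise descent
#'     (3.8 mmol/L for 20 min) to 2.7 mmol/L held for 85 min, 30-min
#'     recovery.}
#'   \item{`lundqvist_hyper`}{30-min isoglycemia at the fasting level, then
#'     +3, +6 and +9 mmol/L steps of 45 min each, 30-min return phase; no
#'     insulin infusion (insulin rises endogenously).}
#' }
#' Glucose is sampled every 5 min; hormones every 15 min from `t = 0`
#' (within the reported 15-30 min sampling intervals), including one
#' baseline sample per analyte.
#'
#' @param name preset name, or a custom design built with the `phases`
#'   arguments below.
#' @param phases optional data.frame overriding the preset phases, with
#'   columns `duration` (min), `target` (absolute glucose target, mmol/L, or
#'   `NA` to use `offset`), `offset` (mmol/L added to the fasting glucose)
#'   and `insulin` (logical, insulin infusion running).
#' @param hormone_times optional vector of hormone sampling times (min).
#' @param glucose_interval glucose sampling interval (min, default 5).
#' @return A classed list `clamp_design` with elements `name`, `phases`,
#'   `hormone_times`, `glucose_interval`, `t_end`.
#' @examples
#' d <- clamp_design("almby")
#' d$t_end
#' clamp_design_names()
#' @export
clamp_design <- function(name = clamp_design_names(), phases = NULL,
                         hormone_times = NULL, glucose_interval = 5) {
  if (is.null(phases)) {
    name <- match.arg(name)
    phases <- switch(name,
      abrahamsson = data.frame(
        duration = c(110, 105, 30), target = c(5.0, 2.7, 5.0),
        offset = NA_real_, insulin = c(TRUE, TRUE, FALSE)),
      almby = data.frame(
        duration = c(60, 105, 30), target = c(5.0, 2.7, 5.0),
        offset = NA_real_, insulin = c(TRUE, TRUE, FALSE)),
      lundqvist_hypo = data.frame(
        duration = c(60, 20, 85, 30), target = c(5.0, 3.8, 2.7, 5.0),
        offset = NA_real_, insulin = c(TRUE, TRUE, TRUE, FALSE)),
      lundqvist_hyper = data.frame(
        duration = c(30, 45, 45, 45, 30),
        target = NA_real_, offset = c(0, 3, 6, 9, 0),
        insulin = FALSE))
  } else {
    stopifnot(is.data.frame(phases),
              all(c("duration", "target", "insulin") %in% names(phases)))
    if (is.null(phases$offset)) phases$offset <- NA_real_
    if (!is.character(name)) name <- "custom"
  }
  t_end <- sum(phases$duration)
  if (is.null(hormone_times)) hormone_times <- seq(0, t_end, by = 15)
  if (any(hormone_times < 0) || any(hormone_times > t_end))
    stop("hormone sampling times must lie within [0, t_end]")
  structure(list(name = name[1L], phases = phases,
                 hormone_times = sort(unique(hormone_times)),
                 glucose_interval = glucose_interval, t_end = t_end),
            class = "clamp_design")
}

#' @rdname clamp_design
#' @export
clamp_design_names <- function() {
  c("abrahamsson", "almby", "lundqvist_hypo", "lundqvist_hyper")
}

#' Build glucose/insulin forcing for a clamp design and an individual
#'
#' The glucose track starts at the individual's fasting glucose and
#' approaches each phase target exponentially (time constant `tau`), with
#' optional Gaussian measurement jitter at the 5-min sampling knots. While
#' the insulin infusion runs, insulin rises from the fasting level to a
#' clamp plateau (default 60-120 uU/mL, scaled by the individual's
#' insulin-resistance index) and decays back after termination; in phases
#' without infusion insulin follows the endogenous response to glucose
#' above the fasting level. Insulin knots are placed at the hormone
#' sampling times.
#'
#' @param design a [clamp_design()].
#' @param cov covariate record (list/row) with `fasting_glucose`,
#'   `fasting_insulin` and (optionally) `homa_ir`.
#' @param seed integer seed, or `NULL` to draw from the current RNG state.
#' @param tau glucose equilibration time constant (min, default 10).
#' @param tau_ins insulin rise/decay time constants (min, rise then decay).
#' @param jitter_sd glucose measurement jitter SD (mmol/L, default 0.1; 0
#'   gives a deterministic piecewise-smooth track).
#' @param insulin_jitter proportional insulin jitter SD (default 0.03).
#' @param insulin_plateau clamp insulin plateau (uU/mL); default scales
#'   75 uU/mL by `(homa_ir / 2.68)^0.25`, clipped to 60-120.
#' @param endogenous_slope fractional endogenous insulin rise per mmol/L of
#'   glucose above fasting (hyperglycemic phases without infusion).
#' @param dialect interpolation dialect carried by the profile: `"linear"`
#'   (default) or `"step"` (left-continuous step functions).
#' @return A `forcing_profile`: list with `time`, `glucose`, `insulin`
#'   (values at `time`), `insulin_time`, `dialect`, `t_end`.
#' @examples
#' cov <- list(fasting_glucose = 5.3, fasting_insulin = 10.4, homa_ir = 2.68)
#' fp <- make_forcing(clamp_design("almby"), cov, seed = 1)
#' range(fp$glucose)
#' @export
make_forcing <- function(design, cov, seed = NULL, tau = 10,
                         tau_ins = c(8, 12), jitter_sd = 0.1,
                         insulin_jitter = 0.03, insulin_plateau = NULL,
                         endogenous_slope = 0.45,
                         dialect = c("linear", "step")) {
  dialect <- match.arg(dialect)
  old_rng <- save_rng(seed)
  on.exit(restore_rng(old_rng), add = TRUE)
  gf <- cov$fasting_glucose
  insf <- cov$fasting_insulin
  hir <- if (!is.null(cov$homa_ir)) cov$homa_ir else homa_ir(gf, insf)
  tt <- seq(0, design$t_end, by = design$glucose_interval)

  ph <- design$phases
  ph$target_abs <- ifelse(is.na(ph$target), gf + ph$offset, ph$target)
  ph$t0 <- cumsum(c(0, ph$duration[-nrow(ph)]))
  ph$t1 <- cumsum(ph$duration)

  # smooth glucose: exponential approach to each phase target from the level
  # reached at the end of the previous phase
  g_smooth <- function(t) {
    g <- numeric(length(t))
    lvl <- gf
    for (k in seq_len(nrow(ph))) {
      sel <- t >= ph$t0[k] & (t < ph$t1[k] | k == nrow(ph))
      g[sel] <- ph$target_abs[k] +
        (lvl - ph$target_abs[k]) * exp(-(t[sel] - ph$t0[k]) / tau)
      lvl <- ph$target_abs[k] +
        (lvl - ph$target_abs[k]) * exp(-ph$duration[k] / tau)
    }
    g
  }
  glu <- g_smooth(tt)
  if (jitter_sd > 0) glu <- pmax(glu + rnorm(length(tt), 0, jitter_sd), 1.0)

  ins_t <- design$hormone_times
  plateau <- if (!is.null(insulin_plateau)) insulin_plateau else
    min(max(75 * (hir / 2.68)^0.25, 60), 120)
  t_stop <- if (any(ph$insulin)) max(ph$t1[ph$insulin]) else 0
  g_at <- approxfun(tt, glu, rule = 2)
  ins <- numeric(length(ins_t))
  for (j in seq_along(ins_t)) {
    t <- ins_t[j]
    if (any(ph$insulin)) {
      if (t <= t_stop) {
        ins[j] <- plateau + (insf - plateau) * exp(-t / tau_ins[1])
      } else {
        i_stop <- plateau + (insf - plateau) * exp(-t_stop / tau_ins[1])
        ins[j] <- insf + (i_stop - insf) * exp(-(t - t_stop) / tau_ins[2])
      }
    } else {
      ins[j] <- insf * (1 + endogenous_slope * max(0, g_at(t) - gf))
    }
  }
  if (insulin_jitter > 0)
    ins <- pmax(ins * (1 + rnorm(length(ins), 0, insulin_jitter)), 0.5)

  structure(list(time = tt, glucose = glu, insulin = ins,
                 insulin_time = ins_t, dialect = dialect,
                 t_end = design$t_end),
            class = "forcing_profile")
}

# interpolating functions for a forcing profile; constant extrapolation
# beyond the knots; "step" dialect is left-continuous (value of the
# incoming segment at a knot)
forcing_funs <- function(fp) {
  if (fp$dialect == "linear") {
    list(glucose = approxfun(fp$time, fp$glucose, rule = 2),
         insulin = approxfun(fp$insulin_time, fp$insulin, rule = 2))
  } else {
    list(glucose = approxfun(fp$time, fp$glucose, method = "constant",
                             f = 1, rule = 2),
         insulin = approxfun(fp$insulin_time, fp$insulin,
                             method = "constant", f = 1, rule = 2))
  }
}
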