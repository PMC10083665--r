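# Exact solution of dC/dt = a(t) - k*C on a uniform grid, with a(t) taken
# piecewise linear between the grid nodes (the secretion input is a smooth
# function of piecewise-linear forcing, so this is second-order accurate in
# the grid step). Computed blockwise with a cumulative-sum formulation so
# the growing exponentials stay below exp(30) regardless of k * t_end.
expfilter <- function(a, k, h, c0) {
  n <- length(a) - 1L
  if (n < 1L) return(c0)
  if (k <= 0) stop("removal rate must be positive")
  kh <- k * h
  if (kh < 1e-8) {  # series limit, avoids 0/0
    P1 <- h * (1 - kh / 2 + kh^2 / 6)
    P2 <- h / 2 * (1 - kh / 3)
  } else {
    E1 <- (1 - exp(-kh)) / k
    P1 <- E1
    P2 <- 1 / k - E1 / kh
  }
  b <- a[-(n + 1L)] * P1 + diff(a) * P2       # per-step forced increment
  out <- numeric(n + 1L)
  out[1L] <- c0
  m <- max(1L, min(n, floor(30 / max(kh, 1e-12))))
  j0 <- 0L
  cur <- c0
  while (j0 < n) {
    len <- min(m, n - j0)
    idx <- (j0 + 1L):(j0 + len)
    w <- b[idx] * exp(kh * seq_len(len))
    cvals <- exp(-kh * seq_len(len)) * (cur + cumsum(w))
    out[idx + 1L] <- cvals
    cur <- cvals[len]
    j0 <- j0 + len
  }
  out
}

# variant with a time-varying removal rate (pool model with effects on the
# secretion rate constant); midpoint freezing of a and k per step
expfilter_tv <- function(a, k, h, c0) {
  n <- length(a) - 1L
  out <- numeric(n + 1L)
  out[1L] <- c0
  cur <- c0
  for (j in seq_len(n)) {
    km <- (k[j] + k[j + 1L]) / 2
    am <- (a[j] + a[j + 1L]) / 2
    E <- exp(-km * h)
    cur <- cur * E + am * (1 - E) / km
    out[j + 1L] <- cur
  }
  out
}

# Solve one hormone's structure given the secretion modifier trajectory.
# mod: (1 - inhibition) or the stimulation fold at the grid nodes; mod0 is
# the fasting value used for the steady-state closure of the secretion rate.
solve_structure <- function(mod, mod0, c0, kout, k_pool, h, structure) {
  if (mod0 <= 0) stop("degenerate baseline: fasting secretion fully shut off")
  switch(structure,
    turnover = {
      ksecr <- c0 * kout / mod0
      expfilter(ksecr * mod, kout, h, c0)
    },
    pool_synthesis = {
      ksynth <- c0 * kout / mod0
      cex <- expfilter(ksynth * mod, k_pool, h, c0 * kout / k_pool)
      expfilter(k_pool * cex, kout, h, c0)
    },
    pool_secretion = {
      ksynth <- c0 * kout
      cex0 <- ksynth / (k_pool * mod0)
      cex <- expfilter_tv(rep(ksynth, length(mod)), k_pool * mod, h, cex0)
      expfilter(k_pool * mod * cex, kout, h, c0)
    },
    stop("unknown structure: ", structure))
}

# Grid predictions of the three hormone sub-models for one individual.
# G, I: forcing at the uniform grid (step h); p: individual parameters with
# covariate-adjusted potencies and fasting values. The fasting conditions
# close the secretion rates (steady state at t = 0). Returns a list of
# trajectories at the grid nodes (plus the delayed glucose `ge`).
predict_grid <- function(p, G, I, h, variant = model_variant(),
                         which = c("glucagon", "acth", "cortisol")) {
  gf <- p$fasting_glucose
  insf <- p$fasting_insulin
  if (is.null(gf) || is.null(insf))
    stop("individual parameters must carry fasting_glucose/fasting_insulin")
  out <- list()
  if ("glucagon" %in% which) {
    inh <- glucagon_inhibition(G, I, p, variant)
    inh0 <- glucagon_inhibition(gf, insf, p, variant)
    out$glucagon <- solve_structure(1 - inh, 1 - inh0, p$gn0, p$kout_g,
                                    p$k_pool, h, variant$structure)
  }
  need_acth <- any(c("acth", "cortisol") %in% which)
  if (need_acth) {
    ge <- if (variant$delay) {
      ke <- log(2) / p$t_half
      expfilter(ke * G, ke, h, gf)
    } else G
    inh <- acth_inhibition(ge, p)
    inh0 <- acth_inhibition(gf, p)
    acth <- solve_structure(1 - inh, 1 - inh0, p$acth0, p$kout_a,
                            p$k_pool, h, variant$structure)
    out$ge <- ge
    if ("acth" %in% which) out$acth <- acth
    if ("cortisol" %in% which) {
      stim <- cortisol_stimulation(acth, p, variant)
      stim0 <- cortisol_stimulation(p$acth0, p, variant)
      out$cortisol <- solve_structure(stim, stim0, p$cort0, p$kout_c,
                                      p$k_pool, h, variant$structure)
    }
  }
  out
}
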