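# ---- internal: per subject-occasion "frames" for prediction ----------------
# A frame holds the uniform prediction grid, the forcing interpolated onto
# it (from the dataset's glucose/insulin records), the observation indices
# per hormone, and the covariate row.

.analyte_codes <- c(glucagon = 1L, acth = 2L, cortisol = 3L,
                    glucose = 4L, insulin = 5L)
.required_cols <- c("ID", "OCC", "TIME", "DVID", "DV", "BLQ", "LOQ")

build_frames <- function(data, h = 1) {
  miss <- setdiff(.required_cols, names(data))
  if (length(miss))
    stop("dataset lacks column(s): ", paste(miss, collapse = ", "))
  covcols <- setdiff(names(data), .required_cols)
  key <- interaction(data$ID, data$OCC, drop = TRUE)
  lapply(split(seq_len(nrow(data)), key), function(ix) {
    d <- data[ix, ]
    gl <- d[d$DVID == 4L, ]
    ins <- d[d$DVID == 5L, ]
    if (!nrow(gl) || !nrow(ins))
      stop("subject ", d$ID[1], " occasion ", d$OCC[1],
           ": glucose/insulin forcing records missing")
    tend <- max(d$TIME)
    grid <- seq(0, tend, by = h)
    G <- approx(gl$TIME, gl$DV, xout = grid, rule = 2)$y
    I <- approx(ins$TIME, ins$DV, xout = grid, rule = 2)$y
    obs <- lapply(c(glucagon = 1L, acth = 2L, cortisol = 3L), function(code) {
      o <- d[d$DVID == code, ]
      if (!nrow(o)) return(NULL)
      oi <- round(o$TIME / h) + 1L
      if (any(abs(grid[oi] - o$TIME) > 1e-8))
        stop("observation times must lie on the ", h, "-min prediction grid")
      list(ix = oi, dv = o$DV, blq = o$BLQ == 1L, loq = o$LOQ)
    })
    cov <- lapply(d[1, covcols, drop = FALSE], identity)
    list(id = d$ID[1], occ = d$OCC[1], grid = grid, h = h, G = G, I = I,
         obs = obs, cov = cov)
  })
}

# covariate-adjusted individual parameter list for one frame: the native
# exponential GIR effects on ic50_i/ic50_a plus any generic `beta` slopes
# (named beta_<parameter>_<COLUMN>) estimated by the covariate screen
frame_params <- function(par, frame, beta_refs = NULL) {
  ind <- par
  gir <- frame$cov$GIR
  if (is.null(gir)) stop("dataset lacks the GIR covariate column")
  ind$ic50_i <- par$ic50_i * exp(par$theta_gir_i * (gir - par$gir_ref))
  ind$ic50_a <- par$ic50_a * exp(par$theta_gir_a * (gir - par$gir_ref))
  bn <- grep("^beta_", names(par), value = TRUE)
  for (nm in bn) {
    spl <- sub("^beta_", "", nm)
    covname <- sub("^.*__", "", spl)
    target <- sub("__.*$", "", spl)
    x <- frame$cov[[covname]]
    if (is.null(x)) stop("covariate column '", covname, "' not in dataset")
    ref <- if (!is.null(beta_refs[[nm]])) beta_refs[[nm]] else 0
    ind[[target]] <- ind[[target]] * exp(par[[nm]] * (x - ref))
  }
  ind$fasting_glucose <- frame$cov$GLUF
  ind$fasting_insulin <- frame$cov$INSF
  if (is.null(ind$fasting_glucose) || is.null(ind$fasting_insulin))
    stop("dataset lacks the GLUF/INSF fasting covariate columns")
  ind
}

.sigma_name <- c(glucagon = "sigma_g", acth = "sigma_a", cortisol = "sigma_c")

# -2 log-likelihood over the frames for the requested sub-models
frames_ofv <- function(frames, par, submodels, variant, beta_refs = NULL) {
  ll <- 0
  for (fr in frames) {
    ind <- frame_params(par, fr, beta_refs)
    pr <- predict_grid(ind, fr$G, fr$I, fr$h, variant, which = submodels)
    for (an in submodels) {
      o <- fr$obs[[an]]
      if (is.null(o)) next
      f <- pr[[an]][o$ix]
      if (any(!is.finite(f)) || any(f <= 0))
        stop("non-positive prediction for ", an, " (subject ", fr$id,
             ", occasion ", fr$occ, ")")
      sig <- par[[.sigma_name[[an]]]] * f * ifelse(o$blq, par$f_add, 1)
      ll <- ll + sum(log(2 * pi) + 2 * log(sig) + ((o$dv - f) / sig)^2)
    }
  }
  ll
}

#' Objective function value (-2 log-likelihood) of a dataset
#'
#' Gaussian proportional-error likelihood of the longitudinal hormone
#' records given population parameters (naive-pooled: the parameters are
#' applied to every subject after covariate adjustment). Each record
#' contributes `log(2*pi) + log(sigma_i^2) + (y - f)^2 / sigma_i^2` with
#' `sigma_i = sigma_analyte * f`, inflated by the factor `f_add` for
#' below-quantification records.
#'
#' @param data a longitudinal clamp dataset (see [generate_dataset()] /
#'   [read_dataset()]).
#' @param p a [hormone_params()] set (or named list of the same shape).
#' @param submodel `"glucagon"`, `"acth"`, `"cortisol"` or `"all"`.
#' @param variant a [model_variant()].
#' @param h prediction grid step (min).
#' @return The OFV (numeric scalar).
#' @export
neg2loglik <- function(data, p, submodel = "all",
                       variant = model_variant(), h = 1) {
  submodels <- if (identical(submodel, "all"))
    c("glucagon", "acth", "cortisol") else
    match.arg(submodel, c("glucagon", "acth", "cortisol"), several.ok = TRUE)
  frames <- build_frames(data, h = h)
  frames_ofv(frames, unclass(p), submodels, variant)
}

# ---- parameter transforms --------------------------------------------------

.trans_kind <- function(nm) {
  if (nm %in% c("imax_a", "frac")) "logit"
  else if (nm %in% c("theta_gir_i", "theta_gir_a") || grepl("^beta_", nm))
    "identity"
  else "log"
}

to_trans <- function(val, nm) switch(.trans_kind(nm),
  log = log(val), logit = log(val / (1 - val)), identity = val)

from_trans <- function(x, nm) switch(.trans_kind(nm),
  log = exp(x), logit = 1 / (1 + exp(-x)), identity = x)

.default_free <- list(
  glucagon = c("ic50_g", "gamma_g", "ic50_i", "theta_gir_i", "sigma_g"),
  acth = c("ic50_a", "imax_a", "t_half", "theta_gir_a", "sigma_a"),
  cortisol = c("ec50_c", "emax_c", "gamma_c", "sigma_c"))

data_fingerprint <- function(data) {
  paste(nrow(data), signif(sum(data$DV), 12), signif(sum(data$TIME), 12),
        sep = "/")
}

#' Fit a hormone sub-model by maximum likelihood
#'
#' Naive-pooled maximum-likelihood estimation of one sub-model's fixed
#' effects on a longitudinal clamp dataset. The forcing (glucose, insulin)
#' is reconstructed from the dataset's records; baselines and removal rates
#' default to the typical values and are estimated only if listed in
#' `free`. Positive parameters are optimized on the log scale, bounded
#' fractions on the logit scale, covariate slopes untransformed, with a
#' derivative-free Nelder-Mead search and multi-start (jittered restarts;
#' the best OFV wins, ties broken by the lexicographically smallest
#' parameter vector).
#'
#' @param data the dataset.
#' @param submodel `"glucagon"`, `"acth"` or `"cortisol"`.
#' @param variant a [model_variant()].
#' @param free names of free parameters (default: the sub-model's potency,
#'   shape, delay, covariate-slope and residual-error parameters).
#' @param start named list of starting values for free parameters (default:
#'   the typical values).
#' @param fixed named list of parameter values to fix (overrides defaults
#'   and removes the name from `free`).
#' @param betas optional data.frame with columns `parameter`, `covariate`
#'   adding generic exponential covariate slopes `beta_<par>__<col>` (used
#'   by [scm()]); the covariate reference is its median across subjects.
#' @param n_starts number of starts (default 5: the supplied start plus 4
#'   jittered).
#' @param seed integer seed for the start jitter.
#' @param h prediction grid step (min).
#' @param jitter SD of the start jitter on the transformed scale.
#' @param control passed to [stats::optim()] (defaults: Nelder-Mead,
#'   `reltol = 1e-8`, `maxit = 2000`).
#' @return A `clamp_fit` object: estimates (full parameter list), `free`,
#'   `ofv`, `n_obs`, `n_params`, `convergence` flag, `iterations`, `seed`,
#'   `submodel`, `variant`, `beta_refs`, and a data fingerprint.
#' @export
fit_submodel <- function(data, submodel = c("glucagon", "acth", "cortisol"),
                         variant = model_variant(), free = NULL,
                         start = NULL, fixed = NULL, betas = NULL,
                         n_starts = 5, seed = 1, h = 1, jitter = 0.2,
                         control = list()) {
  submodel <- match.arg(submodel)
  par <- unclass(hormone_params())
  if (!is.null(fixed)) par[names(fixed)] <- fixed
  if (is.null(free)) free <- .default_free[[submodel]]
  free <- setdiff(free, names(fixed))
  beta_refs <- NULL
  if (!is.null(betas) && nrow(betas)) {
    ids <- !duplicated(data$ID)
    for (k in seq_len(nrow(betas))) {
      nm <- paste0("beta_", betas$parameter[k], "__", betas$covariate[k])
      par[[nm]] <- 0
      free <- c(free, nm)
      beta_refs[[nm]] <- median(data[[betas$covariate[k]]][ids])
    }
  }
  if (!is.null(start)) {
    bad <- setdiff(names(start), free)
    if (length(bad))
      stop("start value(s) for non-free parameter(s): ",
           paste(bad, collapse = ", "))
    par[names(start)] <- start
  }
  frames <- build_frames(data, h = h)
  n_obs <- sum(vapply(frames, function(fr)
    length(fr$obs[[submodel]]$dv), integer(1)))
  if (n_obs == 0L) stop("no ", submodel, " observations in the dataset")

  theta0 <- vapply(free, function(nm) to_trans(par[[nm]], nm), numeric(1))
  objective <- function(theta) {
    pp <- par
    for (j in seq_along(free)) pp[[free[j]]] <- from_trans(theta[j], free[j])
    v <- tryCatch(frames_ofv(frames, pp, submodel, variant, beta_refs),
                  error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }
  ctrl <- modifyList(list(reltol = 1e-8, maxit = 2000), control)
  old_rng <- save_rng(seed)
  on.exit(restore_rng(old_rng), add = TRUE)
  starts <- list(theta0)
  if (n_starts > 1)
    for (s in seq_len(n_starts - 1))
      starts[[s + 1]] <- theta0 + rnorm(length(theta0), 0, jitter)
  best <- NULL
  conv <- FALSE
  iters <- 0L
  for (th in starts) {
    o <- if (length(th) == 1L)
      optim(th, objective, method = "Brent", lower = th - 10,
            upper = th + 10, control = list(maxit = ctrl$maxit))
    else optim(th, objective, method = "Nelder-Mead", control = ctrl)
    iters <- iters + o$counts[["function"]]
    lex_less <- function(a, b) {
      i <- which(a != b)[1]
      !is.na(i) && a[i] < b[i]
    }
    better <- is.null(best) || o$value < best$value - 1e-9 ||
      (abs(o$value - best$value) <= 1e-9 && lex_less(o$par, best$par))
    if (better) best <- o
    if (o$convergence == 0) conv <- TRUE
  }
  for (j in seq_along(free)) par[[free[j]]] <- from_trans(best$par[j], free[j])
  structure(list(estimates = par, free = free, ofv = best$value,
                 n_obs = n_obs, n_params = length(free),
                 convergence = conv, iterations = iters, seed = seed,
                 submodel = submodel, variant = variant,
                 beta_refs = beta_refs, h = h,
                 data_hash = data_fingerprint(data)),
            class = "clamp_fit")
}

#' @export
print.clamp_fit <- function(x, ...) {
  cat("<clamp_fit>", x$submodel, "sub-model (", x$variant$structure,
      "), OFV =", format(x$ofv, digits = 8), "\n")
  est <- unlist(x$estimates[x$free])
  names(est) <- x$free
  print(signif(est, 4))
  cat(x$n_obs, "observations,", x$n_params, "free parameters, converged:",
      x$convergence, "\n")
  if (!is.null(x[["se"]])) {
    cat("bootstrap RSE (%):\n")
    print(signif(x$rse, 3))
  }
  invisible(x)
}

#' Compare two fitted sub-models
#'
#' Nested models are compared by the likelihood-ratio test on the OFV
#' difference (chi-squared with df = difference in number of parameters,
#' alpha = 0.05); non-nested models by the Akaike information criterion
#' `AIC = OFV + 2 * n_params` (lower wins). Both fits must be on the same
#' data.
#'
#' @param a,b `clamp_fit` objects; for a nested comparison `a` is the
#'   reduced and `b` the full model (or vice versa; the parameter counts
#'   decide).
#' @param nested logical.
#' @param alpha LRT significance level.
#' @return A list: `test`, `delta_ofv`, `df`/`delta_aic`, `p_value`,
#'   `significant`, `preferred` (`"a"` or `"b"`).
#' @export
compare_fits <- function(a, b, nested = TRUE, alpha = 0.05) {
  if (!identical(a$data_hash, b$data_hash))
    stop("comparison error: fits are not on the same dataset")
  if (nested) {
    red <- if (a$n_params <= b$n_params) a else b
    full <- if (a$n_params <= b$n_params) b else a
    if (full$n_params == red$n_params)
      stop("nested comparison needs different parameter counts")
    d_ofv <- red$ofv - full$ofv
    df <- full$n_params - red$n_params
    p <- pchisq(d_ofv, df, lower.tail = FALSE)
    sig <- p < alpha
    pref_fit <- if (sig) full else red
    list(test = "LRT", delta_ofv = d_ofv, df = df, p_value = p,
         significant = sig,
         preferred = if (identical(pref_fit, a)) "a" else "b")
  } else {
    aic_a <- a$ofv + 2 * a$n_params
    aic_b <- b$ofv + 2 * b$n_params
    list(test = "AIC", aic = c(a = aic_a, b = aic_b),
         delta_aic = aic_a - aic_b,
         preferred = if (aic_a <= aic_b) "a" else "b")
  }
}

#' Bootstrap standard errors of a fitted sub-model
#'
#' Subject-level resampling with replacement: each replicate redraws `n`
#' subjects, refits the sub-model (single start from the original
#' estimates) and the SE is the SD of the re-estimates; RSE% =
#' 100 * SE / estimate. Replicates that error or fail to converge are
#' dropped, with a warning when more than 20% fail.
#'
#' @param data the dataset the fit used.
#' @param fit a `clamp_fit` from [fit_submodel()].
#' @param reps number of bootstrap replicates (default 200).
#' @param seed integer seed.
#' @return The fit with `se`, `rse` (named vectors over free parameters),
#'   `boot_estimates` (matrix) and `n_failed` attached.
#' @export
bootstrap_se <- function(data, fit, reps = 200, seed = 1) {
  if (reps < 2) stop("'reps' must be >= 2")
  ids <- unique(data$ID)
  start <- fit$estimates[fit$free]
  names(start) <- fit$free
  old_rng <- save_rng(seed)
  on.exit(restore_rng(old_rng), add = TRUE)
  est <- matrix(NA_real_, reps, length(fit$free),
                dimnames = list(NULL, fit$free))
  failed <- 0L
  for (r in seq_len(reps)) {
    take <- sample(ids, length(ids), replace = TRUE)
    pieces <- lapply(seq_along(take), function(k) {
      d <- data[data$ID == take[k], ]
      d$ID <- k
      d
    })
    bd <- do.call(rbind, pieces)
    f <- tryCatch(
      fit_submodel(bd, fit$submodel, variant = fit$variant, free = fit$free,
                   start = start, n_starts = 1, seed = seed + r, h = fit$h,
                   control = list(reltol = 1e-7, maxit = 1500)),
      error = function(e) NULL)
    if (is.null(f) || !f$convergence) { failed <- failed + 1L; next }
    est[r, ] <- unlist(f$estimates[fit$free])
  }
  if (failed > 0.2 * reps)
    warning(failed, " of ", reps, " bootstrap replicates failed")
  se <- apply(est, 2, sd, na.rm = TRUE)
  point <- unlist(fit$estimates[fit$free])
  fit$se <- se
  fit$rse <- 100 * se / abs(point)
  fit$boot_estimates <- est
  fit$n_failed <- failed
  fit
}

.param_submodel <- c(ic50_g = "glucagon", gamma_g = "glucagon",
                     ic50_i = "glucagon", frac = "glucagon",
                     ic50_a = "acth", imax_a = "acth", t_half = "acth",
                     gamma_a = "acth",
                     ec50_c = "cortisol", emax_c = "cortisol",
                     gamma_c = "cortisol")

#' Stepwise covariate modelling (forward inclusion / backward elimination)
#'
#' Greedy forward inclusion of exponential parameter-covariate
#' relationships at a 5% likelihood-ratio significance level, followed by
#' backward elimination at 1%. The screen runs on the structural sub-models
#' with the built-in GIR effects switched off, so the GIR relationships of
#' the final model are themselves discoverable candidates. Candidate
#' covariate columns with pairwise correlation above 0.95 are flagged as
#' collinear (but still tested).
#'
#' @param data the dataset.
#' @param candidates data.frame with columns `parameter` (e.g. `"ic50_i"`,
#'   `"ic50_a"`) and `covariate` (a dataset column, e.g. `"GIR"`).
#' @param forward_alpha,backward_alpha significance levels.
#' @param variant a [model_variant()].
#' @param h prediction grid step (min).
#' @param seed integer seed (start jitter of the underlying fits).
#' @return List: `selected` (data.frame with slope estimates), `trace`
#'   (inclusion/elimination log), `collinear` (flagged covariate pairs).
#' @export
scm <- function(data, candidates, forward_alpha = 0.05,
                backward_alpha = 0.01, variant = model_variant(), h = 1,
                seed = 1) {
  if (is.null(candidates) || !nrow(candidates))
    return(list(selected = data.frame(parameter = character(),
                                      covariate = character(),
                                      estimate = numeric(),
                                      p_value = numeric()),
                trace = data.frame(), collinear = character()))
  candidates$submodel <- .param_submodel[candidates$parameter]
  if (anyNA(candidates$submodel))
    stop("candidate references an undeclared parameter")
  ids <- !duplicated(data$ID)
  covs <- unique(candidates$covariate)
  collinear <- character()
  if (length(covs) > 1) {
    cm <- cor(data[ids, covs, drop = FALSE])
    hi <- which(abs(cm) > 0.95 & row(cm) < col(cm), arr.ind = TRUE)
    if (nrow(hi))
      collinear <- apply(hi, 1, function(z)
        paste(covs[z[1]], covs[z[2]], sep = "~"))
    if (length(collinear))
      message("collinear candidate covariates: ",
              paste(collinear, collapse = ", "))
  }
  no_gir <- list(theta_gir_i = 0, theta_gir_a = 0)
  refit <- function(sm, sel) {
    b <- sel[sel$submodel == sm, c("parameter", "covariate"), drop = FALSE]
    fit_submodel(data, sm, variant = variant, fixed = no_gir,
                 betas = if (nrow(b)) b else NULL, n_starts = 1,
                 seed = seed, h = h)
  }
  base_fits <- list()
  for (sm in unique(candidates$submodel)) {
    base_fits[[sm]] <- refit(sm, candidates[0, ])
  }
  sel <- candidates[0, ]
  trace <- data.frame()
  repeat {  # forward
    remaining <- candidates[!paste(candidates$parameter,
                                   candidates$covariate) %in%
                              paste(sel$parameter, sel$covariate), ]
    if (!nrow(remaining)) break
    pvals <- numeric(nrow(remaining))
    fits <- vector("list", nrow(remaining))
    for (k in seq_len(nrow(remaining))) {
      trial <- rbind(sel, remaining[k, ])
      f <- refit(remaining$submodel[k], trial)
      d_ofv <- base_fits[[remaining$submodel[k]]]$ofv - f$ofv
      pvals[k] <- pchisq(max(d_ofv, 0), 1, lower.tail = FALSE)
      fits[[k]] <- f
    }
    best <- which.min(pvals)
    trace <- rbind(trace, data.frame(
      step = "forward", parameter = remaining$parameter[best],
      covariate = remaining$covariate[best], p_value = pvals[best],
      included = pvals[best] < forward_alpha))
    if (pvals[best] >= forward_alpha) break
    sel <- rbind(sel, remaining[best, ])
    base_fits[[remaining$submodel[best]]] <- fits[[best]]
  }
  repeat {  # backward
    if (!nrow(sel)) break
    pvals <- numeric(nrow(sel))
    reduced <- vector("list", nrow(sel))
    for (k in seq_len(nrow(sel))) {
      f <- refit(sel$submodel[k], sel[-k, ])
      d_ofv <- f$ofv - base_fits[[sel$submodel[k]]]$ofv
      pvals[k] <- pchisq(max(d_ofv, 0), 1, lower.tail = FALSE)
      reduced[[k]] <- f
    }
    worst <- which.max(pvals)
    if (pvals[worst] <= backward_alpha) break
    trace <- rbind(trace, data.frame(
      step = "backward", parameter = sel$parameter[worst],
      covariate = sel$covariate[worst], p_value = pvals[worst],
      included = FALSE))
    base_fits[[sel$submodel[worst]]] <- reduced[[worst]]
    sel <- sel[-worst, ]
  }
  est <- numeric(nrow(sel))
  pv <- numeric(nrow(sel))
  if (nrow(sel)) for (k in seq_len(nrow(sel))) {
    nm <- paste0("beta_", sel$parameter[k], "__", sel$covariate[k])
    est[k] <- base_fits[[sel$submodel[k]]]$estimates[[nm]]
    drop_fit <- refit(sel$submodel[k], sel[-k, ])
    pv[k] <- pchisq(max(drop_fit$ofv - base_fits[[sel$submodel[k]]]$ofv, 0),
                    1, lower.tail = FALSE)
  }
  list(selected = data.frame(parameter = sel$parameter,
                             covariate = sel$covariate,
                             estimate = est, p_value = pv),
       trace = trace, collinear = collinear)
}
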