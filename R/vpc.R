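#' Visual predictive check
#'
#' Simulates `n_sim` replicates of the dataset under the full population
#' model (between-subject and between-occasion variability plus residual
#' error), keeping each subject's design, forcing and covariates, and
#' compares binned observed percentiles (2.5th, 50th, 97.5th) with the 95%
#' confidence intervals of the corresponding simulated percentiles.
#' Observations are binned by the concurrent glucose concentration or by
#' time (equal-frequency bins; empty bins cannot arise, and duplicate
#' quantile breaks are merged with a warning). Companion panels report the
#' observed and simulated fractions of records below the limit of
#' quantification per bin.
#'
#' @param data the observed (or synthetic) dataset.
#' @param p a [hormone_params()] set to simulate from.
#' @param n_sim number of simulation replicates (default 1000).
#' @param bin_by `"glucose"` or `"time"`.
#' @param n_bins target number of bins.
#' @param seed integer seed.
#' @param bsv,bov,residual variability toggles for the replicates.
#' @param variant a [model_variant()].
#' @param h prediction grid step (min).
#' @return A `vpc_result`: list with `stats` (per analyte, bin and
#'   percentile: observed value and simulated CI), `blq` (BLQ fractions),
#'   `coverage` (fraction of bins whose observed percentile lies inside the
#'   simulated CI, per analyte and percentile), `bin_by`, `n_sim`.
#' @export
vpc <- function(data, p, n_sim = 1000, bin_by = c("glucose", "time"),
                n_bins = 8, seed = 1, bsv = TRUE, bov = TRUE,
                residual = TRUE, variant = model_variant(), h = 1) {
  bin_by <- match.arg(bin_by)
  old_rng <- save_rng(seed)
  on.exit(restore_rng(old_rng), add = TRUE)
  frames <- build_frames(data, h = h)
  sig <- c(glucagon = p$sigma_g, acth = p$sigma_a, cortisol = p$sigma_c)
  analytes <- c("glucagon", "acth", "cortisol")

  # observation bookkeeping: per analyte, pooled over frames
  meta <- list()
  for (an in analytes) {
    rows <- list()
    for (k in seq_along(frames)) {
      o <- frames[[k]]$obs[[an]]
      if (is.null(o)) next
      x <- if (bin_by == "glucose") frames[[k]]$G[o$ix]
           else frames[[k]]$grid[o$ix]
      rows[[length(rows) + 1L]] <-
        data.frame(frame = k, ix = o$ix, dv = o$dv, x = x, loq = o$loq)
    }
    if (length(rows)) meta[[an]] <- do.call(rbind, rows)
  }
  if (!length(meta)) stop("no hormone observations to check")

  # replicate simulations: redraw random effects per subject/occasion
  ids <- vapply(frames, function(fr) fr$id, numeric(1))
  sims <- lapply(meta, function(m)
    matrix(NA_real_, nrow(m), n_sim))
  for (r in seq_len(n_sim)) {
    eta_tab <- list()
    preds <- vector("list", length(frames))
    for (k in seq_along(frames)) {
      fr <- frames[[k]]
      sid <- as.character(fr$id)
      if (bsv && is.null(eta_tab[[sid]]))
        eta_tab[[sid]] <- setNames(rnorm(length(p$bsv)), names(p$bsv))
      kappa <- if (bov) setNames(rnorm(length(p$bov)), names(p$bov)) else NULL
      cov <- list(gir = fr$cov$GIR, fasting_glucose = fr$cov$GLUF,
                  fasting_insulin = fr$cov$INSF)
      ind <- realize_individual(p, cov, eta = eta_tab[[sid]], kappa = kappa,
                                id = fr$id, occ = fr$occ)
      preds[[k]] <- predict_grid(ind, fr$G, fr$I, fr$h, variant,
                                 which = analytes)
    }
    for (an in names(meta)) {
      m <- meta[[an]]
      f <- numeric(nrow(m))
      for (k in unique(m$frame)) {
        sel <- m$frame == k
        f[sel] <- preds[[k]][[an]][m$ix[sel]]
      }
      dv <- f
      if (residual) {
        dv <- f * (1 + sig[[an]] * rnorm(length(f)))
        while (any(dv <= 0))
          dv[dv <= 0] <- f[dv <= 0] * (1 + sig[[an]] * rnorm(sum(dv <= 0)))
      }
      sims[[an]][, r] <- dv
    }
  }

  probs <- c(0.025, 0.5, 0.975)
  stats <- list()
  blq <- list()
  for (an in names(meta)) {
    m <- meta[[an]]
    br <- unique(quantile(m$x, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < n_bins + 1)
      warning("duplicate bin breaks merged for ", an)
    bin <- cut(m$x, br, include.lowest = TRUE)
    for (b in levels(bin)) {
      sel <- bin == b
      if (!any(sel)) next
      obs_q <- quantile(m$dv[sel], probs, names = FALSE)
      sim_q <- apply(sims[[an]][sel, , drop = FALSE], 2, quantile,
                     probs = probs, names = FALSE)
      ci <- apply(sim_q, 1, quantile, probs = c(0.025, 0.975), names = FALSE)
      stats[[length(stats) + 1L]] <- data.frame(
        analyte = an, bin = b, x_mid = median(m$x[sel]),
        percentile = 100 * probs, observed = obs_q,
        sim_lo = ci[1, ], sim_hi = ci[2, ], n = sum(sel))
      obs_blq <- mean(m$dv[sel] < m$loq[sel])
      sim_blq <- colMeans(sims[[an]][sel, , drop = FALSE] < m$loq[sel])
      bq <- quantile(sim_blq, c(0.025, 0.975), names = FALSE)
      blq[[length(blq) + 1L]] <- data.frame(
        analyte = an, bin = b, x_mid = median(m$x[sel]),
        observed = obs_blq, sim_lo = bq[1], sim_hi = bq[2], n = sum(sel))
    }
  }
  stats <- do.call(rbind, stats)
  blq <- do.call(rbind, blq)
  cov_tab <- stats
  cov_tab$inside <- cov_tab$observed >= cov_tab$sim_lo &
    cov_tab$observed <= cov_tab$sim_hi
  coverage <- stats::aggregate(inside ~ analyte + percentile, cov_tab, mean)
  structure(list(stats = stats, blq = blq, coverage = coverage,
                 bin_by = bin_by, n_sim = n_sim),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat("<vpc_result>", x$n_sim, "simulations, binned by", x$bin_by, "\n")
  cat("coverage of observed percentiles by simulated 95% CIs:\n")
  print(x$coverage)
  invisible(x)
}

#' Plot a visual predictive check
#'
#' Base-graphics panels (one per analyte): observed percentiles (lines and
#' points) over the simulated 95% confidence bands (shaded), with the BLQ
#' fraction panel underneath when any record is below the limit of
#' quantification.
#'
#' @param x a `vpc_result`.
#' @param ... unused.
#' @export
plot.vpc_result <- function(x, ...) {
  ans <- unique(x$stats$analyte)
  op <- graphics::par(mfrow = c(1, length(ans)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (an in ans) {
    s <- x$stats[x$stats$analyte == an, ]
    s <- s[order(s$x_mid), ]
    ylim <- range(c(s$observed, s$sim_lo, s$sim_hi))
    plot(NA, xlim = range(s$x_mid), ylim = ylim, xlab = x$bin_by,
         ylab = an, main = an)
    for (pc in unique(s$percentile)) {
      sp <- s[s$percentile == pc, ]
      graphics::polygon(c(sp$x_mid, rev(sp$x_mid)),
                        c(sp$sim_lo, rev(sp$sim_hi)),
                        col = grDevices::adjustcolor("steelblue", 0.3),
                        border = NA)
      graphics::lines(sp$x_mid, sp$observed, lty = if (pc == 50) 1 else 2)
      graphics::points(sp$x_mid, sp$observed, pch = 16, cex = 0.6)
    }
  }
  invisible(x)
}
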