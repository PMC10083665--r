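.default_loq <- c(glucagon = 1.5, acth = 1.1, cortisol = 80)

#' Generate a fully synthetic longitudinal clamp dataset
#'
#' The synthetic stand-in for the (non-public) pooled clamp data: for each
#' subject and each design (one occasion per design), individual parameters
#' are realized from the population parameters, covariates and random
#' effects; the hormone trajectories are simulated under the design's
#' glucose/insulin forcing; hormone observations are sampled at the
#' design's sampling times with proportional residual error
#' `DV = f * (1 + sigma * eps)` (negative values are redrawn and counted);
#' and records below the limit of quantification are flagged (the value is
#' kept, matching the inflated-residual-error treatment of BLQ data, not
#' censored). Glucose (every 5 min) and insulin (at sampling times) forcing
#' records are written to the dataset as analytes 4 and 5.
#'
#' @param designs character vector of [clamp_design()] preset names, or a
#'   list of design objects; each is one occasion per subject.
#' @param n number of subjects.
#' @param p a [hormone_params()] set.
#' @param covariates optional covariate data.frame (defaults to
#'   [sample_covariates()] of size `n`).
#' @param bsv,bov,residual logical toggles for between-subject variability,
#'   between-occasion variability and residual error.
#' @param loq named limits of quantification per hormone (defaults:
#'   glucagon 1.5 pmol/L, ACTH 1.1 pmol/L, cortisol 80 nmol/L; assumed
#'   assay limits, configurable, not data-derived).
#' @param seed integer seed (all randomness: covariates, random effects,
#'   forcing jitter, residual error).
#' @param variant a [model_variant()].
#' @param h simulation grid step (min).
#' @param forcing_args named list passed on to [make_forcing()] (e.g.
#'   `jitter_sd`, `insulin_plateau`).
#' @return A data.frame of class `clamp_data` with columns `ID`, `OCC`,
#'   `TIME`, `DVID` (1 glucagon, 2 ACTH, 3 cortisol, 4 glucose, 5 insulin),
#'   `DV`, `BLQ`, `LOQ`, and covariate columns `GIR`, `BMI`, `HOMAIR`,
#'   `SEX`, `AGE`, `GLUF`, `INSF`, `BFP`, `WHR`, `HBA1C`. The number of
#'   redrawn negative observations is in `attr(, "n_truncated")`.
#' @examples
#' d <- generate_dataset("almby", n = 2, seed = 1, bsv = FALSE,
#'                       residual = FALSE)
#' table(d$DVID)
#' @export
generate_dataset <- function(designs = c("almby", "lundqvist_hyper"), n,
                             p = hormone_params(), covariates = NULL,
                             bsv = TRUE, bov = TRUE, residual = TRUE,
                             loq = .default_loq, seed = NULL,
                             variant = model_variant(), h = 0.5,
                             forcing_args = list()) {
  old_rng <- save_rng(seed)
  on.exit(restore_rng(old_rng), add = TRUE)
  if (is.character(designs)) designs <- lapply(designs, clamp_design)
  if (inherits(designs, "clamp_design")) designs <- list(designs)
  loq <- modifyList(as.list(.default_loq), as.list(loq))
  if (is.null(covariates)) covariates <- sample_covariates(n)
  if (nrow(covariates) < n) stop("covariate table has fewer than n rows")
  sig <- c(glucagon = p$sigma_g, acth = p$sigma_a, cortisol = p$sigma_c)
  n_trunc <- 0L
  rows <- list()
  for (i in seq_len(n)) {
    cov <- as.list(covariates[i, ])
    eta <- if (bsv) setNames(rnorm(length(p$bsv)), names(p$bsv)) else NULL
    for (j in seq_along(designs)) {
      des <- designs[[j]]
      kappa <- if (bov) setNames(rnorm(length(p$bov)), names(p$bov)) else NULL
      ind <- realize_individual(p, cov, eta = eta, kappa = kappa,
                                id = i, occ = j)
      fp <- do.call(make_forcing, c(list(design = des, cov = cov), forcing_args))
      sim <- simulate_individual(ind, fp, des$hormone_times,
                                 variant = variant, method = "grid", h = h)
      covrow <- data.frame(GIR = cov$gir, BMI = cov$bmi,
                           HOMAIR = cov$homa_ir, SEX = cov$sex,
                           AGE = cov$age, GLUF = cov$fasting_glucose,
                           INSF = cov$fasting_insulin, BFP = cov$body_fat,
                           WHR = cov$waist_hip, HBA1C = cov$hba1c)
      hr <- lapply(c("glucagon", "acth", "cortisol"), function(an) {
        f <- sim[[an]]
        dv <- f
        if (residual) {
          eps <- rnorm(length(f))
          dv <- f * (1 + sig[[an]] * eps)
          while (any(dv <= 0)) {      # truncation: redraw negative draws
            bad <- dv <= 0
            n_trunc <<- n_trunc + sum(bad)
            dv[bad] <- f[bad] * (1 + sig[[an]] * rnorm(sum(bad)))
          }
        }
        data.frame(ID = i, OCC = j, TIME = des$hormone_times,
                   DVID = .analyte_codes[[an]], DV = dv,
                   BLQ = as.integer(dv < loq[[an]]), LOQ = loq[[an]])
      })
      gr <- data.frame(ID = i, OCC = j, TIME = fp$time, DVID = 4L,
                       DV = fp$glucose, BLQ = 0L, LOQ = NA_real_)
      ir <- data.frame(ID = i, OCC = j, TIME = fp$insulin_time, DVID = 5L,
                       DV = fp$insulin, BLQ = 0L, LOQ = NA_real_)
      blk <- rbind(do.call(rbind, hr), gr, ir)
      rows[[length(rows) + 1L]] <- cbind(blk, covrow, row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$ID, out$OCC, out$DVID, out$TIME), ]
  rownames(out) <- NULL
  attr(out, "n_truncated") <- n_trunc
  class(out) <- c("clamp_data", "data.frame")
  out
}
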