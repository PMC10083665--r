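test_that("single-record likelihood matches the closed form", {
  # on the fasting steady state the glucagon prediction is gn0 exactly;
  # with gn0 = 10 and y = 10 the record contributes ln(2*pi*(0.338*10)^2)
  p <- hormone_params(gn0 = 10)
  d <- steady_record_data(p, dv = 10)
  expect_equal(neg2loglik(d, p, "glucagon"), log(2 * pi * 3.38^2),
               tolerance = 1e-9)
  expect_equal(log(2 * pi * 3.38^2), 4.27363, tolerance = 1e-5)
  # flagging the record BLQ inflates sigma by f_add: +2*ln(2.01)
  db <- steady_record_data(p, dv = 10, blq = 1L, loq = 12)
  expect_equal(neg2loglik(db, p, "glucagon") -
                 neg2loglik(d, p, "glucagon"), 2 * log(2.01),
               tolerance = 1e-9)
})

test_that("likelihood agrees with an independent dnorm summation", {
  # oracle route: per-record Gaussian density via dnorm() with the
  # analytically known steady-state predictions
  p <- hormone_params()
  set.seed(31)
  y_g <- p$gn0 * exp(rnorm(4, 0, 0.3))
  y_a <- p$acth0 * exp(rnorm(3, 0, 0.3))
  obs_row <- function(...) {
    x <- steady_record_data(p, ...)
    x[x$DVID %in% 1:3, ]
  }
  d <- steady_record_data(p, dv = y_g[1])
  for (y in y_g[-1]) d <- rbind(d, obs_row(dv = y))
  for (y in y_a) d <- rbind(d, obs_row(dv = y, analyte = "acth"))
  class(d) <- c("clamp_data", "data.frame")
  ofv <- neg2loglik(d, p, c("glucagon", "acth"))
  oracle <- -2 * sum(dnorm(y_g, p$gn0, p$sigma_g * p$gn0, log = TRUE)) -
    2 * sum(dnorm(y_a, p$acth0, p$sigma_a * p$acth0, log = TRUE))
  expect_equal(ofv, oracle, tolerance = 1e-10)
})

test_that("duplicating a dataset doubles the objective", {
  p <- hormone_params()
  d <- generate_dataset("almby", n = 2, covariates = ref_cov_df(2),
                        bsv = FALSE, bov = FALSE, seed = 32)
  d2 <- d
  d2$ID <- d2$ID + 10
  dd <- rbind(d, d2)
  class(dd) <- c("clamp_data", "data.frame")
  expect_equal(neg2loglik(dd, p), 2 * neg2loglik(d, p), tolerance = 1e-12)
})

test_that("missing forcing or covariates fail loudly", {
  p <- hormone_params()
  d <- steady_record_data(p, dv = 5)
  expect_error(neg2loglik(d[d$DVID != 5, ], p, "glucagon"),
               "forcing records missing")
  d2 <- d
  d2$GIR <- NULL
  expect_error(neg2loglik(d2, p, "glucagon"), "GIR")
})

test_that("fitting noise-free data from the truth returns the truth", {
  d <- generate_dataset("almby", n = 2, covariates = ref_cov_df(2),
                        bsv = FALSE, bov = FALSE, residual = FALSE,
                        seed = 33, forcing_args = list(jitter_sd = 0,
                                                       insulin_jitter = 0))
  truth <- list(ic50_g = 2.91, gamma_g = 5.26, ic50_i = 5.51)
  f <- fit_submodel(d, "glucagon", free = names(truth), start = truth,
                    fixed = list(sigma_g = 0.01, f_add = 1), n_starts = 1)
  for (nm in names(truth))
    expect_equal(f$estimates[[nm]], truth[[nm]], tolerance = 5e-3,
                 ignore_attr = TRUE)
  # the objective at the optimum equals its analytic floor (residuals ~ 0
  # up to integration error)
  expect_equal(f$ofv, f$n_obs * log(2 * pi) +
                 2 * sum(log(0.01 * d$DV[d$DVID == 1])), tolerance = 1e-3)
})

test_that("model comparison follows the LRT and AIC rules", {
  fa <- structure(list(ofv = 100, n_params = 3, data_hash = "x"),
                  class = "clamp_fit")
  fb <- structure(list(ofv = 100 - 3.84, n_params = 4, data_hash = "x"),
                  class = "clamp_fit")
  cmp <- compare_fits(fa, fb, nested = TRUE)
  expect_false(cmp$significant)   # 3.84 sits just below chisq(0.95, 1)
  fb$ofv <- 90
  expect_true(compare_fits(fa, fb, nested = TRUE)$significant)
  # equal OFV: the smaller model wins by AIC with a 2-point margin
  fb$ofv <- 100
  cmp2 <- compare_fits(fa, fb, nested = FALSE)
  expect_equal(cmp2$delta_aic, -2)
  expect_identical(cmp2$preferred, "a")
  fb$data_hash <- "y"
  expect_error(compare_fits(fa, fb), "same dataset")
})

test_that("bootstrap SEs vanish on noise-free data and are reproducible", {
  d <- generate_dataset("almby", n = 4, covariates = ref_cov_df(4),
                        bsv = FALSE, bov = FALSE, residual = FALSE,
                        seed = 34, forcing_args = list(jitter_sd = 0,
                                                       insulin_jitter = 0))
  f <- fit_submodel(d, "glucagon", free = c("ic50_g"),
                    fixed = list(sigma_g = 0.1, f_add = 1), n_starts = 1)
  b1 <- bootstrap_se(d, f, reps = 5, seed = 8)
  expect_lt(b1$se[["ic50_g"]], 1e-3)
  b2 <- bootstrap_se(d, f, reps = 5, seed = 8)
  expect_identical(b1$se, b2$se)
  expect_error(bootstrap_se(d, f, reps = 1), "reps")
})

test_that("bootstrap RSE of the glucose potency is a few percent", {
  # scaled-down replication of the reported ~3% relative standard error
  des <- clamp_design("almby")
  set.seed(35)
  cc <- sample_covariates(12)
  d <- generate_dataset(list(des), n = 12, covariates = cc, bsv = FALSE,
                        bov = FALSE, residual = TRUE, seed = 36)
  f <- fit_submodel(d, "glucagon", free = c("ic50_g", "gamma_g", "sigma_g"),
                    fixed = list(f_add = 1), n_starts = 1)
  f <- bootstrap_se(d, f, reps = 25, seed = 37)
  expect_gt(f$rse[["ic50_g"]], 0.3)
  expect_lt(f$rse[["ic50_g"]], 30)
})

test_that("an unneeded extra parameter rejects at about the nominal 5%", {
  des <- clamp_design("almby", hormone_times = seq(0, 195, 30))
  cc <- sample_covariates(6, seed = 301)
  set.seed(302)
  nrep <- 200
  rej <- 0L
  for (r in seq_len(nrep)) {
    d <- generate_dataset(list(des), n = 6, covariates = cc, bsv = FALSE,
                          bov = FALSE, residual = TRUE)
    noise <- rnorm(6)
    d$NOISE <- noise[d$ID]
    f0 <- fit_submodel(d, "cortisol", free = c("ec50_c", "sigma_c"),
                       n_starts = 1, fixed = list(f_add = 1))
    f1 <- fit_submodel(d, "cortisol", free = c("ec50_c", "sigma_c"),
                       n_starts = 1, fixed = list(f_add = 1),
                       betas = data.frame(parameter = "ec50_c",
                                          covariate = "NOISE"))
    if (f0$ofv - f1$ofv > qchisq(0.95, 1)) rej <- rej + 1L
  }
  expect_gte(rej / nrep, 0.01)
  expect_lte(rej / nrep, 0.105)
})

test_that("scm with no candidates returns an empty selection", {
  d <- generate_dataset("almby", n = 2, covariates = ref_cov_df(2),
                        seed = 38)
  res <- scm(d, data.frame(parameter = character(),
                           covariate = character()))
  expect_equal(nrow(res$selected), 0)
})
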