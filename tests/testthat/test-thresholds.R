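test_that("ACTH suppression thresholds match the closed form", {
  expect_equal(glucose_for_acth_inhibition(0.9, 8.13), 3.3039,
               tolerance = 1e-4)
  expect_equal(glucose_for_acth_inhibition(0.9, 12.0), 3.112,
               tolerance = 1e-3)
  expect_equal(glucose_for_acth_inhibition(0.9, 4.5), 3.495,
               tolerance = 1e-3)
  # targets above the maximal effect are unattainable
  expect_true(is.na(glucose_for_acth_inhibition(0.95, 8.13)))
  expect_error(glucose_for_acth_inhibition(1.2, 8.13), "target")
  # 50% response occurs exactly at the covariate-adjusted potency
  expect_equal(glucose_for_acth_half_response(8.13), 2.85)
  expect_equal(glucose_for_acth_half_response(12.0), 2.684,
               tolerance = 1e-3)
  expect_equal(glucose_for_acth_half_response(4.5), 3.015,
               tolerance = 1e-3)
})

test_that("insulin thresholds for glucagon suppression match closed form", {
  expect_equal(insulin_for_glucagon_inhibition(0.9, 5.0, 8.13), 17.886,
               tolerance = 1e-4)
  # glucose saturated: the insulin share is 0.6 of its span
  expect_equal(insulin_for_glucagon_inhibition(0.9, 1e9, 8.13), 8.265,
               tolerance = 1e-4)
  # deep hypoglycemia: insulin cannot reach 90% suppression alone
  expect_true(is.na(insulin_for_glucagon_inhibition(0.9, 2.0, 8.13)))
  expect_error(insulin_for_glucagon_inhibition(0, 5, 8.13), "target")
})

test_that("threshold solvers agree with a brute-force grid search", {
  set.seed(61)
  for (k in 1:6) {
    p <- jitter_params(0.2)
    gir <- runif(1, 3, 14)
    target <- runif(1, 0.5, 0.9 * p$imax_a)
    g_cf <- glucose_for_acth_inhibition(target, gir, p)
    gg <- seq(1e-4, 20, by = 1e-4)
    g_bf <- gg[which(acth_inhibition(
      gg, realize_individual(p, modifyList(ref_cov(),
                                           list(gir = gir)))) >= target)[1]]
    expect_equal(g_cf, g_bf, tolerance = 1e-3)
    i_cf <- insulin_for_glucagon_inhibition(0.9, 5.0, gir, p)
    if (!is.na(i_cf) && i_cf < 200) {
      ii <- seq(1e-4, 200, by = 1e-4)
      ind <- realize_individual(p, modifyList(ref_cov(), list(gir = gir)))
      i_bf <- ii[which(glucagon_inhibition(5.0, ii, ind) >= 0.9)[1]]
      expect_equal(i_cf, i_bf, tolerance = 1e-3)
    }
  }
})

test_that("thresholds are monotone in insulin sensitivity and glucose", {
  girs <- seq(3, 14, 1)
  g90 <- glucose_for_acth_inhibition(0.9, girs)
  expect_true(all(diff(g90) < 0))
  i90 <- insulin_for_glucagon_inhibition(0.9, 5.0, girs)
  expect_true(all(diff(i90) < 0))
  gl <- c(4.5, 5, 6, 8)
  iv <- vapply(gl, function(g)
    insulin_for_glucagon_inhibition(0.9, g, 8.13), numeric(1))
  expect_true(all(diff(iv) < 0))
})

test_that("threshold inversion round-trips through the effect function", {
  p <- hormone_params()
  for (x in c(0.3, 0.6, 0.9)) {
    g <- glucose_for_acth_inhibition(x, 8.13, p)
    expect_equal(acth_inhibition(g, p), x, tolerance = 1e-8)
  }
})

test_that("fasting suppression reflects the population variability", {
  # degenerate population: a single deterministic value per hormone
  fs0 <- fasting_suppression(ref_cov_df(5), bsv = FALSE)
  expect_equal(length(unique(round(fs0$individual$glucagon, 12))), 1)
  p <- hormone_params()
  expect_equal(fs0$individual$glucagon[1],
               glucagon_inhibition(5.3, 10.4, typical_individual(p)))
  # pure hypoglycemia with no insulin: frac * H_G(2.0)
  cov2 <- ref_cov_df(1)
  cov2$fasting_glucose <- 2.0
  cov2$fasting_insulin <- 1e-12
  fs2 <- fasting_suppression(cov2, bsv = FALSE)
  expect_equal(fs2$individual$glucagon[1], 0.75 * hill(2.0, 2.91, 5.26),
               tolerance = 1e-6)
  expect_equal(fs2$individual$glucagon[1], 0.0915, tolerance = 1e-2)
  # BSV on the insulin potency spreads the glucagon suppression widely,
  # qualitatively like the reported 68-95% fasting span
  fs <- fasting_suppression(sample_covariates(400, seed = 62), seed = 63)
  spread <- fs$summary$p95[1] - fs$summary$p5[1]
  expect_gt(spread, 0.10)
  expect_lt(fs$summary$p5[1], 0.95)
  expect_gt(fs$summary$median[1], 0.5)
  # individuals with missing fasting values are excluded with a message
  cc <- sample_covariates(10, seed = 64)
  cc$fasting_insulin[3] <- NA
  expect_message(fs3 <- fasting_suppression(cc, bsv = FALSE), "excluded")
  expect_equal(nrow(fs3$individual), 9)
})

test_that("insulin-resistant individuals need more insulin than sensitive", {
  # ordering behind the reported 43.4 > 16.3 uU/mL contrast
  i_sens <- insulin_for_glucagon_inhibition(0.9, 5.0, 12.0)
  i_res <- insulin_for_glucagon_inhibition(0.9, 5.0, 4.5)
  expect_gt(i_res, i_sens)
})
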