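test_that("clamp design presets encode the study protocols", {
  d <- clamp_design("almby")
  expect_equal(d$t_end, 195)
  expect_equal(d$phases$target, c(5.0, 2.7, 5.0))
  hyper <- clamp_design("lundqvist_hyper")
  expect_equal(hyper$phases$offset, c(0, 3, 6, 9, 0))
  expect_false(any(hyper$phases$insulin))
  expect_equal(clamp_design("abrahamsson")$phases$duration[1], 110)
  expect_error(clamp_design("almby", hormone_times = c(-5, 10)), "within")
})

test_that("hypoglycemic forcing reaches the 2.7 mmol/L target", {
  fp <- make_forcing(clamp_design("almby"), ref_cov(), jitter_sd = 0,
                     insulin_jitter = 0)
  hypo <- fp$time >= 120 & fp$time <= 165
  expect_equal(min(fp$glucose[hypo]), 2.7, tolerance = 0.02)
  # insulin is at a hyperinsulinemic plateau during the infusion and
  # decays toward fasting in recovery
  expect_gt(min(fp$insulin[fp$insulin_time == 60]), 50)
  expect_lt(fp$insulin[fp$insulin_time == 195],
            fp$insulin[fp$insulin_time == 165])
})

test_that("hyperglycemic forcing plateaus near fasting + 9", {
  cov <- modifyList(ref_cov(), list(fasting_glucose = 5.0))
  fp <- make_forcing(clamp_design("lundqvist_hyper"), cov, jitter_sd = 0,
                     insulin_jitter = 0)
  last_step <- fp$time >= 150 & fp$time <= 165
  expect_equal(max(fp$glucose[last_step]), 14.0, tolerance = 0.02)
  # endogenous insulin rises with the glucose steps (no infusion)
  expect_gt(fp$insulin[fp$insulin_time == 150],
            2 * fp$insulin[fp$insulin_time == 0])
})

test_that("forcing is reproducible and deterministic without jitter", {
  d <- clamp_design("almby")
  f1 <- make_forcing(d, ref_cov(), seed = 9)
  f2 <- make_forcing(d, ref_cov(), seed = 9)
  expect_identical(f1, f2)
  f0 <- make_forcing(d, ref_cov(), jitter_sd = 0, insulin_jitter = 0)
  f0b <- make_forcing(d, ref_cov(), jitter_sd = 0, insulin_jitter = 0)
  expect_identical(f0, f0b)
})

test_that("record counts follow subjects x analytes x sampling times", {
  des <- clamp_design("almby", hormone_times = seq(0, 195, length.out = 9))
  expect_error(generate_dataset(list(des), n = 5, seed = 1,
                                covariates = ref_cov_df(5)), NA)
  d <- generate_dataset(list(des), n = 5, seed = 1,
                        covariates = ref_cov_df(5))
  expect_equal(sum(d$DVID %in% 1:3), 5 * 3 * 9)
  expect_equal(sum(d$DVID == 4), 5 * length(seq(0, 195, 5)))
  # one baseline record per analyte per occasion
  base <- d[d$TIME == 0 & d$DVID %in% 1:3, ]
  expect_equal(nrow(base), 5 * 3)
})

test_that("noise-free generation lies on the typical trajectory", {
  des <- clamp_design("almby")
  d <- generate_dataset(list(des), n = 1, covariates = ref_cov_df(1),
                        bsv = FALSE, bov = FALSE, residual = FALSE,
                        seed = 3, forcing_args = list(jitter_sd = 0,
                                                      insulin_jitter = 0))
  ind <- typical_individual()
  fp <- make_forcing(des, ref_cov(), jitter_sd = 0, insulin_jitter = 0)
  s <- simulate_individual(ind, fp, des$hormone_times)
  g <- d$DV[d$DVID == 1]
  expect_equal(g, s$glucagon, tolerance = 1e-3)
  expect_equal(d$DV[d$DVID == 3], s$cortisol, tolerance = 1e-3)
})

test_that("BLQ flagging responds to the limit of quantification", {
  des <- clamp_design("almby")
  d <- generate_dataset(list(des), n = 2, covariates = ref_cov_df(2),
                        seed = 4, loq = c(glucagon = 1e6))
  expect_true(all(d$BLQ[d$DVID == 1] == 1))
  d2 <- generate_dataset(list(des), n = 2, covariates = ref_cov_df(2),
                         seed = 4, loq = c(glucagon = 1e-6))
  expect_true(all(d2$BLQ[d2$DVID == 1] == 0))
  # flag implies value at or below the limit
  d3 <- generate_dataset(list(des), n = 6, seed = 5)
  blq <- d3[d3$BLQ == 1, ]
  expect_true(all(blq$DV <= blq$LOQ))
})

test_that("same seed gives identical datasets", {
  a <- generate_dataset("almby", n = 3, seed = 21)
  b <- generate_dataset("almby", n = 3, seed = 21)
  expect_identical(a, b)
})

test_that("generated hormone values stay in physiological ranges", {
  # the quantifiable (non-BLQ) records should fall inside the spans
  # observed in pooled clamp cohorts: glucagon 0.2-96 pmol/L, ACTH
  # 1.0-73 pmol/L, cortisol 73-819 nmol/L. The lognormal variability
  # model places a small upper tail beyond each empirical maximum, so
  # the requirement is the overwhelming majority (95%), not all.
  d <- generate_dataset(c("almby", "lundqvist_hyper"), n = 30, seed = 6)
  spans <- list(`1` = c(0.2, 96), `2` = c(1.0, 73), `3` = c(73, 819))
  for (code in 1:3) {
    x <- d[d$DVID == code & d$BLQ == 0, "DV"]
    frac <- mean(x >= spans[[code]][1] & x <= spans[[code]][2])
    expect_gte(frac, 0.95)
    # the central mass must be fully inside
    expect_true(all(quantile(x, c(0.05, 0.9)) >= spans[[code]][1] &
                      quantile(x, c(0.05, 0.9)) <= spans[[code]][2]))
  }
})
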