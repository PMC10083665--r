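# shared fixtures: all synthetic, built in code at test time

ref_cov <- function() {
  list(id = 1L, gir = 8.13, bmi = 37.3, homa_ir = 2.68, sex = "F",
       age = 40, fasting_glucose = 5.3, fasting_insulin = 10.4,
       body_fat = 37.0, waist_hip = 0.90, hba1c = 34)
}

ref_cov_df <- function(n = 1, gir = 8.13) {
  data.frame(id = seq_len(n), gir = gir, bmi = 37.3, homa_ir = 2.68,
             sex = "F", age = 40, fasting_glucose = 5.3,
             fasting_insulin = 10.4, body_fat = 37.0, waist_hip = 0.90,
             hba1c = 34)
}

# constant forcing profile at given glucose/insulin levels
const_forcing <- function(g = 5.3, i = 10.4, t_end = 300) {
  structure(list(time = c(0, t_end), glucose = c(g, g),
                 insulin = c(i, i), insulin_time = c(0, t_end),
                 dialect = "linear", t_end = t_end),
            class = "forcing_profile")
}

typical_individual <- function(p = hormone_params(), cov = ref_cov()) {
  realize_individual(p, cov)
}

# a single-record dataset on the fasting steady state, so the model
# prediction is the baseline concentration exactly (closed form)
steady_record_data <- function(p, dv, analyte = "glucagon", blq = 0L,
                               loq = NA_real_, time = 60) {
  code <- c(glucagon = 1L, acth = 2L, cortisol = 3L)[[analyte]]
  d <- rbind(
    data.frame(ID = 1L, OCC = 1L, TIME = c(0, 60, 120), DVID = 4L,
               DV = 5.3, BLQ = 0L, LOQ = NA_real_),
    data.frame(ID = 1L, OCC = 1L, TIME = c(0, 60, 120), DVID = 5L,
               DV = 10.4, BLQ = 0L, LOQ = NA_real_),
    data.frame(ID = 1L, OCC = 1L, TIME = time, DVID = code, DV = dv,
               BLQ = blq, LOQ = loq))
  d$GIR <- 8.13; d$GLUF <- 5.3; d$INSF <- 10.4
  class(d) <- c("clamp_data", "data.frame")
  d
}

# jittered-but-valid parameter draw for property tests
jitter_params <- function(scale = 0.3) {
  p <- hormone_params()
  for (nm in c("gn0", "kout_g", "ic50_g", "gamma_g", "ic50_i", "acth0",
               "kout_a", "t_half", "ic50_a", "cort0", "kout_c", "emax_c",
               "ec50_c", "gamma_c"))
    p[[nm]] <- p[[nm]] * exp(runif(1, -scale, scale))
  p$frac <- min(max(p$frac * exp(runif(1, -0.2, 0.2)), 0.05), 0.95)
  p$imax_a <- min(max(p$imax_a * exp(runif(1, -0.1, 0.05)), 0.5), 0.99)
  p
}
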