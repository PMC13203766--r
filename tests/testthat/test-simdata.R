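# Synthetic dyad and cohort generator.

test_that("invalid configurations are rejected", {
  expect_error(sim_config(duration_s = -5), class = "dyadflow_input_error")
  expect_error(sim_config(maternal_mean_rr = 0), class = "dyadflow_input_error")
  expect_error(sim_config(decel_variance_factor = 1.5),
               class = "dyadflow_input_error")
  expect_error(sim_config(coupling_lag_s = -1), class = "dyadflow_input_error")
  expect_error(cohort_spec(n_dyads = 1), class = "dyadflow_input_error")
  expect_error(cohort_spec(effects = list(c_sd = -1)),
               class = "dyadflow_input_error")
  expect_error(generate_dyad(sim_config()), class = "dyadflow_input_error")
})

test_that("beat times are strictly increasing, quantized, and RR-consistent", {
  d <- generate_dyad(sim_config(duration_s = 120), seed = 11)
  for (rr in list(d$maternal_rr, d$fetal_rr)) {
    expect_true(all(diff(rr$beat_time_s) > 0))
    expect_true(all(rr$rr_s > 0, na.rm = TRUE))
    # every beat time (hence every interval) on the 1 ms lattice
    expect_true(all(abs(rr$beat_time_s * 1000 -
                          round(rr$beat_time_s * 1000)) < 1e-6))
  }
  expect_length(d$quality_mask, 120)
})

test_that("quantization perturbs each interval by less than 2/f_ecg", {
  cfg <- sim_config(duration_s = 120, f_ecg_hz = 1000)
  d_coarse <- generate_dyad(cfg, seed = 3)
  cfg_fine <- cfg
  cfg_fine$f_ecg_hz <- 1e9 # effectively unquantized reference
  d_fine <- generate_dyad(cfg_fine, seed = 3)
  n <- min(nrow(d_coarse$fetal_rr), nrow(d_fine$fetal_rr)) - 1
  err <- abs(d_coarse$fetal_rr$rr_s[1:n] - d_fine$fetal_rr$rr_s[1:n])
  expect_lt(max(err), 2 / 1000)
  # beat order is preserved under quantization
  expect_true(all(diff(d_coarse$fetal_rr$beat_time_s) > 0))
})

test_that("quantization of a metronomic 0.75 s heart moves HR by under ~0.2 bpm", {
  # silence the oscillators and noise: a constant 80 bpm target
  cfg <- sim_config(
    duration_s = 200,
    maternal_oscillators = data.frame(freq_hz = 0.1, amp_bpm = 0),
    maternal_innovation_sd = 1e-9, maternal_fast_sd = 1e-9,
    maternal_accel_events = list(rate_per_min = 0, amp_bpm = 0,
                                 rise_s = 1, fall_s = 1),
    coupling_gain = 0, mask_drop_fraction = 0)
  d <- generate_dyad(cfg, seed = 7)
  hr <- 60 / d$maternal_rr$rr_s[!is.na(d$maternal_rr$rr_s)]
  expect_lt(max(abs(hr - 80)), hr_quantization_noise(80, 1000))
  expect_equal(hr_quantization_noise(80, 1000), 0.2133, tolerance = 1e-3)
})

test_that("uncoupled dyads are uncorrelated; generation is deterministic", {
  cfg <- sim_config(duration_s = 300, coupling_gain = 0,
                    decel_variance_factor = 1)
  d1 <- generate_dyad(cfg, seed = 21)
  d2 <- generate_dyad(cfg, seed = 21)
  expect_identical(d1$maternal_rr, d2$maternal_rr)
  expect_identical(d1$fetal_rr, d2$fetal_rr)
  expect_identical(d1$quality_mask, d2$quality_mask)

  p <- preprocess_dyad(d1, min_run_s = 0)
  ok <- p$mhr$valid & p$fhr$valid
  r <- cor(p$mhr$hr_bpm[ok], p$fhr$hr_bpm[ok])
  expect_lt(abs(r), 3 / sqrt(sum(ok) / 20)) # ~1 s effective samples
})

test_that("cohort labels have exact counts and reproducible structure", {
  spec <- cohort_spec(n_dyads = 118, stress_fraction = 0.5, seed = 5)
  ch <- generate_cohort(spec, simulate_recordings = FALSE)$cohort
  expect_equal(sum(ch$group == "stressed"), 59)
  expect_equal(sum(ch$group == "control"), 59)
  expect_true(all(ch$pss[ch$group == "stressed"] >= 19))
  expect_true(all(ch$pss[ch$group == "control"] < 19))
  ch2 <- generate_cohort(spec, simulate_recordings = FALSE)$cohort
  expect_identical(ch, ch2)
})

test_that("null effect map gives equal group gains; cortisol correlation holds", {
  null_spec <- cohort_spec(n_dyads = 400, effects = list(
    stress = 0, sex_stress = 0, c_sd = 0.06, cortisol_cor = 0), seed = 8)
  ch <- generate_cohort(null_spec, simulate_recordings = FALSE)$cohort
  p <- t.test(coupling_gain ~ group, data = ch)$p.value
  expect_gt(p, 0.01)

  cor_spec <- cohort_spec(n_dyads = 500, effects = list(
    stress = 0, sex_stress = 0, cortisol_cor = 0.3), seed = 9)
  ch <- generate_cohort(cor_spec, simulate_recordings = FALSE)$cohort
  r <- cor(ch$coupling_gain, log(ch$cortisol))
  expect_lt(abs(r - 0.3), 0.1)
})

test_that("decel variance factor suppresses fetal variance in truth epochs", {
  cfg <- sim_config(duration_s = 600, coupling_gain = 0,
                    decel_variance_factor = 0.3)
  d <- generate_dyad(cfg, seed = 31)
  fhr <- rr_to_hr(d$fetal_rr, fs = 20, duration_s = 600)
  td <- d$truth_decel
  ok <- fhr$valid
  v_dec <- var(fhr$hr_bpm[ok & td])
  v_acc <- var(fhr$hr_bpm[ok & !td])
  expect_lt(v_dec, v_acc)
})

test_that("RR round trip through CSV is lossless and validated", {
  d <- generate_dyad(sim_config(duration_s = 60), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_rr_csv(d$fetal_rr, path)
  back <- read_rr_csv(path)
  expect_equal(back$beat_time_s, d$fetal_rr$beat_time_s, tolerance = 1e-12)
  bad <- d$fetal_rr
  bad$rr_s[1] <- bad$rr_s[1] + 1
  expect_error(write_rr_csv(bad, path), class = "dyadflow_input_error")
})
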