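# RR -> HR conversion, filtering, masking, exclusion.

test_that("zero-order hold reproduces piecewise-constant HR", {
  # constant maternal-like RR
  hr <- rr_to_hr(constant_rr(0.75, 30), fs = 20)
  expect_equal(unique(hr$hr_bpm[hr$valid]), 80)
  # constant fetal-like RR: ~139.5 bpm, one cardiac cycle ~0.43 s at 140 bpm
  hrf <- rr_to_hr(constant_rr(0.43, 30), fs = 20)
  expect_true(all(abs(hrf$hr_bpm[hrf$valid] - 60 / 0.43) < 1e-9))
  expect_equal(cardiac_cycle_s(140), 0.43, tolerance = 0.005)
  # hand-computed two-interval case: 0.5 s then 1.0 s at fs = 20
  hr2 <- rr_to_hr(rr_from_intervals(c(0.5, 1.0)), fs = 20)
  expect_equal(hr2$hr_bpm[1:10], rep(120, 10))
  expect_equal(hr2$hr_bpm[11:30], rep(60, 20))
  expect_false(any(hr2$valid[-(1:30)]))
  expect_error(rr_to_hr(constant_rr(0.75, 0.5), fs = 1),
               class = "dyadflow_input_error")
})

test_that("HR means stay within the range of instantaneous rates", {
  set.seed(4)
  ints <- runif(200, 0.4, 1.0)
  hr <- rr_to_hr(rr_from_intervals(ints), fs = 20)
  m <- mean(hr$hr_bpm[hr$valid])
  expect_gte(m, 60 / max(ints))
  expect_lte(m, 60 / min(ints))
})

test_that("moving average: identity on constants, window size, cancellation", {
  hc <- hr_series(rep(80, 200), fs = 20)
  f <- hr_moving_average(hc, 2.5)
  expect_equal(unique(f$hr_bpm[f$valid]), 80)
  expect_equal(round(2.5 * 20), 50)
  expect_equal(sum(f$valid), 200 - 50 + 1)
  # alternating +-1 around 80, even window: exactly 80 wherever valid
  ha <- hr_series(80 + rep(c(1, -1), 100), fs = 20)
  fa <- hr_moving_average(ha, 0.1) # 2-sample window
  expect_true(all(abs(fa$hr_bpm[fa$valid] - 80) < 1e-12))
  expect_error(hr_moving_average(hc, 0.01), class = "dyadflow_input_error")
  expect_error(hr_moving_average(f, 1), class = "dyadflow_input_error")
})

test_that("moving average is linear, shift-equivariant, and gap-respecting", {
  set.seed(5)
  v <- rnorm(300, 100, 5)
  w <- rnorm(300, 120, 3)
  ma <- function(x) hr_moving_average(hr_series(x, fs = 10), 1)$hr_bpm
  lhs <- ma(2 * v + 3 * w)
  rhs <- 2 * ma(v) + 3 * ma(w)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  sh <- ma(c(v[-(1:7)], v[1:7]))
  expect_equal(sh[5:200], ma(v)[12:207], tolerance = 1e-9)
  # invalid samples never become valid
  valid <- rep(TRUE, 300)
  valid[100:110] <- FALSE
  f <- hr_moving_average(hr_series(v, fs = 10, valid = valid), 1)
  expect_false(any(f$valid[96:114]))
  expect_true(all(which(f$valid) %in% which(valid)))
})

test_that("quality mask invalidates flagged seconds and short runs", {
  hr <- hr_series(rep(80, 400), fs = 20) # 20 s
  m <- rep(TRUE, 20)
  out <- apply_quality_mask(hr, m, min_run_s = 0)
  expect_equal(out$valid, hr$valid)
  m[5] <- FALSE
  out <- apply_quality_mask(hr, m, min_run_s = 0)
  expect_equal(sum(hr$valid) - sum(out$valid), 20)
  # alternating good/bad seconds with a 10 s minimum: everything dies
  alt <- rep(c(TRUE, FALSE), 10)
  out <- apply_quality_mask(hr, alt, min_run_s = 10)
  expect_false(any(out$valid))
  expect_error(apply_quality_mask(hr, m[1:10]),
               class = "dyadflow_input_error")
})

test_that("dyad exclusion triggers on low fetal HR fraction", {
  mhr <- hr_series(rep(80, 200), fs = 20)
  keep <- dyad_exclusion(hr_series(rep(140, 200), fs = 20), mhr)
  expect_false(keep$excluded)
  expect_equal(keep$low_fraction, 0)
  drop <- dyad_exclusion(hr_series(rep(80, 200), fs = 20), mhr)
  expect_true(drop$excluded)
  expect_equal(drop$low_fraction, 1)
  # 6% low at threshold 5%
  v <- c(rep(90, 12), rep(140, 188))
  mid <- dyad_exclusion(hr_series(v, fs = 20), mhr, max_low_fraction = 0.05)
  expect_true(mid$excluded)
  expect_equal(mid$low_fraction, 0.06)
  none <- hr_series(rep(140, 10), fs = 20, valid = rep(FALSE, 10))
  expect_error(dyad_exclusion(none, hr_series(rep(80, 10), fs = 20)),
               class = "dyadflow_input_error")
})
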