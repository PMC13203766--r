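# Acceleration/deceleration labelling and event statistics.

test_that("monotone, constant and sinusoidal signals label as expected", {
  ramp <- label_epochs(filtered_series(1:50, fs = 1, tau = 1))
  ev <- epoch_events(ramp)
  expect_equal(nrow(ev[ev$label == "accel", ]), 1)
  expect_equal(ev$n_samples[ev$label == "accel"], 49)
  expect_equal(as.character(ramp$label[50]), "neither")

  const <- label_epochs(filtered_series(rep(3, 40), fs = 1, tau = 1))
  expect_true(all(const$label == "neither"))
  st <- epoch_stats(const)
  expect_equal(st$n_accel_events + st$n_decel_events, 0)
  expect_true(st$ratio_undefined)

  x <- cos(2 * pi * seq(0, 1, length.out = 1000))
  sine <- label_epochs(filtered_series(x[-1000], fs = 1, tau = 1))
  st <- epoch_stats(sine)
  expect_equal(st$n_accel_events, 1)
  expect_equal(st$n_decel_events, 1)
  expect_equal(st$accel_frac_time, 0.5, tolerance = 0.01)
  expect_equal(st$decel_frac_time, 0.5, tolerance = 0.01)
})

test_that("negating the signal swaps accel and decel exactly", {
  set.seed(6)
  v <- cumsum(rnorm(300))
  a <- label_epochs(filtered_series(v, fs = 1, tau = 1))
  b <- label_epochs(filtered_series(-v, fs = 1, tau = 1))
  expect_equal(as.character(a$label) == "accel",
               as.character(b$label) == "decel")
  expect_equal(as.character(a$label) == "decel",
               as.character(b$label) == "accel")
  sa <- epoch_stats(a)
  sb <- epoch_stats(b)
  expect_equal(sa$n_accel_events, sb$n_decel_events)
})

test_that("event fractions follow counts; symmetric sawtooth has ratio one", {
  saw <- rep(c(1, 2, 3, 2), 25)
  st <- epoch_stats(label_epochs(filtered_series(saw, fs = 1, tau = 1)))
  expect_equal(st$decel_accel_ratio_event, 1)
  # 3 accel / 2 decel events -> event fraction 0.6
  v <- c(1, 2, 1, 2, 1, 2) # alternating
  st2 <- epoch_stats(label_epochs(filtered_series(v, fs = 1, tau = 1)))
  expect_equal(st2$accel_frac_event,
               st2$n_accel_events / (st2$n_accel_events + st2$n_decel_events))
  # time-point fractions never exceed 1 and drop below 1 with zero-derivative
  flat <- c(1, 2, 2, 3, 3, 3, 2, 1)
  st3 <- epoch_stats(label_epochs(filtered_series(flat, fs = 1, tau = 1)))
  expect_lt(st3$accel_frac_time + st3$decel_frac_time, 1)
})

test_that("invalid gaps break events and are labelled invalid", {
  v <- c(1:10, 11:2)
  valid <- rep(TRUE, 20)
  valid[10] <- FALSE
  m <- label_epochs(filtered_series(v, fs = 1, tau = 1, valid = valid))
  expect_equal(as.character(m$label[10]), "invalid")
  expect_true(is.na(m$event_id[10]))
  ev <- epoch_events(m)
  expect_true(all(ev$n_samples >= 1))
  expect_error(label_epochs(filtered_series(v, fs = 1, tau = 1,
                                            valid = rep(FALSE, 20))),
               class = "dyadflow_input_error")
})

test_that("smaller tau yields more, shorter events on simulated HR", {
  d <- generate_dyad(sim_config(duration_s = 300), seed = 41)
  p <- preprocess_dyad(d)
  taus <- c(0.5, 1, 2.5, 5)
  res <- t(vapply(taus, function(tau) {
    ev <- epoch_events(label_epochs(hr_moving_average(p$fhr, tau)))
    ev <- ev[ev$label %in% c("accel", "decel"), ]
    c(n = nrow(ev), mean_dur = mean(ev$duration_s))
  }, numeric(2)))
  expect_true(all(diff(res[, "n"]) < 0)) # fewer events as tau grows
  expect_true(all(diff(res[, "mean_dur"]) > 0)) # longer events as tau grows
})

test_that("fetal accelerations outnumber decelerations at tau 2.5 s", {
  # direction-only check on the default (asymmetric-transient) generator
  fr <- vapply(61:68, function(s) {
    d <- generate_dyad(sim_config(duration_s = 300), seed = s)
    p <- preprocess_dyad(d)
    st <- epoch_stats(label_epochs(hr_moving_average(p$fhr, 2.5)))
    c(st$accel_frac_time, st$decel_frac_time)
  }, numeric(2))
  expect_gt(mean(fr[1, ]), mean(fr[2, ]))
})
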