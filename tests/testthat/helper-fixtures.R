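# Shared fixtures, built in code at test time.

# RR tibble with constant intervals
constant_rr <- function(rr = 0.75, duration = 30) {
  beats <- seq(0, duration, by = rr)
  tibble::tibble(beat_time_s = beats, rr_s = c(diff(beats), NA))
}

# RR tibble from explicit interval sequence
rr_from_intervals <- function(intervals, t0 = 0) {
  beats <- t0 + c(0, cumsum(intervals))
  tibble::tibble(beat_time_s = beats, rr_s = c(diff(beats), NA))
}

# filtered-tagged series straight from values (lag = tau * fs samples)
filtered_series <- function(values, fs = 1, tau = 1, valid = NULL) {
  hr_series(values, fs = fs, tau = tau, valid = valid)
}

# small entropy params for fast tests
fast_params <- function(...) {
  entropy_params(n_surrogates = 5, min_vectors = 50, ...)
}

# band-mean net TE of one preprocessed dyad over a small tau grid
band_mean_nette <- function(prep, params, n_tau = 4, band = c(0.5, 2.5)) {
  taus <- exp(seq(log(band[1]), log(band[2]), length.out = n_tau))
  mean(vapply(taus, function(tau) {
    fm <- hr_moving_average(prep$mhr, tau)
    ff <- hr_moving_average(prep$fhr, tau)
    net_transfer_entropy(fm, ff, params)$net_te
  }, numeric(1)))
}

# brute-force O(n^2) sample-entropy oracle: direct template counting on a
# fully valid series, lag `L`, tolerance r (absolute), Chebyshev distance
sampen_oracle <- function(x, m, L, r) {
  n <- length(x)
  starts <- seq_len(n - m * L)
  a <- 0L
  b <- 0L
  for (i in seq_along(starts)) {
    for (j in seq_along(starts)) {
      if (j <= i) next
      if (abs(starts[i] - starts[j]) < L) next # same Theiler rule
      dm <- max(abs(x[starts[i] + (0:(m - 1)) * L] -
                      x[starts[j] + (0:(m - 1)) * L]))
      if (dm <= r) {
        b <- b + 1L
        if (max(dm, abs(x[starts[i] + m * L] - x[starts[j] + m * L])) <= r) {
          a <- a + 1L
        }
      }
    }
  }
  -log(a / b)
}
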