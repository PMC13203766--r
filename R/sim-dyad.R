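# Synthetic dyad generation: continuous-time target heart rates integrated to
# beat times (integrate-and-fire on cumulative cardiac phase), then quantized
# to the ECG timing resolution.

# sum of AR(1) ("Ornstein-Uhlenbeck on a grid") components with stationary SD
# `total_sd`, split equally across correlation times
ar_mixture <- function(n, dt, corr_times, total_sd) {
  k <- length(corr_times)
  out <- numeric(n)
  comp_var <- total_sd^2 / k
  for (tc in corr_times) {
    a <- exp(-dt / tc)
    innov_sd <- sqrt(comp_var * (1 - a^2))
    out <- out + as.numeric(
      stats::filter(rnorm(n, sd = innov_sd), a, method = "recursive"))
  }
  out
}

# asymmetric accelerative transient: half-cosine rise over rise_s, fall over
# fall_s; rise_s > fall_s yields more time points with positive derivative.
event_bumps <- function(t, dt, duration, ev) {
  n_ev <- rpois(1, ev$rate_per_min * duration / 60)
  out <- numeric(length(t))
  if (n_ev == 0) return(out)
  onsets <- runif(n_ev, 0, duration)
  shape_t <- seq(0, ev$rise_s + ev$fall_s, by = dt)
  shape <- ifelse(shape_t <= ev$rise_s,
                  0.5 * (1 - cos(pi * shape_t / ev$rise_s)),
                  0.5 * (1 + cos(pi * (shape_t - ev$rise_s) / ev$fall_s)))
  for (o in onsets) {
    i0 <- floor(o / dt) + 1L
    idx <- i0:min(length(t), i0 + length(shape) - 1L)
    out[idx] <- out[idx] + ev$amp_bpm * shape[seq_along(idx)]
  }
  out
}

# asymmetric slew limiter: upward HR movement is rate-limited (bpm/s),
# downward movement is free, so ascents take longer than descents — the
# mechanism behind the predominance of accelerations over decelerations.
slew_limit <- function(x, up_max, dt) {
  if (!is.finite(up_max)) return(x)
  step <- up_max * dt
  y <- x
  for (i in 2:length(x)) {
    dy <- x[i] - y[i - 1]
    y[i] <- y[i - 1] + min(dy, step)
  }
  y
}

# trailing moving average over a window of `w` samples (causal)
trailing_ma <- function(x, w) {
  cs <- cumsum(x)
  out <- c(cs[seq_len(w)] / seq_len(w),
           (cs[(w + 1):length(x)] - cs[1:(length(x) - w)]) / w)
  out
}

# centered moving average, full-window only (NA-padded at edges)
centered_ma_full <- function(x, w) {
  n <- length(x)
  left <- floor((w - 1) / 2)
  out <- rep(NA_real_, n)
  cs <- cumsum(x)
  k <- seq_len(n)
  lo <- k - left
  hi <- lo + w - 1L
  ok <- lo >= 1L & hi <= n
  out[ok] <- (cs[hi[ok]] - ifelse(lo[ok] > 1L, cs[lo[ok] - 1L], 0)) / w
  out
}

# integrate-and-fire: beat times where cumulative phase HR/60 crosses integers
beats_from_hr <- function(hr_bpm, dt) {
  rate <- pmax(hr_bpm, 20) / 60 # beats per second, floored away from zero
  phase <- cumsum(rate * dt)
  n_beats <- floor(phase[length(phase)])
  if (n_beats < 2) return(numeric(0))
  targets <- seq_len(n_beats)
  idx <- findInterval(targets, phase) # last sample with phase < target
  phase0 <- c(0, phase)
  t_grid <- seq_along(phase) * dt
  frac <- (targets - phase0[idx + 1L]) / (phase[idx + 1L] - phase0[idx + 1L])
  (t_grid[idx + 1L] - dt) + frac * dt
}

#' Generate one synthetic maternal--fetal dyad recording
#'
#' Simulates the maternal and fetal target heart-rate processes described in
#' [sim_config()], converts each to a beat sequence by integrate-and-fire on
#' the cumulative cardiac phase, quantizes beat times to the ECG timing
#' resolution `1/f_ecg_hz`, and draws a per-second quality mask.
#'
#' The fetal target HR receives the coupling drive
#' `c * (mbar(t - delta) - mean(mbar))`, where `mbar` is the maternal HR
#' moving-averaged over a window `delta` — an additive innovation on the fetal
#' process carrying maternal information at lag `delta`. During ground-truth
#' maternal deceleration epochs (negative derivative of the maternal target
#' HR smoothed at `truth_epoch_tau_s`) the variance of the entire fetal
#' fluctuation is multiplied by `decel_variance_factor`.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (overrides `config$seed`).
#' @return An object of class `dyad_recording`: a list with tibbles
#'   `maternal_rr` and `fetal_rr` (columns `beat_time_s`, `rr_s`; `rr_s` is
#'   the interval to the *next* beat, `NA` on the last row), logical
#'   `quality_mask` (one entry per second), the generating `config` (with the
#'   realized seed), and `truth_decel` (ground-truth maternal deceleration
#'   indicator on the internal grid, with attribute `fs`).
#' @export
#' @examples
#' d <- generate_dyad(sim_config(duration_s = 60), seed = 1)
#' head(d$fetal_rr)
generate_dyad <- function(config, seed = NULL) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be a sim_config.", class = "dyadflow_input_error")
  }
  seed <- seed %||% config$seed
  if (is.null(seed)) {
    abort("a seed is required (in `config$seed` or `seed`).",
          class = "dyadflow_input_error")
  }
  with_seed(seed, {
    dt <- 1 / config$internal_fs_hz
    duration <- config$duration_s
    t <- seq(dt, duration, by = dt)
    n <- length(t)

    # --- maternal target HR ---
    m_mean <- 60 / config$maternal_mean_rr
    m_det <- rep(m_mean, n)
    for (i in seq_len(nrow(config$maternal_oscillators))) {
      o <- config$maternal_oscillators[i, ]
      m_det <- m_det + o$amp_bpm * sin(2 * pi * o$freq_hz * t + runif(1, 0, 2 * pi))
    }
    m_osc <- m_det - m_mean
    m_slow <- event_bumps(t, dt, duration, config$maternal_accel_events) +
      ar_mixture(n, dt, config$noise_corr_times_s,
                 config$maternal_innovation_sd)
    m_fast <- ar_mixture(n, dt, config$fast_noise_corr_s,
                         config$maternal_fast_sd)
    # slew asymmetry acts on the slow stochastic part; oscillators and fast
    # symmetric variability ride on top unlimited
    m_hr <- m_mean + m_osc + m_fast +
      slew_limit(m_slow, config$maternal_slew_up_bpm_s, dt)

    # ground-truth maternal deceleration epochs from the smoothed target HR
    w_truth <- max(1L, round(config$truth_epoch_tau_s / dt))
    m_smooth <- centered_ma_full(m_hr, w_truth)
    d_truth <- c(diff(m_smooth), NA)
    truth_decel <- !is.na(d_truth) & d_truth < 0

    # --- fetal target HR ---
    f_mean <- 60 / config$fetal_mean_rr
    f_det <- rep(f_mean, n)
    for (i in seq_len(nrow(config$fetal_oscillators))) {
      o <- config$fetal_oscillators[i, ]
      f_det <- f_det + o$amp_bpm * sin(2 * pi * o$freq_hz * t + runif(1, 0, 2 * pi))
    }
    f_slow <- event_bumps(t, dt, duration, config$fetal_accel_events) +
      ar_mixture(n, dt, config$noise_corr_times_s,
                 config$fetal_innovation_sd)
    f_fast <- ar_mixture(n, dt, config$fast_noise_corr_s,
                         config$fetal_fast_sd)

    coupling <- numeric(n)
    if (config$coupling_gain > 0) {
      w_c <- max(1L, round(config$coupling_lag_s / dt))
      mbar <- trailing_ma(m_hr, w_c)
      lag_n <- round(config$coupling_lag_s / dt)
      m_lag <- c(rep(mbar[1], lag_n), mbar)[seq_len(n)]
      coupling <- config$coupling_gain * (m_lag - mean(mbar))
    }
    # state-contingent variance: the whole fetal fluctuation is scaled so
    # its variance is multiplied by rho inside ground-truth maternal
    # deceleration epochs; the maternal coupling drive stays untouched
    rho_scale <- ifelse(truth_decel, sqrt(config$decel_variance_factor), 1)
    f_fluct <- (f_det - f_mean) + f_fast +
      slew_limit(f_slow, config$fetal_slew_up_bpm_s, dt)
    f_hr <- f_mean + rho_scale * f_fluct + coupling

    # --- beats + quantization ---
    q <- 1 / config$f_ecg_hz
    m_beats <- round(beats_from_hr(m_hr, dt) / q) * q
    f_beats <- round(beats_from_hr(f_hr, dt) / q) * q

    mask_len <- ceiling(duration)
    mask <- rep(TRUE, mask_len)
    n_bad <- round(config$mask_drop_fraction * mask_len)
    if (n_bad > 0) mask[sample.int(mask_len, n_bad)] <- FALSE

    cfg <- config
    cfg$seed <- seed
    structure(
      list(maternal_rr = new_rr_series(m_beats),
           fetal_rr = new_rr_series(f_beats),
           quality_mask = mask,
           config = cfg,
           truth_decel = structure(truth_decel, fs = config$internal_fs_hz)),
      class = "dyad_recording")
  })
}

new_rr_series <- function(beat_times) {
  if (length(beat_times) < 2 || any(diff(beat_times) <= 0)) {
    abort("beat times must be strictly increasing (>= 2 beats).",
          class = "dyadflow_input_error")
  }
  tibble(beat_time_s = beat_times,
         rr_s = c(diff(beat_times), NA_real_))
}

#' @export
print.dyad_recording <- function(x, ...) {
  cat("<dyad_recording>\n")
  cat(sprintf("  maternal: %d beats | fetal: %d beats | %d s, %.0f%% seconds usable\n",
              nrow(x$maternal_rr), nrow(x$fetal_rr),
              length(x$quality_mask), 100 * mean(x$quality_mask)))
  cat(sprintf("  truth: coupling gain %.3g, lag %.2g s, rho %.2g\n",
              x$config$coupling_gain, x$config$coupling_lag_s,
              x$config$decel_variance_factor))
  invisible(x)
}

#' Read and write RR-interval CSV files
#'
#' RR series are exchanged as CSV with columns `beat_time_s` and `rr_s`
#' (interval to the next beat; last row `NA`).
#'
#' @param rr A tibble with columns `beat_time_s`, `rr_s`.
#' @param path File path.
#' @return `read_rr_csv()` returns the validated tibble; `write_rr_csv()`
#'   returns `path` invisibly.
#' @export
write_rr_csv <- function(rr, path) {
  validate_rr(rr)
  readr::write_csv(rr[, c("beat_time_s", "rr_s")], path)
  invisible(path)
}

#' @rdname write_rr_csv
#' @export
read_rr_csv <- function(path) {
  rr <- readr::read_csv(path, col_types = readr::cols(
    beat_time_s = readr::col_double(), rr_s = readr::col_double()))
  validate_rr(rr)
  rr
}

validate_rr <- function(rr) {
  if (!all(c("beat_time_s", "rr_s") %in% names(rr))) {
    abort("RR series needs columns beat_time_s and rr_s.",
          class = "dyadflow_input_error")
  }
  if (nrow(rr) < 2 || any(diff(rr$beat_time_s) <= 0)) {
    abort("beat times must be strictly increasing (>= 2 beats).",
          class = "dyadflow_input_error")
  }
  d <- diff(rr$beat_time_s)
  r <- rr$rr_s[-nrow(rr)]
  if (any(abs(d - r) > 1e-9, na.rm = TRUE)) {
    abort("rr_s must equal diff(beat_time_s) within 1e-9 s.",
          class = "dyadflow_input_error")
  }
  invisible(rr)
}
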