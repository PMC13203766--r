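#' Configuration for a synthetic maternal--fetal dyad recording
#'
#' Defines the generating model for one simulated dyad: two continuous-time
#' target heart-rate processes (deterministic oscillators + multi-timescale
#' autoregressive noise + asymmetric accelerative transients) that are
#' integrated to beat times, with unidirectional maternal-to-fetal coupling
#' and a state-contingent reduction of fetal innovation variance during
#' maternal decelerations.
#'
#' The default maternal heart beats at 80 bpm (mean RR 0.75 s) and the fetal
#' heart at ~140 bpm (mean RR 0.43 s). Oscillators place a respiratory
#' (~0.25 Hz) and a Mayer-band (~0.1 Hz) component on the maternal heart and
#' a fetal-breathing-band (~0.8 Hz) plus slow component on the fetal heart.
#' The stochastic part of each target HR is a sum of AR(1) processes with
#' log-spaced correlation times, approximating the 1/f-like spectrum of real
#' heart-rate variability. Accelerative transients (slow rise, faster fall)
#' reproduce the empirical predominance of accelerations over decelerations.
#'
#' @param duration_s Recording length in seconds (default 2400 s = 40 min,
#'   the nominal length of one antepartum recording).
#' @param maternal_mean_rr,fetal_mean_rr Mean RR interval of each heart (s).
#' @param maternal_oscillators,fetal_oscillators Data frame with columns
#'   `freq_hz` and `amp_bpm`: deterministic sinusoidal HR components.
#' @param maternal_innovation_sd,fetal_innovation_sd Stationary standard
#'   deviation (bpm) of the stochastic HR component of each heart.
#' @param noise_corr_times_s Correlation times (s) of the AR(1) components
#'   that make up the slow stochastic HR part; variance is split equally.
#' @param fast_noise_corr_s,maternal_fast_sd,fetal_fast_sd Correlation time
#'   (s) and per-heart SD (bpm) of an additional fast, symmetric variability
#'   component that is not slew-limited; it sets the information floor at
#'   sub-second scales.
#' @param maternal_accel_events,fetal_accel_events List with `rate_per_min`,
#'   `amp_bpm`, `rise_s`, `fall_s`: Poisson-timed accelerative HR transients.
#' @param maternal_slew_up_bpm_s,fetal_slew_up_bpm_s Maximum upward HR slew
#'   rate (bpm/s; `Inf` disables). Ascents are rate-limited while descents
#'   are free, which stretches accelerations in time — the source of the
#'   acceleration predominance seen in epoch statistics.
#' @param coupling_gain Dimensionless gain `c >= 0` of the maternal-to-fetal
#'   drive. `c = 0` makes the fetal process statistically independent of the
#'   maternal process.
#' @param coupling_lag_s Coupling lag `delta >= 0` (s): fetal target HR at
#'   time `t` receives `c * (mbar(t - delta) - mean)`, where `mbar` is the
#'   maternal HR moving-averaged over a window `delta`.
#' @param decel_variance_factor Factor `rho` in (0, 1] multiplying the
#'   variance of the fetal HR fluctuation during ground-truth maternal
#'   deceleration epochs.
#' @param truth_epoch_tau_s Time scale (s) of the moving average applied to
#'   the maternal target HR (pre-quantization, on the internal grid) when
#'   defining ground-truth deceleration epochs — deliberately independent of
#'   the epoch estimator under test.
#' @param mask_drop_fraction Fraction of 1 s windows dropped at random from
#'   the quality mask (emulates signal-quality exclusions).
#' @param f_ecg_hz ECG sampling rate (Hz) used to quantize beat times; RR
#'   intervals inherit a timing resolution of `1/f_ecg_hz` and a worst-case
#'   interval error below `2/f_ecg_hz`.
#' @param internal_fs_hz Internal simulation grid rate (Hz).
#' @param seed Default RNG seed for [generate_dyad()]; any seed passed there
#'   takes precedence.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_dyad()], [cohort_spec()]
#' @export
#' @examples
#' cfg <- sim_config(duration_s = 120, seed = 1)
#' cfg$coupling_gain
sim_config <- function(duration_s = 2400,
                       maternal_mean_rr = 0.75,
                       fetal_mean_rr = 0.43,
                       maternal_oscillators = data.frame(
                         freq_hz = c(0.25, 0.10), amp_bpm = c(0.8, 0.8)),
                       fetal_oscillators = data.frame(
                         freq_hz = c(0.80, 0.05), amp_bpm = c(1.5, 2.0)),
                       maternal_innovation_sd = 2.5,
                       fetal_innovation_sd = 3.5,
                       noise_corr_times_s = c(0.5, 2, 8, 32),
                       fast_noise_corr_s = 0.3,
                       maternal_fast_sd = 0.9,
                       fetal_fast_sd = 1.5,
                       maternal_accel_events = list(
                         rate_per_min = 2, amp_bpm = 4, rise_s = 5, fall_s = 3),
                       fetal_accel_events = list(
                         rate_per_min = 3, amp_bpm = 7, rise_s = 5, fall_s = 3),
                       maternal_slew_up_bpm_s = 1,
                       fetal_slew_up_bpm_s = 1,
                       coupling_gain = 0.6,
                       coupling_lag_s = 1.5,
                       decel_variance_factor = 1,
                       truth_epoch_tau_s = 2.5,
                       mask_drop_fraction = 0.05,
                       f_ecg_hz = 1000,
                       internal_fs_hz = 20,
                       seed = NULL) {
  check_number(duration_s, "duration_s", lower = 1e-9)
  check_number(maternal_mean_rr, "maternal_mean_rr", lower = 1e-9)
  check_number(fetal_mean_rr, "fetal_mean_rr", lower = 1e-9)
  check_number(coupling_gain, "coupling_gain", lower = 0)
  check_number(coupling_lag_s, "coupling_lag_s", lower = 0)
  check_number(decel_variance_factor, "decel_variance_factor",
               lower = 1e-9, upper = 1)
  check_number(mask_drop_fraction, "mask_drop_fraction", lower = 0, upper = 1)
  check_number(f_ecg_hz, "f_ecg_hz", lower = 1)
  check_number(internal_fs_hz, "internal_fs_hz", lower = 1)
  for (osc in list(maternal_oscillators, fetal_oscillators)) {
    if (!is.data.frame(osc) || !all(c("freq_hz", "amp_bpm") %in% names(osc))) {
      abort("oscillators must be data frames with freq_hz and amp_bpm.",
            class = "dyadflow_input_error")
    }
  }
  for (ev in list(maternal_accel_events, fetal_accel_events)) {
    stopifnot(all(c("rate_per_min", "amp_bpm", "rise_s", "fall_s") %in%
                    names(ev)))
  }
  if (any(noise_corr_times_s <= 0)) {
    abort("noise_corr_times_s must be positive.",
          class = "dyadflow_input_error")
  }
  structure(
    list(duration_s = duration_s,
         maternal_mean_rr = maternal_mean_rr,
         fetal_mean_rr = fetal_mean_rr,
         maternal_oscillators = as_tibble(maternal_oscillators),
         fetal_oscillators = as_tibble(fetal_oscillators),
         maternal_innovation_sd = maternal_innovation_sd,
         fetal_innovation_sd = fetal_innovation_sd,
         noise_corr_times_s = noise_corr_times_s,
         fast_noise_corr_s = fast_noise_corr_s,
         maternal_fast_sd = maternal_fast_sd,
         fetal_fast_sd = fetal_fast_sd,
         maternal_accel_events = maternal_accel_events,
         fetal_accel_events = fetal_accel_events,
         maternal_slew_up_bpm_s = maternal_slew_up_bpm_s,
         fetal_slew_up_bpm_s = fetal_slew_up_bpm_s,
         coupling_gain = coupling_gain,
         coupling_lag_s = coupling_lag_s,
         decel_variance_factor = decel_variance_factor,
         truth_epoch_tau_s = truth_epoch_tau_s,
         mask_drop_fraction = mask_drop_fraction,
         f_ecg_hz = f_ecg_hz,
         internal_fs_hz = internal_fs_hz,
         seed = seed),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  duration: %.0f s | mHR %.0f bpm, fHR %.0f bpm\n",
              x$duration_s, 60 / x$maternal_mean_rr, 60 / x$fetal_mean_rr))
  cat(sprintf("  coupling: gain %.3g, lag %.2g s | decel variance factor %.2g\n",
              x$coupling_gain, x$coupling_lag_s, x$decel_variance_factor))
  cat(sprintf("  beat quantization: 1/%g s\n", x$f_ecg_hz))
  invisible(x)
}

#' Specification of a synthetic cohort of dyads
#'
#' Describes the cohort-level structure layered on top of per-dyad recordings:
#' group sizes, how the maternal-to-fetal coupling gain depends on stress
#' group and fetal sex, and how stress biomarkers and neurodevelopmental
#' outcomes are generated.
#'
#' The effect map is a free modelling choice (the underlying study reports
#' coupling effects on model coefficients, not in generator units); defaults
#' are chosen so that group contrasts are detectable at cohort scale while
#' per-dyad gains stay in a physiological-looking range.
#'
#' @param n_dyads Number of dyads (>= 2); default 118.
#' @param stress_fraction Fraction classified as stressed (default 0.5, i.e.
#'   59/59 at n = 118). Counts are exact: `round(n_dyads * stress_fraction)`.
#' @param male_fraction Fraction of male fetuses (default 0.415).
#' @param effects List of cohort-level effects:
#'   \describe{
#'     \item{c_base}{baseline coupling gain (control, female)}
#'     \item{c_sd}{between-dyad SD of the gain}
#'     \item{stress}{additive stress main effect on the gain}
#'     \item{sex_stress}{additive male-x-stressed interaction on the gain}
#'     \item{cortisol_cor}{correlation between the gain's dyad-level residual
#'       and log hair cortisol}
#'     \item{outcome_sd}{SD of the (null) Bayley composite outcomes}
#'   }
#' @param dyad Base [sim_config()] shared by all dyads (its coupling gain is
#'   overridden per dyad).
#' @param seed RNG seed; the full cohort is reproducible given the spec.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_dyads = 118,
                        stress_fraction = 0.5,
                        male_fraction = 0.415,
                        effects = list(),
                        dyad = sim_config(),
                        seed = NULL) {
  check_number(n_dyads, "n_dyads", lower = 2)
  check_number(stress_fraction, "stress_fraction", lower = 0, upper = 1)
  check_number(male_fraction, "male_fraction", lower = 0, upper = 1)
  defaults <- list(c_base = 0.6, c_sd = 0.1, stress = 0.12,
                   sex_stress = -0.15, cortisol_cor = 0.3, outcome_sd = 15)
  effects <- utils::modifyList(defaults, as.list(effects))
  if (effects$c_sd < 0 || effects$outcome_sd < 0) {
    abort("effect-map variances must be non-negative.",
          class = "dyadflow_input_error")
  }
  if (abs(effects$cortisol_cor) > 1) {
    abort("cortisol_cor must lie in [-1, 1].", class = "dyadflow_input_error")
  }
  if (!inherits(dyad, "sim_config")) {
    abort("`dyad` must be a sim_config.", class = "dyadflow_input_error")
  }
  structure(list(n_dyads = as.integer(n_dyads),
                 stress_fraction = stress_fraction,
                 male_fraction = male_fraction,
                 effects = effects, dyad = dyad, seed = seed),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  n_dyads: %d (stressed fraction %.2f, male fraction %.2f)\n",
              x$n_dyads, x$stress_fraction, x$male_fraction))
  cat(sprintf("  gain: base %.3g (sd %.3g), stress %+0.3g, sex x stress %+0.3g\n",
              x$effects$c_base, x$effects$c_sd, x$effects$stress,
              x$effects$sex_stress))
  invisible(x)
}
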