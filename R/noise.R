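# Error-propagation helpers for beat-timing quantization.

#' RR-interval and heart-rate quantization noise
#'
#' R-peak localisation on an ECG sampled at `f_ecg_hz` carries a timing
#' resolution of one sample per peak, so an RR interval (the difference of
#' two peak times) has a worst-case error `Delta(RRI) = 2 / f_ecg_hz`.
#' Propagated to instantaneous heart rate `HR = 60 / RRI`, this gives
#' `Delta(HR) = 60 * Delta(RRI) / <RRI>^2 = <HR>^2 * Delta(RRI) / 60`
#' (about 0.2 bpm at 80 bpm for a 1000 Hz ECG).
#'
#' @param f_ecg_hz ECG sampling rate (Hz).
#' @param mean_hr_bpm Mean heart rate (bpm).
#' @return Noise amplitude in seconds (`rr_quantization_noise`) or bpm
#'   (`hr_quantization_noise`).
#' @export
#' @examples
#' rr_quantization_noise(1000)        # 2e-3 s
#' hr_quantization_noise(80, 1000)    # ~0.21 bpm
rr_quantization_noise <- function(f_ecg_hz = 1000) {
  check_number(f_ecg_hz, "f_ecg_hz", lower = 1e-9)
  2 / f_ecg_hz
}

#' @rdname rr_quantization_noise
#' @export
hr_quantization_noise <- function(mean_hr_bpm = 80, f_ecg_hz = 1000) {
  check_number(mean_hr_bpm, "mean_hr_bpm", lower = 1e-9)
  mean_hr_bpm^2 * rr_quantization_noise(f_ecg_hz) / 60
}

#' Cardiac cycle length at a given heart rate
#'
#' @param hr_bpm Heart rate in bpm.
#' @return Cycle length in seconds (0.43 s at 140 bpm).
#' @export
cardiac_cycle_s <- function(hr_bpm) {
  check_number(hr_bpm, "hr_bpm", lower = 1e-9)
  60 / hr_bpm
}
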