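# RR -> evenly sampled HR, scale-dependent moving-average filtering, quality
# masking, and dyad-level exclusion.

#' Construct an HR series from raw values
#'
#' Low-level constructor for an evenly sampled heart-rate series, mainly
#' useful for feeding synthetic signals to the estimators directly.
#'
#' @param values Heart-rate samples (bpm).
#' @param fs Sampling rate (Hz).
#' @param tau Scale attribute in seconds (`NA` = unfiltered).
#' @param valid Logical validity per sample (default all valid).
#' @param t0 Time of the first sample (s).
#' @return An `hr_series` tibble.
#' @export
hr_series <- function(values, fs, tau = NA_real_, valid = NULL, t0 = 0) {
  check_number(fs, "fs", lower = 1e-9)
  valid <- valid %||% rep(TRUE, length(values))
  stopifnot(length(valid) == length(values))
  new_hr_series(t0 + (seq_along(values) - 1L) / fs,
                ifelse(valid, values, NA_real_), valid, fs = fs, tau = tau)
}

new_hr_series <- function(t_s, hr_bpm, valid, fs, tau = NA_real_) {
  out <- tibble(t_s = t_s, hr_bpm = hr_bpm, valid = valid)
  class(out) <- c("hr_series", class(out))
  attr(out, "fs") <- fs
  attr(out, "tau") <- tau
  out
}

#' @export
print.hr_series <- function(x, ...) {
  tau <- attr(x, "tau")
  cat(sprintf("<hr_series> fs = %g Hz, scale tau = %s, %d samples (%.1f%% valid)\n",
              attr(x, "fs"), if (is.na(tau)) "unfiltered" else paste0(tau, " s"),
              nrow(x), 100 * mean(x$valid)))
  NextMethod()
}

#' Instantaneous heart rate from an RR-interval series
#'
#' Samples the piece-wise-constant instantaneous heart rate
#' `HR(t) = 60 / RRI` (zero-order hold over the interval containing `t`) on
#' the even grid `t = t0 + k/fs`, `k = 0, 1, ...`. Samples before the first
#' or at/after the last beat are marked invalid.
#'
#' @param rr RR tibble with columns `beat_time_s`, `rr_s` (see
#'   [read_rr_csv()]).
#' @param fs Sampling rate in Hz (default 20).
#' @param duration_s Grid length in seconds; defaults to the last beat time.
#'   The grid has `floor(duration_s * fs)` samples.
#' @param t0 Grid origin (s), default 0.
#' @return An `hr_series` tibble: `t_s`, `hr_bpm`, `valid`, with attributes
#'   `fs` and `tau` (`NA` = unfiltered).
#' @export
#' @examples
#' rr <- tibble::tibble(beat_time_s = seq(0, 10, 0.75),
#'                      rr_s = c(rep(0.75, 13), NA))
#' hr <- rr_to_hr(rr, fs = 20)
#' unique(hr$hr_bpm[hr$valid]) # 80 bpm
rr_to_hr <- function(rr, fs = 20, duration_s = NULL, t0 = 0) {
  validate_rr(rr)
  check_number(fs, "fs", lower = 1e-9)
  beats <- rr$beat_time_s
  duration_s <- duration_s %||% beats[length(beats)]
  n <- floor(duration_s * fs)
  if (n < 1) abort("duration too short for one sample.",
                   class = "dyadflow_input_error")
  t <- t0 + (seq_len(n) - 1L) / fs
  idx <- findInterval(t, beats) # interval i covers [beats[i], beats[i+1])
  ok <- idx >= 1L & idx < length(beats)
  hr <- rep(NA_real_, n)
  hr[ok] <- 60 / (beats[idx[ok] + 1L] - beats[idx[ok]])
  new_hr_series(t, hr, ok, fs = fs)
}

#' Moving-average (low-pass) filter at time scale tau
#'
#' Centered moving average over a window of `round(tau * fs)` samples. An
#' output sample is valid only when the entire window lies inside a valid run
#' of the input, so filtering never bridges gaps nor creates validity. For
#' even windows the extra sample is taken from the future side.
#'
#' @param hr An unfiltered `hr_series` (from [rr_to_hr()]).
#' @param tau Time scale in seconds; `tau * fs` must be at least 1.
#' @return An `hr_series` with attribute `tau` set.
#' @export
hr_moving_average <- function(hr, tau) {
  stopifnot(inherits(hr, "hr_series"))
  if (!is.na(attr(hr, "tau"))) {
    abort("input is already filtered; filter the unfiltered series.",
          class = "dyadflow_input_error")
  }
  fs <- attr(hr, "fs")
  w <- round(tau * fs)
  if (w < 1) {
    abort("tau * fs < 1: window shorter than one sample.",
          class = "dyadflow_input_error")
  }
  n <- nrow(hr)
  x <- ifelse(hr$valid, hr$hr_bpm, 0)
  v <- as.integer(hr$valid)
  cs <- c(0, cumsum(x))
  cv <- c(0, cumsum(v))
  left <- floor((w - 1) / 2)
  k <- seq_len(n)
  lo <- k - left
  hi <- lo + w - 1L
  ok <- lo >= 1L & hi <= n
  out <- rep(NA_real_, n)
  nval <- integer(n)
  nval[ok] <- cv[hi[ok] + 1L] - cv[lo[ok]]
  full <- ok & nval == w
  out[full] <- (cs[hi[full] + 1L] - cs[lo[full]]) / w
  new_hr_series(hr$t_s, out, full, fs = fs, tau = tau)
}

#' Apply a per-second quality mask to an HR series
#'
#' Invalidates samples falling in flagged seconds, then prunes residual valid
#' runs shorter than `min_run_s` (short fragments support no embedding
#' vectors and only add boundary artifacts).
#'
#' @param hr An `hr_series`.
#' @param mask Logical vector, one entry per second of recording (`TRUE` =
#'   usable); must cover the full grid.
#' @param min_run_s Minimum surviving valid-run length in seconds
#'   (default 10).
#' @return The masked `hr_series`.
#' @export
apply_quality_mask <- function(hr, mask, min_run_s = 10) {
  stopifnot(inherits(hr, "hr_series"))
  fs <- attr(hr, "fs")
  needed <- ceiling((max(hr$t_s) + 1 / fs) - min(hr$t_s))
  if (length(mask) < needed) {
    abort(sprintf("mask covers %d s but the recording spans %d s.",
                  length(mask), needed),
          class = "dyadflow_input_error")
  }
  sec <- floor(hr$t_s - min(hr$t_s)) + 1L
  valid <- hr$valid & mask[sec]
  if (min_run_s > 0) {
    id <- run_ids(valid)
    if (any(!is.na(id))) {
      len <- tabulate(id[!is.na(id)])
      short <- which(len < round(min_run_s * fs))
      valid[!is.na(id) & id %in% short] <- FALSE
    }
  }
  new_hr_series(hr$t_s, ifelse(valid, hr$hr_bpm, NA_real_), valid,
                fs = fs, tau = attr(hr, "tau"))
}

#' Dyad-level exclusion rule
#'
#' A dyad is excluded when the fetal HR sits in the maternal range (below
#' `low_bpm`) for more than `max_low_fraction` of its valid samples —
#' the signature of the maternal heart having been picked up twice.
#'
#' @param fhr,mhr Fetal and maternal `hr_series` on the same grid.
#' @param max_low_fraction Maximal tolerated fraction (default 0.05; the
#'   source analysis states no numeric threshold).
#' @param low_bpm Threshold separating fetal from maternal HR (default 100).
#' @return One-row tibble: `excluded`, `low_fraction`, `n_valid`.
#' @export
dyad_exclusion <- function(fhr, mhr, max_low_fraction = 0.05, low_bpm = 100) {
  stopifnot(inherits(fhr, "hr_series"), inherits(mhr, "hr_series"))
  if (nrow(fhr) != nrow(mhr) || attr(fhr, "fs") != attr(mhr, "fs")) {
    abort("fetal and maternal series must share the sampling grid.",
          class = "dyadflow_input_error")
  }
  v <- fhr$valid
  if (!any(v)) abort("no valid fetal samples.", class = "dyadflow_input_error")
  frac <- mean(fhr$hr_bpm[v] < low_bpm)
  tibble(excluded = frac > max_low_fraction,
         low_fraction = frac,
         n_valid = sum(v))
}

#' Preprocess one dyad recording to masked HR series
#'
#' Convenience wrapper: RR to HR for both hearts on a common grid, quality
#' mask application, and the exclusion diagnostic.
#'
#' @param dyad A `dyad_recording` (or list with `maternal_rr`, `fetal_rr`,
#'   `quality_mask`).
#' @param fs Sampling rate (Hz), default 20.
#' @param min_run_s Passed to [apply_quality_mask()].
#' @param max_low_fraction Passed to [dyad_exclusion()].
#' @return List with `mhr`, `fhr` (masked `hr_series`) and `exclusion`
#'   (one-row tibble).
#' @export
preprocess_dyad <- function(dyad, fs = 20, min_run_s = 10,
                            max_low_fraction = 0.05) {
  duration <- length(dyad$quality_mask)
  mhr <- rr_to_hr(dyad$maternal_rr, fs = fs, duration_s = duration)
  fhr <- rr_to_hr(dyad$fetal_rr, fs = fs, duration_s = duration)
  mhr <- apply_quality_mask(mhr, dyad$quality_mask, min_run_s = min_run_s)
  fhr <- apply_quality_mask(fhr, dyad$quality_mask, min_run_s = min_run_s)
  excl <- dyad_exclusion(fhr, mhr, max_low_fraction = max_low_fraction)
  list(mhr = mhr, fhr = fhr, exclusion = excl)
}

#' Write an HR series as CSV
#'
#' Columns `t_s`, `hr_bpm`, `valid`.
#' @param hr An `hr_series`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_hr_csv <- function(hr, path) {
  readr::write_csv(as_tibble(hr), path)
  invisible(path)
}
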