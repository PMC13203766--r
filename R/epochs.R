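# Acceleration/deceleration epoch labelling at a given time scale, and event
# statistics.

#' Label acceleration and deceleration epochs
#'
#' Computes the forward first difference `d[k] = x[k+1] - x[k]` of the
#' filtered HR inside each valid run and labels sample `k` as `accel`
#' (`d > mu`), `decel` (`d < -mu`) or `neither` (`|d| <= mu`); the last
#' sample of each valid run has no forward difference and is labelled
#' `neither`. Invalid samples are labelled `invalid`. Maximal runs of equal
#' labels form events.
#'
#' With the default zero threshold every sample with a strictly monotone
#' local derivative belongs to an epoch, so the accel + decel time-point
#' fractions fall just short of 1 (exact-zero differences and run endpoints
#' make up the remainder).
#'
#' @param filtered A filtered `hr_series` (see [hr_moving_average()]).
#' @param mu Derivative threshold in bpm per sample step (default 0).
#' @return An `epoch_mask`: tibble `t_s`, `label` (factor accel/decel/
#'   neither/invalid), `event_id` (integer, `NA` on invalid samples), with
#'   attributes `tau` and `fs`.
#' @export
label_epochs <- function(filtered, mu = 0) {
  stopifnot(inherits(filtered, "hr_series"))
  if (!any(filtered$valid)) {
    abort("all samples invalid.", class = "dyadflow_input_error")
  }
  n <- nrow(filtered)
  x <- filtered$hr_bpm
  id <- run_ids(filtered$valid)
  d <- c(x[-1] - x[-n], NA)
  same_run <- c(id[-1] == id[-n], FALSE)
  lab <- rep("invalid", n)
  in_run <- !is.na(id)
  lab[in_run] <- "neither" # run endpoints and |d| <= mu
  use <- in_run & same_run & !is.na(d)
  lab[use & d > mu] <- "accel"
  lab[use & d < -mu] <- "decel"
  lab <- factor(lab, levels = c("accel", "decel", "neither", "invalid"))

  # events: maximal same-label runs inside valid runs
  key <- paste(id, lab)
  newev <- in_run & (seq_len(n) == 1L | key != c("", key[-n]))
  ev <- cumsum(newev)
  ev[!in_run] <- NA_integer_

  out <- tibble(t_s = filtered$t_s, label = lab, event_id = ev)
  class(out) <- c("epoch_mask", class(out))
  attr(out, "tau") <- attr(filtered, "tau")
  attr(out, "fs") <- attr(filtered, "fs")
  out
}

#' Event list of an epoch mask
#'
#' @param mask An `epoch_mask` from [label_epochs()].
#' @return Tibble with one row per event: `event_id`, `label`, `start_s`,
#'   `duration_s`, `n_samples`.
#' @export
epoch_events <- function(mask) {
  stopifnot(inherits(mask, "epoch_mask"))
  fs <- attr(mask, "fs")
  keep <- !is.na(mask$event_id)
  dplyr::summarise(
    dplyr::group_by(mask[keep, ], .data$event_id, .data$label),
    start_s = min(.data$t_s), n_samples = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(duration_s = .data$n_samples / fs) |>
    dplyr::arrange(.data$event_id)
}

#' Acceleration/deceleration event statistics
#'
#' Event counts, event-based fractions
#' (`N_accel / (N_accel + N_decel)`), time-point-based fractions (labelled
#' samples over all non-invalid samples, so accel + decel can fall short
#' of 1), and the deceleration/acceleration ratio in both conventions.
#'
#' @param mask An `epoch_mask`.
#' @return One-row tibble: `tau_s`, `n_accel_events`, `n_decel_events`,
#'   `accel_frac_event`, `decel_frac_event`, `accel_frac_time`,
#'   `decel_frac_time`, `decel_accel_ratio_event`, `decel_accel_ratio_time`,
#'   `ratio_undefined`.
#' @export
epoch_stats <- function(mask) {
  stopifnot(inherits(mask, "epoch_mask"))
  ev <- epoch_events(mask)
  n_acc <- sum(ev$label == "accel")
  n_dec <- sum(ev$label == "decel")
  n_ev <- n_acc + n_dec
  n_lab <- sum(mask$label != "invalid")
  t_acc <- sum(mask$label == "accel")
  t_dec <- sum(mask$label == "decel")
  tibble(
    tau_s = attr(mask, "tau"),
    n_accel_events = n_acc, n_decel_events = n_dec,
    accel_frac_event = if (n_ev > 0) n_acc / n_ev else NA_real_,
    decel_frac_event = if (n_ev > 0) n_dec / n_ev else NA_real_,
    accel_frac_time = t_acc / n_lab,
    decel_frac_time = t_dec / n_lab,
    decel_accel_ratio_event = if (n_acc > 0) n_dec / n_acc else NA_real_,
    decel_accel_ratio_time = if (t_acc > 0) t_dec / t_acc else NA_real_,
    ratio_undefined = n_acc == 0)
}

#' Epoch statistics for both hearts of a cohort
#'
#' Per dyad and heart: time-point and event fractions at one time scale.
#' Produces the long table consumed by [mlm_long_fractions()].
#'
#' @param prep_list Named list of preprocessed dyads (see
#'   [preprocess_dyad()]).
#' @param tau Time scale in seconds (default 2.5).
#' @param mu Derivative threshold (default 0).
#' @return Tibble: `dyad_id`, `signal` (`fhr`/`mhr`), plus [epoch_stats()]
#'   columns.
#' @export
cohort_epoch_stats <- function(prep_list, tau = 2.5, mu = 0) {
  purrr::list_rbind(purrr::imap(prep_list, function(p, id) {
    purrr::list_rbind(purrr::imap(list(fhr = p$fhr, mhr = p$mhr),
                                  function(hr, sig) {
      st <- epoch_stats(label_epochs(hr_moving_average(hr, tau), mu = mu))
      dplyr::bind_cols(tibble(dyad_id = id, signal = sig), st)
    }))
  }))
}
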