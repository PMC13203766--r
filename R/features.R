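# Multiscale metric curves and their reduction to the 50-feature vector:
# {ER, SE} x {mHR, fHR} x 5 conditioning paradigms x {max, AUC}  (40)
# + netTE x 5 paradigms x {max, AUC}                             (10)

#' Time-scale grid for the multiscale analysis
#'
#' Log-spaced scales from `1/fs` up to `tau_max`, with the guarantee of at
#' least `min_band_points` grid points inside the summary band (default
#' [0.5, 2.5] s — the vagally dominated range where net maternal-to-fetal
#' flow is expected to be positive).
#'
#' @param fs Sampling rate (Hz), default 20.
#' @param tau_max Largest scale (s), default 20.
#' @param n Number of grid points (default 25).
#' @param band Summary interval in seconds (default `c(0.5, 2.5)`).
#' @param min_band_points Minimum grid points inside `band` (default 6).
#' @return A list of class `scale_grid` with `tau` (s) and `band`.
#' @export
scale_grid <- function(fs = 20, tau_max = 20, n = 25, band = c(0.5, 2.5),
                       min_band_points = 6) {
  tau_min <- 1 / fs
  tau <- exp(seq(log(tau_min), log(tau_max), length.out = n))
  in_band <- tau >= band[1] & tau <= band[2]
  if (sum(in_band) < min_band_points) {
    extra <- exp(seq(log(band[1]), log(band[2]),
                     length.out = min_band_points))
    tau <- sort(unique(c(tau, extra)))
  }
  structure(list(tau = tau, band = band), class = "scale_grid")
}

#' Band-only scale grid
#'
#' Grid restricted to the summary band — the economical choice when only the
#' `max`/`AUC` summaries are needed.
#' @inheritParams scale_grid
#' @export
band_grid <- function(n = 6, band = c(0.5, 2.5)) {
  structure(list(tau = exp(seq(log(band[1]), log(band[2]), length.out = n)),
                 band = band), class = "scale_grid")
}

paradigms <- function() c("none", "mhr_accel", "mhr_decel",
                          "fhr_accel", "fhr_decel")

paradigm_condition <- function(paradigm, mask_m, mask_f) {
  switch(paradigm,
         none = list(condition = NULL, label = "accel"),
         mhr_accel = list(condition = mask_m, label = "accel"),
         mhr_decel = list(condition = mask_m, label = "decel"),
         fhr_accel = list(condition = mask_f, label = "accel"),
         fhr_decel = list(condition = mask_f, label = "decel"))
}

#' Multiscale entropy features of one dyad
#'
#' Runs the full per-dyad metric battery: at each scale of the grid, filters
#' both HR series, labels their acceleration/deceleration epochs, and
#' estimates the entropy rate and sample entropy of each heart plus the
#' surrogate-corrected bidirectional and net transfer entropy, each under the
#' five conditioning paradigms (`none`, `mhr_accel`, `mhr_decel`,
#' `fhr_accel`, `fhr_decel`). Curves are reduced to `max` and `AUC` (mean
#' over band grid points, proportional to the area under the curve) on the
#' summary band.
#'
#' @param dyad A `dyad_recording`, or a preprocessed list with elements
#'   `mhr` and `fhr` (see [preprocess_dyad()]).
#' @param grid A [scale_grid()] or [band_grid()].
#' @param params An [entropy_params()].
#' @param fs Sampling rate used if `dyad` is a raw recording (default 20).
#' @param metrics Subset of `c("er", "se", "nette")` to compute (default
#'   all).
#' @return An object of class `dyad_features`: list with `features` (one-row
#'   wide tibble, columns `{metric}_{signal}_{paradigm}_{summary}`) and
#'   `curves` (long tibble: `metric`, `signal`, `paradigm`, `tau_s`,
#'   `value_nats`, `n_points`).
#' @export
compute_features <- function(dyad, grid = scale_grid(),
                             params = entropy_params(), fs = 20,
                             metrics = c("er", "se", "nette")) {
  if (inherits(dyad, "dyad_recording")) dyad <- preprocess_dyad(dyad, fs = fs)
  mhr <- dyad$mhr
  fhr <- dyad$fhr
  metrics <- match.arg(metrics, several.ok = TRUE)
  rows <- list()
  for (tau in grid$tau) {
    fm <- hr_moving_average(mhr, tau)
    ff <- hr_moving_average(fhr, tau)
    mask_m <- label_epochs(fm)
    mask_f <- label_epochs(ff)
    for (p in paradigms()) {
      cnd <- paradigm_condition(p, mask_m, mask_f)
      if ("er" %in% metrics) {
        for (sig in c("mhr", "fhr")) {
          est <- entropy_rate(if (sig == "mhr") fm else ff, params,
                              cnd$condition, cnd$label)
          rows[[length(rows) + 1L]] <-
            tibble(metric = "er", signal = sig, paradigm = p, tau_s = tau,
                   value_nats = est$value_nats, n_points = est$n_vectors)
        }
      }
      if ("se" %in% metrics) {
        for (sig in c("mhr", "fhr")) {
          est <- sample_entropy(if (sig == "mhr") fm else ff, params,
                                condition = cnd$condition,
                                condition_label = cnd$label)
          rows[[length(rows) + 1L]] <-
            tibble(metric = "se", signal = sig, paradigm = p, tau_s = tau,
                   value_nats = est$value, n_points = est$n_vectors)
        }
      }
      if ("nette" %in% metrics) {
        est <- net_transfer_entropy(fm, ff, params, cnd$condition, cnd$label)
        rows[[length(rows) + 1L]] <-
          tibble(metric = "nette", signal = "pair", paradigm = p, tau_s = tau,
                 value_nats = est$net_te,
                 n_points = min(est$n_vectors_mf, est$n_vectors_fm))
      }
    }
  }
  curves <- purrr::list_rbind(rows)
  features <- summarize_curves(curves, grid$band)
  structure(list(features = features, curves = curves,
                 band = grid$band, params = params),
            class = "dyad_features")
}

summarize_curves <- function(curves, band) {
  in_band <- dplyr::filter(curves, .data$tau_s >= band[1],
                           .data$tau_s <= band[2])
  summ <- dplyr::summarise(
    dplyr::group_by(in_band, .data$metric, .data$signal, .data$paradigm),
    max = if (all(is.na(.data$value_nats))) NA_real_ else
      max(.data$value_nats, na.rm = TRUE),
    auc = if (all(is.na(.data$value_nats))) NA_real_ else
      mean(.data$value_nats, na.rm = TRUE),
    .groups = "drop")
  long <- tidyr::pivot_longer(summ, c("max", "auc"), names_to = "summary")
  long$feature <- feature_name(long$metric, long$signal, long$paradigm,
                               long$summary)
  tidyr::pivot_wider(long[, c("feature", "value")],
                     names_from = "feature", values_from = "value")
}

feature_name <- function(metric, signal, paradigm, summary) {
  ifelse(metric == "nette",
         paste("nette", paradigm, summary, sep = "_"),
         paste(metric, signal, paradigm, summary, sep = "_"))
}

#' All 50 feature names
#' @return Character vector of length 50.
#' @export
feature_names <- function() {
  c(as.vector(outer(
      as.vector(outer(c("er", "se"), c("mhr", "fhr"), paste, sep = "_")),
      as.vector(outer(paradigms(), c("max", "auc"), paste, sep = "_")),
      paste, sep = "_")),
    as.vector(outer("nette",
      as.vector(outer(paradigms(), c("max", "auc"), paste, sep = "_")),
      paste, sep = "_")))
}

#' @export
print.dyad_features <- function(x, ...) {
  n_miss <- sum(is.na(unlist(x$features)))
  cat(sprintf("<dyad_features> %d features (%d missing), %d curve points\n",
              ncol(x$features), n_miss, nrow(x$curves)))
  invisible(x)
}

#' @export
tidy.dyad_features <- function(x, ...) {
  out <- tidyr::pivot_longer(x$features, dplyr::everything(),
                             names_to = "feature")
  parts <- strsplit(out$feature, "_")
  out$metric <- vapply(parts, `[`, "", 1)
  out$summary <- vapply(parts, function(p) p[length(p)], "")
  out
}

#' Feature table for a cohort of dyads
#'
#' Applies [compute_features()] to every recording and binds the one-row
#' feature vectors into a cohort feature table.
#'
#' @param recordings Named list of `dyad_recording`s (or preprocessed dyads).
#' @inheritParams compute_features
#' @param min_run_s,max_low_fraction Preprocessing thresholds (see
#'   [preprocess_dyad()]); excluded dyads are dropped with a warning.
#' @param progress Print per-dyad progress lines.
#' @return Tibble: `dyad_id` + feature columns.
#' @export
cohort_features <- function(recordings, grid = scale_grid(),
                            params = entropy_params(), fs = 20,
                            metrics = c("er", "se", "nette"),
                            min_run_s = 10, max_low_fraction = 0.05,
                            progress = FALSE) {
  purrr::list_rbind(purrr::imap(recordings, function(d, id) {
    if (inherits(d, "dyad_recording")) {
      d <- preprocess_dyad(d, fs = fs, min_run_s = min_run_s,
                           max_low_fraction = max_low_fraction)
    }
    if (isTRUE(d$exclusion$excluded)) {
      warn(sprintf("dyad %s excluded (low-fHR fraction %.2f).",
                   id, d$exclusion$low_fraction))
      return(NULL)
    }
    if (progress) message("features: ", id)
    fx <- compute_features(d, grid = grid, params = params,
                           metrics = metrics)
    dplyr::bind_cols(tibble(dyad_id = id), fx$features)
  }))
}
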