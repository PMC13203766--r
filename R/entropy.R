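# Entropy estimation: Kozachenko-Leonenko k-NN differential entropy, the
# multiscale entropy rate, and sample entropy, all with gap- and epoch-aware
# embedding.

#' Estimation parameters for the entropy/transfer-entropy family
#'
#' @param k Number of nearest neighbours for the k-NN estimators (default 5).
#' @param sampen_m Sample-entropy embedding dimension (default 1).
#' @param sampen_r_factor Sample-entropy tolerance as a multiple of the
#'   analyzed segment set's SD (default 0.2).
#' @param n_surrogates Number of circular-shift surrogates for transfer-
#'   entropy bias correction (default 20).
#' @param min_vectors Minimum usable embedding vectors per estimate; below
#'   this the estimate is reported missing (default 100 — k-NN estimates on
#'   fewer vectors are variance-dominated).
#' @param max_vectors Cap on embedding vectors per estimate; larger sets are
#'   thinned evenly (default 1000). Successive vectors at high sampling rates
#'   are strongly dependent, so thinning costs little information while
#'   keeping the O(n^2) neighbour search fast.
#' @param jitter_sd_factor Amplitude of the uniform tie-breaking jitter as a
#'   multiple of each coordinate's SD (default 1e-6); k-NN estimators need
#'   distinct distances and HR data are quantized.
#' @param theiler_factor Theiler exclusion window as a multiple of the
#'   embedding lag `L = round(tau * fs)` (default 1): embedding vectors
#'   closer than this in time are never counted as neighbours of each
#'   other, so serial correlation does not masquerade as recurrence.
#' @param seed Seed for jitter and surrogate offsets (default 20240501);
#'   estimates are deterministic given data and seed.
#' @return A list of class `entropy_params`.
#' @export
entropy_params <- function(k = 5, sampen_m = 1, sampen_r_factor = 0.2,
                           n_surrogates = 20, min_vectors = 100,
                           max_vectors = 1000, jitter_sd_factor = 1e-6,
                           theiler_factor = 1, seed = 20240501) {
  check_number(k, "k", lower = 1)
  check_number(sampen_m, "sampen_m", lower = 1)
  check_number(sampen_r_factor, "sampen_r_factor", lower = 1e-12)
  check_number(n_surrogates, "n_surrogates", lower = 1)
  check_number(min_vectors, "min_vectors", lower = 2)
  check_number(max_vectors, "max_vectors", lower = 10)
  structure(list(k = as.integer(k), sampen_m = as.integer(sampen_m),
                 sampen_r_factor = sampen_r_factor,
                 n_surrogates = as.integer(n_surrogates),
                 min_vectors = as.integer(min_vectors),
                 max_vectors = as.integer(max_vectors),
                 jitter_sd_factor = jitter_sd_factor,
                 theiler_factor = theiler_factor,
                 seed = seed),
            class = "entropy_params")
}

# deterministic tie-breaking jitter, one uniform draw per matrix entry
jitter_matrix <- function(x, factor, seed) {
  a <- apply(x, 2, sd)
  a[a == 0] <- abs(colMeans(x))[a == 0] + 1
  a <- a * factor
  with_seed(seed, {
    x + matrix(runif(length(x), -1, 1), nrow(x)) %*% diag(a, ncol(x))
  })
}

#' Kozachenko--Leonenko k-NN differential entropy
#'
#' Differential entropy (nats) of a point cloud from k-th nearest-neighbour
#' distances under the Chebyshev norm:
#' `H = psi(N) - psi(k) + d * mean(log(2 * eps_i))`. Ties/duplicates are
#' broken by a small deterministic uniform jitter.
#'
#' @param x Numeric vector or n-by-d matrix of points.
#' @param k Number of neighbours (default 5); must satisfy `n > k`.
#' @param params Optional [entropy_params()] supplying `k`, jitter amplitude
#'   and seed.
#' @param tidx Optional integer time stamps of the points, enabling Theiler
#'   exclusion for serially dependent data.
#' @param theiler Exclusion window in `tidx` units (default 0: only the
#'   point itself is excluded).
#' @return Entropy estimate in nats.
#' @export
#' @examples
#' set.seed(1)
#' knn_entropy(rnorm(2000)) # ~ 0.5*log(2*pi*e) = 1.419
knn_entropy <- function(x, k = NULL, params = entropy_params(),
                        tidx = NULL, theiler = 0) {
  x <- as.matrix(x)
  k <- k %||% params$k
  if (nrow(x) <= k) {
    abort("need more points than neighbours.", class = "dyadflow_input_error")
  }
  if (any(apply(x, 2, sd) == 0)) {
    warn("zero-variance dimension: jittered before estimation.")
  }
  xj <- jitter_matrix(x, params$jitter_sd_factor, params$seed)
  tidx <- tidx %||% seq_len(nrow(x))
  .kl_entropy_cpp(xj, as.integer(k), as.integer(tidx), as.integer(theiler))
}

# --- embedding machinery -----------------------------------------------------

# logical flag per sample: does it carry the required epoch label?
cond_flags <- function(condition, condition_label) {
  if (is.null(condition)) return(NULL)
  stopifnot(inherits(condition, "epoch_mask"))
  condition_label <- match.arg(condition_label, c("accel", "decel", "neither"))
  as.character(condition$label) == condition_label
}

# start indices t such that the whole window [t, t + L] lies inside one valid
# run and (if conditioning) every embedded sample coordinate carries the
# required epoch label. Epochs at scale tau are typically shorter than the
# lag tau itself, so the embedded coordinates may fall in different events of
# the same type; demanding a single event would leave conditioned sets
# empty at all but the smallest scales.
window_starts <- function(valid, L, cond_ok = NULL, cond_points = c(0, L)) {
  n <- length(valid)
  if (n <= L) return(integer(0))
  id <- run_ids(valid)
  t <- seq_len(n - L)
  ok <- !is.na(id[t]) & !is.na(id[t + L]) & id[t] == id[t + L]
  if (!is.null(cond_ok)) {
    for (p in cond_points) ok <- ok & cond_ok[t + p]
  }
  t[ok]
}

lag_samples <- function(tau, fs) max(1L, round(tau * fs))

missing_estimate <- function(reason, cols = "value_nats") {
  out <- tibble(!!cols := NA_real_, n_vectors = 0L, reason = reason)
  out
}

#' Multiscale entropy rate
#'
#' Entropy rate of a filtered HR series at its time scale `tau`:
#' `h(tau) = H(x_t, x_(t+L)) - H(x_t)` with lag `L = round(tau * fs)` — the
#' conditional entropy of the signal one scale step ahead given its present,
#' estimated with [knn_entropy()]. Embedding pairs must lie within one valid
#' run; with conditioning, within a single epoch of the required label of the
#' conditioning signal.
#'
#' @param x A filtered `hr_series` (its `tau` attribute sets the lag).
#' @param params An [entropy_params()].
#' @param condition Optional `epoch_mask` of the conditioning signal at the
#'   same scale (may come from the same or the other heart).
#' @param condition_label `"accel"` or `"decel"`.
#' @return One-row tibble: `value_nats`, `n_vectors`, `reason` (`NA` when
#'   estimated).
#' @export
entropy_rate <- function(x, params = entropy_params(), condition = NULL,
                         condition_label = "accel") {
  stopifnot(inherits(x, "hr_series"))
  tau <- attr(x, "tau")
  if (is.na(tau)) abort("series must be filtered at some scale tau.",
                        class = "dyadflow_input_error")
  L <- lag_samples(tau, attr(x, "fs"))
  ce <- cond_flags(condition, condition_label)
  th <- as.integer(round(params$theiler_factor * L))
  t <- window_starts(x$valid, L, ce)
  t <- thin_spaced(t, max(1L, th %/% 2L), params$max_vectors)
  if (length(t) < params$min_vectors) {
    return(missing_estimate("insufficient embedding pairs"))
  }
  v <- x$hr_bpm
  joint <- jitter_matrix(cbind(v[t], v[t + L]),
                         params$jitter_sd_factor, params$seed)
  h2 <- .kl_entropy_cpp(joint, params$k, as.integer(t), th)
  h1 <- .kl_entropy_cpp(joint[, 1, drop = FALSE], params$k, as.integer(t), th)
  tibble(value_nats = h2 - h1, n_vectors = length(t), reason = NA_character_)
}

#' Sample entropy with scale-aware templates
#'
#' `SE = -ln(A/B)` where `B` counts pairs of `m`-point templates within
#' tolerance `r` (Chebyshev distance, self-matches excluded) and `A` counts
#' pairs still matching at the `(m+1)`-th point. Template points are spaced
#' by the scale lag `L = round(tau * fs)`; templates never span invalid or
#' epoch boundaries. The tolerance is `sampen_r_factor` times the SD of the
#' analyzed (possibly conditioned) sample set.
#'
#' @inheritParams entropy_rate
#' @param m Embedding dimension (defaults to `params$sampen_m`).
#' @return One-row tibble: `value`, `n_vectors` (templates), `reason`.
#' @export
sample_entropy <- function(x, params = entropy_params(), m = NULL,
                           condition = NULL, condition_label = "accel") {
  stopifnot(inherits(x, "hr_series"))
  tau <- attr(x, "tau")
  if (is.na(tau)) abort("series must be filtered at some scale tau.",
                        class = "dyadflow_input_error")
  m <- m %||% params$sampen_m
  L <- lag_samples(tau, attr(x, "fs"))
  ce <- cond_flags(condition, condition_label)
  th_se <- as.integer(round(params$theiler_factor * L))
  t <- window_starts(x$valid, m * L, ce, cond_points = (0:m) * L)
  t <- thin_spaced(t, max(1L, th_se %/% 2L), params$max_vectors)
  if (length(t) < params$min_vectors) {
    return(missing_estimate("insufficient templates", cols = "value"))
  }
  v <- x$hr_bpm
  # sigma over the analyzed segment set (valid samples, label-matched)
  in_set <- x$valid
  if (!is.null(ce)) in_set <- in_set & ce
  sigma <- sd(v[in_set])
  r <- params$sampen_r_factor * sigma
  templ <- vapply(0:m, function(j) v[t + j * L], numeric(length(t)))
  counts <- .sampen_counts_cpp(as.matrix(templ), as.integer(m), r,
                               as.integer(t), th_se)
  if (counts[2] == 0 || counts[1] == 0) {
    return(missing_estimate("no template matches", cols = "value"))
  }
  tibble(value = -log(counts[1] / counts[2]),
         n_vectors = length(t), reason = NA_character_)
}
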