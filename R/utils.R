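# Internal helpers shared across modules.

# Evaluate `code` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.", class = "dyadflow_input_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    abort(sprintf("`%s` must not be NULL.", name),
          class = "dyadflow_input_error")
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].",
                  name, format(lower), format(upper)),
          class = "dyadflow_input_error")
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", name),
          class = "dyadflow_input_error")
  }
  invisible(x)
}

# Evenly thin an index vector down to at most `max_n` entries (deterministic).
thin_evenly <- function(idx, max_n) {
  n <- length(idx)
  if (n <= max_n) return(idx)
  idx[unique(round(seq(1L, n, length.out = max_n)))]
}

# Deterministic subsampling with a minimum temporal gap (greedy), then an
# even thinning down to `max_n`. A common spacing discipline across
# conditioned and unconditioned estimates keeps their k-NN biases comparable:
# clumped, serially redundant vectors would otherwise inflate neighbour
# distances under Theiler exclusion.
thin_spaced <- function(idx, min_gap, max_n) {
  if (length(idx) == 0) return(idx)
  if (min_gap > 1) idx <- .thin_gap_cpp(as.integer(idx), as.integer(min_gap))
  thin_evenly(idx, max_n)
}

# Identify maximal runs of TRUE; returns integer run ids, NA outside runs.
run_ids <- function(valid) {
  valid[is.na(valid)] <- FALSE
  starts <- valid & !c(FALSE, valid[-length(valid)])
  id <- cumsum(starts)
  id[!valid] <- NA_integer_
  id
}
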