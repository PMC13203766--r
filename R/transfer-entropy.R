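# Transfer entropy via the KSG conditional-mutual-information k-NN scheme,
# circular-shift surrogate bias correction, and the net (directional) flow.

te_embedding <- function(src, dst, L, cond_event) {
  # (dst future, src present, dst present); dst window inside one valid run,
  # src present valid; conditioning window inside one epoch
  t <- window_starts(dst$valid, L, cond_event)
  t <- t[src$valid[t]]
  t
}

#' Raw transfer entropy between two HR series
#'
#' `TE_src->dst(tau) = I(dst_(t+L); src_t | dst_t)` with `L = round(tau*fs)`,
#' estimated by the KSG/Frenzel--Pompe conditional-mutual-information k-NN
#' scheme (Chebyshev norm, `k = params$k`). One past lag per signal
#' (embedding dimension 1 at the scale lag); embedding vectors are restricted
#' to valid runs and, when conditioning, to single epochs of the required
#' label.
#'
#' @param src,dst Filtered `hr_series` on the same grid and scale; `src` is
#'   the putative driver.
#' @param params An [entropy_params()].
#' @param condition Optional `epoch_mask` (conditioning signal at the same
#'   scale).
#' @param condition_label `"accel"` or `"decel"`.
#' @return One-row tibble: `value_nats`, `n_vectors`, `reason`.
#' @export
transfer_entropy <- function(src, dst, params = entropy_params(),
                             condition = NULL, condition_label = "accel") {
  stopifnot(inherits(src, "hr_series"), inherits(dst, "hr_series"))
  tau <- attr(dst, "tau")
  if (is.na(tau) || !identical(tau, attr(src, "tau"))) {
    abort("src and dst must be filtered at the same scale.",
          class = "dyadflow_input_error")
  }
  if (nrow(src) != nrow(dst)) {
    abort("src and dst must share the sampling grid.",
          class = "dyadflow_input_error")
  }
  L <- lag_samples(tau, attr(dst, "fs"))
  ce <- cond_flags(condition, condition_label)
  t <- te_embedding(src, dst, L, ce)
  t <- thin_spaced(t, max(1L, round(params$theiler_factor * L) %/% 2L),
                   params$max_vectors)
  if (length(t) < params$min_vectors) {
    return(missing_estimate("insufficient embedding vectors"))
  }
  ksg_te(src$hr_bpm, dst$hr_bpm, t, L, params)
}

ksg_te <- function(s, d, t, L, params) {
  emb <- jitter_matrix(cbind(d[t + L], s[t], d[t]),
                       params$jitter_sd_factor, params$seed)
  th <- as.integer(round(params$theiler_factor * L))
  te <- .ksg_cmi_cpp(emb[, 1], emb[, 2], emb[, 3], params$k,
                     as.integer(t), th)
  tibble(value_nats = te, n_vectors = length(t), reason = NA_character_)
}

#' Surrogate-corrected transfer entropy
#'
#' Subtracts from the raw TE the mean raw TE over `n_surrogates` circular
#' time shifts of the source (offsets drawn uniformly, at least `10 * tau`
#' away from zero on either side), which preserve both marginals and the
#' destination's autocorrelation while destroying cross-coupling. The epoch
#' conditioning frame stays fixed (it is part of the analysis design, not of
#' the coupling under test).
#'
#' @inheritParams transfer_entropy
#' @return One-row tibble: `te_raw`, `te_surrogate_mean`, `te_corrected`
#'   (nats), `n_vectors`, `n_surrogates`, `reason`.
#' @export
surrogate_correction <- function(src, dst, params = entropy_params(),
                                 condition = NULL, condition_label = "accel") {
  raw <- transfer_entropy(src, dst, params, condition, condition_label)
  if (is.na(raw$value_nats)) {
    return(tibble(te_raw = NA_real_, te_surrogate_mean = NA_real_,
                  te_corrected = NA_real_, n_vectors = 0L,
                  n_surrogates = 0L, reason = raw$reason))
  }
  tau <- attr(dst, "tau")
  fs <- attr(dst, "fs")
  L <- lag_samples(tau, fs)
  n <- nrow(src)
  min_shift <- min(ceiling(10 * tau * fs), floor(n / 4))
  offsets <- with_seed(params$seed, {
    sample(seq(min_shift, n - min_shift), params$n_surrogates, replace = TRUE)
  })
  ce <- cond_flags(condition, condition_label)
  sur <- vapply(offsets, function(o) {
    idx <- ((seq_len(n) - 1L + o) %% n) + 1L
    s_sh <- src
    s_sh$hr_bpm <- src$hr_bpm[idx]
    s_sh$valid <- src$valid[idx]
    t <- te_embedding(s_sh, dst, L, ce)
    t <- thin_spaced(t, max(1L, round(params$theiler_factor * L) %/% 2L),
                   params$max_vectors)
    if (length(t) < params$min_vectors) return(NA_real_)
    ksg_te(s_sh$hr_bpm, dst$hr_bpm, t, L, params)$value_nats
  }, numeric(1))
  bias <- mean(sur, na.rm = TRUE)
  tibble(te_raw = raw$value_nats, te_surrogate_mean = bias,
         te_corrected = raw$value_nats - bias,
         n_vectors = raw$n_vectors,
         n_surrogates = sum(!is.na(sur)), reason = NA_character_)
}

#' Net transfer entropy (maternal-to-fetal minus fetal-to-maternal)
#'
#' `netTE(tau) = TEcorr_m->f(tau) - TEcorr_f->m(tau)`; positive values mean
#' net information flow from the mother to the fetus.
#'
#' @param mhr,fhr Filtered maternal and fetal `hr_series` at the same scale.
#' @inheritParams transfer_entropy
#' @return One-row tibble: `net_te`, `te_mf`, `te_fm` (corrected, nats),
#'   `n_vectors_mf`, `n_vectors_fm`, `reason`.
#' @export
net_transfer_entropy <- function(mhr, fhr, params = entropy_params(),
                                 condition = NULL, condition_label = "accel") {
  mf <- surrogate_correction(mhr, fhr, params, condition, condition_label)
  fm <- surrogate_correction(fhr, mhr, params, condition, condition_label)
  if (is.na(mf$te_corrected) || is.na(fm$te_corrected)) {
    reason <- paste(na.omit(c(mf$reason, fm$reason,
                              "one direction missing"))[1])
    return(tibble(net_te = NA_real_, te_mf = NA_real_, te_fm = NA_real_,
                  n_vectors_mf = mf$n_vectors, n_vectors_fm = fm$n_vectors,
                  reason = reason))
  }
  tibble(net_te = mf$te_corrected - fm$te_corrected,
         te_mf = mf$te_corrected, te_fm = fm$te_corrected,
         n_vectors_mf = mf$n_vectors, n_vectors_fm = fm$n_vectors,
         reason = NA_character_)
}
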