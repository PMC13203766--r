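# Net-TE positivity tests and outlier handling.

#' One-sided positivity test for a cohort net-TE feature
#'
#' Two p-values for "net TE > 0": `gaussian_p`, the probability of observing
#' a zero or negative cohort mean under a normal distribution fitted to the
#' cohort values (`pnorm(0, mean, sd / sqrt(n))`), and `t_p`, the one-sided
#' one-sample t-test of the mean against zero. For n of a few dozen or more
#' the two agree closely; the Gaussian version uses only the fitted
#' mean and SD.
#'
#' @param values Numeric vector of a net-TE feature across dyads (no
#'   missing values; `n >= 3`).
#' @return One-row tibble: `n`, `mean`, `sd`, `gaussian_p`, `t_p`,
#'   `degenerate` (TRUE when the SD is zero; p-values then collapse to
#'   0/0.5/1 by the sign of the mean).
#' @export
#' @examples
#' test_net_te_positive(rnorm(50, mean = 0.01, sd = 0.02))
test_net_te_positive <- function(values) {
  if (anyNA(values)) abort("missing values not allowed.",
                           class = "dyadflow_input_error")
  n <- length(values)
  if (n < 3) abort("need n >= 3.", class = "dyadflow_input_error")
  m <- mean(values)
  s <- sd(values)
  if (s == 0) {
    p <- if (m > 0) 0 else if (m < 0) 1 else 0.5
    return(tibble(n = n, mean = m, sd = s, gaussian_p = p, t_p = p,
                  degenerate = TRUE))
  }
  tibble(n = n, mean = m, sd = s,
         gaussian_p = pnorm(0, mean = m, sd = s / sqrt(n)),
         t_p = t.test(values, alternative = "greater")$p.value,
         degenerate = FALSE)
}

#' Iterative z-score outlier filter
#'
#' Repeatedly removes the most extreme point with `|z| > z_max`, where each
#' point's z is computed from the mean and SD of the *other* retained points
#' (leave-one-out: an extreme point does not inflate the SD it is judged
#' against), until no point exceeds the threshold.
#'
#' @param values Numeric vector (`n >= 3`).
#' @param z_max Removal threshold (default 10; generous — the reference
#'   analysis dropped a single z = 23.7 case).
#' @return List with `kept` (logical), `removed` (tibble `index`, `value`,
#'   `z`), and `zero_variance` flag.
#' @export
filter_outliers <- function(values, z_max = 10) {
  if (length(values) < 3) abort("need n >= 3.",
                                class = "dyadflow_input_error")
  kept <- !is.na(values)
  removed <- list()
  loo_z <- function(v_all, kept) {
    idx <- which(kept)
    vapply(idx, function(i) {
      rest <- v_all[setdiff(idx, i)]
      s <- sd(rest)
      if (is.na(s) || s == 0) return(NA_real_)
      (v_all[i] - mean(rest)) / s
    }, numeric(1))
  }
  repeat {
    if (sum(kept) < 3 || sd(values[kept]) == 0) {
      return(list(kept = kept,
                  removed = if (length(removed)) purrr::list_rbind(removed)
                            else tibble(index = integer(), value = numeric(),
                                        z = numeric()),
                  zero_variance = sd(values[kept]) == 0))
    }
    z <- loo_z(values, kept)
    if (all(is.na(z)) || max(abs(z), na.rm = TRUE) <= z_max) break
    worst <- which(kept)[which.max(abs(z))]
    removed[[length(removed) + 1L]] <-
      tibble(index = worst, value = values[worst],
             z = z[which.max(abs(z))])
    kept[worst] <- FALSE
  }
  list(kept = kept,
       removed = if (length(removed)) purrr::list_rbind(removed) else
         tibble(index = integer(), value = numeric(), z = numeric()),
       zero_variance = FALSE)
}

#' Net-TE positivity table across cohort strata
#'
#' Mirrors the standard report layout: rows = cohort and strata (all,
#' stressed, control, male, female), columns = the Gaussian positivity
#' p-value of each net-TE feature (paradigm x max/AUC). Dyads flagged by
#' [filter_outliers()] on any net-TE feature are removed first.
#'
#' @param features Cohort feature table (from [cohort_features()]).
#' @param cohort Cohort table with `dyad_id`, `group`, `sex`.
#' @param z_max Outlier threshold (default 10).
#' @return Tibble: `stratum`, `n`, then one column per net-TE feature.
#' @export
net_te_table <- function(features, cohort, z_max = 10) {
  nette_cols <- grep("^nette_", names(features), value = TRUE)
  dat <- dplyr::inner_join(features, cohort, by = "dyad_id")
  drop <- rep(FALSE, nrow(dat))
  for (cl in nette_cols) {
    v <- dat[[cl]]
    if (sum(!is.na(v)) >= 3) {
      fo <- filter_outliers(ifelse(is.na(v), median(v, na.rm = TRUE), v),
                            z_max = z_max)
      drop <- drop | !fo$kept
    }
  }
  dat <- dat[!drop, ]
  strata <- list(all = rep(TRUE, nrow(dat)),
                 stressed = dat$group == "stressed",
                 control = dat$group == "control",
                 male = dat$sex == "male",
                 female = dat$sex == "female")
  purrr::list_rbind(purrr::imap(strata, function(sel, nm) {
    sub <- dat[sel, ]
    ps <- vapply(nette_cols, function(cl) {
      v <- sub[[cl]][!is.na(sub[[cl]])]
      if (length(v) < 3) NA_real_ else test_net_te_positive(v)$gaussian_p
    }, numeric(1))
    dplyr::bind_cols(tibble(stratum = nm, n = nrow(sub)),
                     as_tibble(as.list(ps)))
  }))
}
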