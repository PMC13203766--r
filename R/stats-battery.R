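# Normality-driven correlation battery with BH-FDR control and strata.

#' Expected number of false positives of a test battery
#'
#' `n_tests * alpha`: the count of spurious nominal discoveries expected
#' under the global null.
#'
#' @param n_tests Number of tests (>= 0).
#' @param alpha Nominal significance level in (0, 1).
#' @return A number.
#' @export
#' @examples
#' expected_false_positives(144, 0.05) # 7.2
expected_false_positives <- function(n_tests, alpha = 0.05) {
  check_number(n_tests, "n_tests", lower = 0)
  check_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  n_tests * alpha
}

shapiro_ok <- function(x, alpha) {
  x <- x[!is.na(x)]
  if (length(x) < 3) return(FALSE)
  if (length(x) > 5000) x <- x[thin_evenly(seq_along(x), 5000)]
  if (sd(x) == 0) return(FALSE)
  shapiro.test(x)$p.value > alpha
}

#' Feature--outcome correlation battery
#'
#' For every feature x outcome pair (pairwise-complete observations):
#' Shapiro--Wilk normality on both variables at level `alpha`; Pearson
#' correlation when both pass, Spearman otherwise; two-tailed uncorrected
#' p-values plus Benjamini--Hochberg q-values across the whole battery.
#' Each stratum is re-run as its own battery (its own BH family).
#'
#' @param features Feature table with `dyad_id` + numeric feature columns.
#' @param cohort Cohort table with `dyad_id`, `group`, `sex` and the outcome
#'   columns.
#' @param feature_cols Feature columns to test (default: every numeric
#'   feature column).
#' @param outcome_cols Outcome columns (default: stress measures + Bayley
#'   composites/subscales present in `cohort`).
#' @param strata Which strata to run: subsets of
#'   `c("all", "stressed", "control", "male", "female", "male_stressed",
#'   "male_control", "female_stressed", "female_control")`.
#' @param alpha Normality-test level (default 0.05).
#' @param min_n Minimum pairwise-complete n per test (default 5); smaller
#'   pairs are skipped.
#' @return Tibble of correlation records: `stratum`, `feature`, `outcome`,
#'   `method`, `n`, `r`, `p`, `q`.
#' @export
run_correlation_battery <- function(features, cohort,
                                    feature_cols = NULL, outcome_cols = NULL,
                                    strata = "all", alpha = 0.05, min_n = 5) {
  dat <- dplyr::inner_join(features, cohort, by = "dyad_id")
  feature_cols <- feature_cols %||%
    setdiff(names(features)[vapply(features, is.numeric, TRUE)], "dyad_id")
  outcome_cols <- outcome_cols %||%
    intersect(c("cortisol", "pss", "pdq", "bayley_cog", "bayley_lang",
                "bayley_motor", "lang_receptive", "lang_expressive",
                "motor_fine", "motor_gross"), names(cohort))
  sel <- list(
    all = function(d) rep(TRUE, nrow(d)),
    stressed = function(d) d$group == "stressed",
    control = function(d) d$group == "control",
    male = function(d) d$sex == "male",
    female = function(d) d$sex == "female",
    male_stressed = function(d) d$sex == "male" & d$group == "stressed",
    male_control = function(d) d$sex == "male" & d$group == "control",
    female_stressed = function(d) d$sex == "female" & d$group == "stressed",
    female_control = function(d) d$sex == "female" & d$group == "control")
  strata <- match.arg(strata, names(sel), several.ok = TRUE)

  purrr::list_rbind(lapply(strata, function(st) {
    sub <- dat[sel[[st]](dat), ]
    recs <- purrr::list_rbind(lapply(feature_cols, function(fc) {
      purrr::list_rbind(lapply(outcome_cols, function(oc) {
        x <- sub[[fc]]
        y <- sub[[oc]]
        ok <- complete.cases(x, y)
        if (sum(ok) < min_n) return(NULL)
        x <- x[ok]
        y <- y[ok]
        if (sd(x) == 0 || sd(y) == 0) return(NULL)
        method <- if (shapiro_ok(x, alpha) && shapiro_ok(y, alpha)) {
          "pearson"
        } else {
          "spearman"
        }
        ct <- suppressWarnings(cor.test(x, y, method = method))
        tibble(stratum = st, feature = fc, outcome = oc, method = method,
               n = sum(ok), r = unname(ct$estimate), p = ct$p.value)
      }))
    }))
    if (is.null(recs) || nrow(recs) == 0) return(NULL)
    recs$q <- p.adjust(recs$p, method = "BH")
    recs
  }))
}
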