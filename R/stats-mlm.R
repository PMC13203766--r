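# Mixed-model stage: REML linear mixed models with a per-dyad random
# intercept (delegated to lme4/lmerTest), the three named presets, and the
# coupling-strength ratio derived from their coefficients.

#' Mixed-model specification
#'
#' @param response Response column name.
#' @param fixed One-sided formula of fixed effects (interactions included as
#'   written).
#' @param group Grouping column for the random intercept (default
#'   `"dyad_id"`).
#' @param covariates Optional character vector of covariate columns appended
#'   additively (the sensitivity-analysis workflow, e.g. gestational age at
#'   birth, maternal age, BMI).
#' @return A list of class `mlm_spec`.
#' @export
mlm_spec <- function(response, fixed, group = "dyad_id", covariates = NULL) {
  stopifnot(is.character(response), inherits(fixed, "formula"))
  structure(list(response = response, fixed = fixed, group = group,
                 covariates = covariates), class = "mlm_spec")
}

#' @rdname mlm_spec
#' @details
#' `mlm_spec_fractions()`: time-point acceleration/deceleration fractions ~
#' heart (`signal`, reference `fhr`) x event type (reference `accel`) + sex x
#' stress group.
#' @export
mlm_spec_fractions <- function(covariates = NULL) {
  mlm_spec("value", ~ signal * event_type + sex * group,
           covariates = covariates)
}

#' @rdname mlm_spec
#' @details
#' `mlm_spec_entropy()`: ER (or SE) features ~ conditioning paradigm
#' (reference `fhr_accel`) + heart + summary metric (reference `max`) + sex x
#' stress group. The conditioning coefficients of this preset feed
#' [coupling_strength()].
#' @export
mlm_spec_entropy <- function(covariates = NULL) {
  mlm_spec("value", ~ conditioning + signal + metric + sex * group,
           covariates = covariates)
}

#' @rdname mlm_spec
#' @param three_way Include the sex x stress x conditioning interaction.
#' @details
#' `mlm_spec_te()`: net-TE features ~ conditioning x summary metric + sex x
#' stress group (optionally + sex x stress x conditioning).
#' @export
mlm_spec_te <- function(covariates = NULL, three_way = FALSE) {
  f <- if (three_way) {
    ~ conditioning * metric + sex * group + sex:group:conditioning
  } else {
    ~ conditioning * metric + sex * group
  }
  mlm_spec("value", f, covariates = covariates)
}

#' Fit a random-intercept mixed model (REML)
#'
#' Thin wrapper around [lmerTest::lmer()]: REML estimation, random intercept
#' per subject, Satterthwaite degrees of freedom for the fixed-effect
#' p-values.
#'
#' @param data Long-format tibble (one row per observation).
#' @param spec An [mlm_spec()].
#' @return Object of class `dyadflow_mlm` with [tidy()] and [glance()]
#'   methods; `$converged` flags estimation problems.
#' @export
fit_mlm <- function(data, spec) {
  stopifnot(inherits(spec, "mlm_spec"))
  rhs <- paste(deparse(spec$fixed[[2]]), collapse = " ")
  if (!is.null(spec$covariates)) {
    rhs <- paste(rhs, "+", paste(spec$covariates, collapse = " + "))
  }
  fml <- stats::as.formula(
    sprintf("%s ~ %s + (1 | %s)", spec$response, rhs, spec$group))
  fit <- lmerTest::lmer(fml, data = data, REML = TRUE)
  msgs <- fit@optinfo$conv$lme4$messages
  structure(list(fit = fit, spec = spec,
                 converged = is.null(msgs), messages = msgs),
            class = "dyadflow_mlm")
}

#' @export
print.dyadflow_mlm <- function(x, ...) {
  cat("<dyadflow_mlm>", if (!x$converged) "(convergence flagged)", "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
tidy.dyadflow_mlm <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(term = rownames(cf), estimate = cf[, "Estimate"],
         std_error = cf[, "Std. Error"], statistic = cf[, "t value"],
         df = cf[, "df"], p_value = cf[, "Pr(>|t|)"])
}

#' @export
glance.dyadflow_mlm <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tibble(n_obs = stats::nobs(x$fit),
         n_groups = lme4::ngrps(x$fit)[[1]],
         sd_intercept = vc$sdcor[1], sigma = stats::sigma(x$fit),
         reml_criterion = as.numeric(lme4::REMLcrit(x$fit)),
         converged = x$converged)
}

#' Coupling strength from mixed-model coefficients
#'
#' The ratio `|beta_conditioned| / beta_baseline` quantifying how much of
#' the dynamic range set by the no-conditioning baseline coefficient a
#' conditioning effect captures (e.g. 0.123/0.206 = 0.597, the "60% rule"
#' for maternal decelerations).
#'
#' @param beta_conditioned Conditioning coefficient (numerator; absolute
#'   value is taken).
#' @param beta_baseline Baseline (no-conditioning) coefficient; must be
#'   positive for the ratio to be defined.
#' @return One-row tibble: `beta_conditioned`, `beta_baseline`, `ratio`,
#'   `undefined`.
#' @export
#' @examples
#' coupling_strength(-0.123, 0.206) # 0.597
coupling_strength <- function(beta_conditioned, beta_baseline) {
  check_number(beta_conditioned, "beta_conditioned")
  check_number(beta_baseline, "beta_baseline")
  if (beta_baseline <= 0) {
    return(tibble(beta_conditioned = beta_conditioned,
                  beta_baseline = beta_baseline,
                  ratio = NA_real_, undefined = TRUE))
  }
  tibble(beta_conditioned = beta_conditioned,
         beta_baseline = beta_baseline,
         ratio = abs(beta_conditioned) / beta_baseline,
         undefined = FALSE)
}

#' Coupling-strength ratios from a fitted entropy-rate model
#'
#' Extracts the conditioning coefficients of an [mlm_spec_entropy()] fit and
#' forms the ratio of each conditioned effect to the no-conditioning
#' baseline.
#'
#' @param mlm A `dyadflow_mlm` fitted with the entropy preset.
#' @return Tibble: `conditioning`, `beta`, `ratio`, `undefined`.
#' @export
coupling_strength_from_mlm <- function(mlm) {
  td <- tidy(mlm)
  cond_terms <- td[grepl("^conditioning", td$term), ]
  base <- cond_terms$estimate[cond_terms$term == "conditioningnone"]
  if (length(base) != 1) {
    abort("model has no `conditioningnone` term.",
          class = "dyadflow_input_error")
  }
  purrr::list_rbind(lapply(seq_len(nrow(cond_terms)), function(i) {
    cs <- coupling_strength(cond_terms$estimate[i], base)
    tibble(conditioning = sub("^conditioning", "", cond_terms$term[i]),
           beta = unname(cond_terms$estimate[i]), ratio = unname(cs$ratio),
           undefined = cs$undefined)
  }))
}

# --- long-table builders -----------------------------------------------------

#' Long tables for the mixed-model presets
#'
#' `mlm_long_fractions()` reshapes [cohort_epoch_stats()] output into the
#' 4-observations-per-dyad fractions table; `mlm_long_features()` reshapes a
#' cohort feature table into the per-feature long table for the ER/SE/net-TE
#' presets. Factor coding is fixed: `signal` reference `fhr`, `event_type`
#' reference `accel`, `conditioning` reference `fhr_accel`, `metric`
#' reference `max`, `sex` reference `female`, `group` reference `control`.
#'
#' @param stats_table Output of [cohort_epoch_stats()].
#' @param cohort Cohort table (`dyad_id`, `group`, `sex`, ...).
#' @return Long tibble with a `value` column and coded factors.
#' @export
mlm_long_fractions <- function(stats_table, cohort) {
  long <- tidyr::pivot_longer(
    stats_table[, c("dyad_id", "signal", "accel_frac_time",
                    "decel_frac_time")],
    c("accel_frac_time", "decel_frac_time"),
    names_to = "event_type", values_to = "value")
  long$event_type <- factor(sub("_frac_time", "", long$event_type),
                            levels = c("accel", "decel"))
  long$signal <- factor(long$signal, levels = c("fhr", "mhr"))
  dplyr::inner_join(long, cohort[, c("dyad_id", "group", "sex")],
                    by = "dyad_id")
}

#' @rdname mlm_long_fractions
#' @param features Cohort feature table (from [cohort_features()]).
#' @param metric_prefix `"er"`, `"se"` or `"nette"`.
#' @export
mlm_long_features <- function(features, cohort, metric_prefix = "er") {
  cols <- grep(paste0("^", metric_prefix, "_"), names(features), value = TRUE)
  long <- tidyr::pivot_longer(features[, c("dyad_id", cols)], -"dyad_id",
                              names_to = "feature", values_to = "value")
  pat <- paste0("^", metric_prefix, "_")
  rest <- sub(pat, "", long$feature)
  long$metric <- factor(sub(".*_(max|auc)$", "\\1", rest),
                        levels = c("max", "auc"))
  rest <- sub("_(max|auc)$", "", rest)
  if (metric_prefix == "nette") {
    long$signal <- factor("pair")
    long$conditioning <- rest
  } else {
    long$signal <- factor(sub("_.*$", "", rest), levels = c("fhr", "mhr"))
    long$conditioning <- sub("^(mhr|fhr)_", "", rest)
  }
  long$conditioning <- factor(long$conditioning,
                              levels = c("fhr_accel", "fhr_decel",
                                         "mhr_accel", "mhr_decel", "none"))
  out <- dplyr::inner_join(long, cohort, by = "dyad_id")
  out[!is.na(out$value), ]
}
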