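# Direct simulation of the mixed-model long tables with planted effects:
# the fast path for calibration and power checks of the model stage, without
# running the signal pipeline.

#' Simulate a mixed-model long table with planted effects
#'
#' Builds the design of one of the three model presets (acceleration/
#' deceleration fractions; entropy-rate features; net-TE features) for
#' `n_dyads` subjects and generates the response as
#' `intercept + planted fixed effects + subject random intercept + noise`.
#' Default effect sizes equal the coefficients reported for the reference
#' cohort, and the noise scales are chosen so that the implied standard
#' errors match the reported ones at n = 118.
#'
#' @param preset `"fractions"`, `"entropy"` or `"te"`.
#' @param n_dyads Number of subjects (default 118).
#' @param effects Named list of planted fixed effects; names follow the
#'   model terms (see Details). Unnamed effects default per preset.
#' @param sd_subject,sd_resid Random-intercept and residual SDs; preset
#'   defaults when `NULL`.
#' @param stress_fraction,male_fraction Group composition.
#' @param seed RNG seed.
#' @details Planted terms by preset: `fractions`: `intercept`, `event_decel`,
#'   `signal_mhr`, `signal_event`, `sex_male`, `stress`, `sex_stress`;
#'   `entropy`: `intercept`, `cond_none`, `cond_mhr_decel`, `cond_mhr_accel`,
#'   `cond_fhr_decel`, `metric_auc`, `signal_mhr`, `sex_male`, `stress`,
#'   `sex_stress`; `te`: `intercept`, `cond_none`, `metric_auc`,
#'   `metric_cond_none`, `sex_male`, `stress`, `sex_stress`.
#' @return Long tibble ready for [fit_mlm()] with the matching preset.
#' @export
simulate_mlm_long <- function(preset = c("fractions", "entropy", "te"),
                              n_dyads = 118, effects = list(),
                              sd_subject = NULL, sd_resid = NULL,
                              stress_fraction = 0.5, male_fraction = 0.415,
                              seed = 1) {
  preset <- match.arg(preset)
  defs <- switch(preset,
    fractions = list(
      effects = list(intercept = 0.515, event_decel = -0.061,
                     signal_mhr = -0.011, signal_event = 0.028,
                     sex_male = 0, stress = 0, sex_stress = 0),
      sd_subject = 0.02, sd_resid = 0.03),
    entropy = list(
      effects = list(intercept = -0.9, cond_none = 0.206,
                     cond_mhr_decel = -0.123, cond_mhr_accel = -0.034,
                     cond_fhr_decel = -0.082, metric_auc = -0.117,
                     signal_mhr = 0.05, sex_male = 0, stress = 0,
                     sex_stress = 0),
      sd_subject = 0.15, sd_resid = 0.25),
    te = list(
      effects = list(intercept = 0.05, cond_none = -0.037,
                     metric_auc = -0.077, metric_cond_none = 0.064,
                     sex_male = 0, stress = 0.023, sex_stress = -0.042),
      sd_subject = 0.04, sd_resid = 0.05))
  ef <- utils::modifyList(defs$effects, as.list(effects))
  sd_subject <- sd_subject %||% defs$sd_subject
  sd_resid <- sd_resid %||% defs$sd_resid

  with_seed(seed, {
    ids <- sprintf("S%03d", seq_len(n_dyads))
    group <- factor(sample(rep(c("stressed", "control"),
                               c(round(n_dyads * stress_fraction),
                                 n_dyads - round(n_dyads * stress_fraction)))),
                    levels = c("control", "stressed"))
    sex <- factor(sample(rep(c("male", "female"),
                             c(round(n_dyads * male_fraction),
                               n_dyads - round(n_dyads * male_fraction)))),
                  levels = c("female", "male"))
    subj <- tibble(dyad_id = ids, group = group, sex = sex,
                   u = rnorm(n_dyads, sd = sd_subject))

    design <- switch(preset,
      fractions = tidyr::expand_grid(
        dyad_id = ids,
        signal = factor(c("fhr", "mhr"), levels = c("fhr", "mhr")),
        event_type = factor(c("accel", "decel"),
                            levels = c("accel", "decel"))),
      entropy = tidyr::expand_grid(
        dyad_id = ids,
        signal = factor(c("fhr", "mhr"), levels = c("fhr", "mhr")),
        conditioning = factor(c("fhr_accel", "fhr_decel", "mhr_accel",
                                "mhr_decel", "none"),
                              levels = c("fhr_accel", "fhr_decel",
                                         "mhr_accel", "mhr_decel", "none")),
        metric = factor(c("max", "auc"), levels = c("max", "auc"))),
      te = tidyr::expand_grid(
        dyad_id = ids,
        conditioning = factor(c("fhr_accel", "fhr_decel", "mhr_accel",
                                "mhr_decel", "none"),
                              levels = c("fhr_accel", "fhr_decel",
                                         "mhr_accel", "mhr_decel", "none")),
        metric = factor(c("max", "auc"), levels = c("max", "auc"))))
    d <- dplyr::inner_join(design, subj, by = "dyad_id")

    mu <- rep(ef$intercept, nrow(d))
    male <- d$sex == "male"
    stressed <- d$group == "stressed"
    mu <- mu + ef$sex_male * male + ef$stress * stressed +
      ef$sex_stress * (male & stressed)
    if (preset == "fractions") {
      decel <- d$event_type == "decel"
      mhr <- d$signal == "mhr"
      mu <- mu + ef$event_decel * decel + ef$signal_mhr * mhr +
        ef$signal_event * (decel & mhr)
    } else if (preset == "entropy") {
      mu <- mu + ef$cond_none * (d$conditioning == "none") +
        ef$cond_mhr_decel * (d$conditioning == "mhr_decel") +
        ef$cond_mhr_accel * (d$conditioning == "mhr_accel") +
        ef$cond_fhr_decel * (d$conditioning == "fhr_decel") +
        ef$metric_auc * (d$metric == "auc") +
        ef$signal_mhr * (d$signal == "mhr")
    } else {
      none <- d$conditioning == "none"
      auc <- d$metric == "auc"
      mu <- mu + ef$cond_none * none + ef$metric_auc * auc +
        ef$metric_cond_none * (none & auc)
    }
    d$value <- mu + d$u + rnorm(nrow(d), sd = sd_resid)
    d$u <- NULL
    d
  })
}
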