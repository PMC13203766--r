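# Cohort-level synthesis: group labels, per-dyad coupling gains, stress
# biomarkers, and (null) neurodevelopmental outcomes.

#' Generate a synthetic cohort of dyads
#'
#' Draws group labels with exact counts (`round(n_dyads * stress_fraction)`
#' stressed, `round(n_dyads * male_fraction)` male), assigns each dyad a
#' coupling gain from the effect map
#' `c_i = c_base + stress*I(stressed) + sex_stress*I(male & stressed) + e_i`
#' (`e_i ~ N(0, c_sd^2)`, truncated at 0), generates stress scores (PSS-10,
#' PDQ), hair cortisol (log-normal, correlated with the gain residual via
#' `cortisol_cor`), and Bayley composite/subscale outcomes (pure noise by
#' default: the reference analysis found no robust feature--outcome
#' associations), then simulates one recording per dyad.
#'
#' @param spec A [cohort_spec()].
#' @param seed RNG seed (overrides `spec$seed`).
#' @param simulate_recordings If `FALSE`, return only the cohort table (fast
#'   path for cohort-structure checks).
#' @return A list with `cohort` (tibble, one row per dyad: `dyad_id`, `group`,
#'   `sex`, `coupling_gain`, stress measures, outcomes, and the covariates
#'   `maternal_age`, `ga_birth_weeks`, `bmi`) and `recordings` (named list of
#'   [generate_dyad()] outputs, or `NULL`).
#' @export
#' @examples
#' ch <- generate_cohort(cohort_spec(n_dyads = 6,
#'   dyad = sim_config(duration_s = 60)), seed = 2)
#' ch$cohort[, c("dyad_id", "group", "sex", "coupling_gain")]
generate_cohort <- function(spec, seed = NULL, simulate_recordings = TRUE) {
  if (!inherits(spec, "cohort_spec")) {
    abort("`spec` must be a cohort_spec.", class = "dyadflow_input_error")
  }
  seed <- seed %||% spec$seed
  if (is.null(seed)) {
    abort("a seed is required (in `spec$seed` or `seed`).",
          class = "dyadflow_input_error")
  }
  ef <- spec$effects
  n <- spec$n_dyads
  with_seed(seed, {
    n_stress <- round(n * spec$stress_fraction)
    group <- sample(rep(c("stressed", "control"), c(n_stress, n - n_stress)))
    n_male <- round(n * spec$male_fraction)
    sex <- sample(rep(c("male", "female"), c(n_male, n - n_male)))

    resid <- rnorm(n, sd = ef$c_sd)
    gain <- pmax(0, ef$c_base +
                   ef$stress * (group == "stressed") +
                   ef$sex_stress * (group == "stressed" & sex == "male") +
                   resid)

    # stress questionnaires (PSS >= 19 defines the stressed group)
    pss <- ifelse(group == "stressed",
                  pmax(19, round(rnorm(n, 22, 3))),
                  pmin(18, pmax(0, round(rnorm(n, 11, 4)))))
    pdq <- pmax(0, round(rnorm(n, ifelse(group == "stressed", 15, 7), 4)))

    # hair cortisol: log-normal; correlated with the gain residual
    rho <- ef$cortisol_cor
    z_c <- if (ef$c_sd > 0) resid / ef$c_sd else rnorm(n)
    z <- rho * z_c + sqrt(1 - rho^2) * rnorm(n)
    cortisol <- exp(log(78) + 0.25 * (group == "stressed") + 0.8 * z)

    out <- function(mu, sd) rnorm(n, mu, sd)
    cohort <- tibble(
      dyad_id = sprintf("FS-%03d", seq_len(n)),
      group = factor(group, levels = c("control", "stressed")),
      sex = factor(sex, levels = c("female", "male")),
      coupling_gain = gain,
      pss = pss, pdq = pdq, cortisol = cortisol,
      bayley_cog = out(100, ef$outcome_sd),
      bayley_lang = out(100, ef$outcome_sd),
      bayley_motor = out(100, ef$outcome_sd),
      lang_receptive = out(10, 3), lang_expressive = out(10, 3),
      motor_fine = out(10, 3), motor_gross = out(10, 3),
      maternal_age = round(rnorm(n, 33, 4.5), 1),
      ga_birth_weeks = round(rnorm(n, 39.7, 1.3), 1),
      bmi = round(exp(rnorm(n, log(22.7), 0.15)), 1))

    recordings <- NULL
    if (simulate_recordings) {
      dyad_seeds <- sample.int(.Machine$integer.max - 1L, n)
      recordings <- lapply(seq_len(n), function(i) {
        cfg <- spec$dyad
        cfg$coupling_gain <- gain[i]
        generate_dyad(cfg, seed = dyad_seeds[i])
      })
      names(recordings) <- cohort$dyad_id
    }
    list(cohort = cohort, recordings = recordings)
  })
}

#' Write a synthetic cohort to disk
#'
#' Writes the cohort table (`cohort.csv`), one RR CSV per dyad and heart
#' (`<id>_maternal_rr.csv`, `<id>_fetal_rr.csv`), the per-second quality masks
#' (`<id>_mask.csv`), and the ground-truth generator parameters
#' (`truth.json`).
#'
#' @param cohort_sim Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort_sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort_sim$cohort, file.path(dir, "cohort.csv"))
  truth <- lapply(cohort_sim$recordings, function(d) {
    cfg <- d$config
    cfg[c("duration_s", "coupling_gain", "coupling_lag_s",
          "decel_variance_factor", "f_ecg_hz", "seed")]
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  for (id in names(cohort_sim$recordings)) {
    d <- cohort_sim$recordings[[id]]
    write_rr_csv(d$maternal_rr, file.path(dir, paste0(id, "_maternal_rr.csv")))
    write_rr_csv(d$fetal_rr, file.path(dir, paste0(id, "_fetal_rr.csv")))
    readr::write_csv(tibble(second = seq_along(d$quality_mask) - 1L,
                            good = d$quality_mask),
                     file.path(dir, paste0(id, "_mask.csv")))
  }
  invisible(dir)
}
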