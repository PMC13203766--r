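# Net-TE positivity tests, outlier filtering, mixed models, coupling
# strength.

test_that("positivity test: limits, symmetry and agreement of the two p-values", {
  allpos <- test_net_te_positive(rep(1, 10))
  expect_true(allpos$degenerate)
  expect_equal(allpos$gaussian_p, 0)

  set.seed(30)
  centered <- rnorm(200)
  centered <- centered - mean(centered) # mean exactly 0
  r <- test_net_te_positive(centered)
  expect_equal(r$gaussian_p, 0.5, tolerance = 1e-10)

  # the two one-sided p-values agree closely for n >= 50 normal samples
  for (s in 1:5) {
    set.seed(s)
    v <- rnorm(60, mean = 0.2, sd = 1)
    r <- test_net_te_positive(v)
    expect_lt(abs(r$gaussian_p - r$t_p), 0.02)
  }
  expect_error(test_net_te_positive(c(1, NA, 2)),
               class = "dyadflow_input_error")
})

test_that("outlier filter removes exactly the planted extreme point", {
  set.seed(31)
  v <- rnorm(118)
  v[40] <- 24 # ~24 SD away
  fo <- filter_outliers(v, z_max = 10)
  expect_equal(fo$removed$index, 40)
  expect_equal(sum(!fo$kept), 1)
  # no outliers: identity
  fo2 <- filter_outliers(rnorm(50), z_max = 10)
  expect_equal(sum(!fo2$kept), 0)
  # all-equal values: flagged
  fo3 <- filter_outliers(rep(2, 10))
  expect_true(fo3$zero_variance)
})

test_that("coupling strength reproduces the reported ratios", {
  expect_equal(coupling_strength(-0.123, 0.206)$ratio, 0.597, tolerance = 5e-4)
  expect_equal(coupling_strength(-0.082, 0.206)$ratio, 0.398, tolerance = 5e-4)
  expect_equal(coupling_strength(-0.034, 0.206)$ratio, 0.165, tolerance = 5e-3)
  # the deceleration hierarchy: maternal ~1.5x the fetal conditioning effect
  expect_equal(0.123 / 0.082, 1.5, tolerance = 0.01)
  expect_equal(coupling_strength(0, 1)$ratio, 0)
  und <- coupling_strength(-0.1, 0)
  expect_true(und$undefined)
  expect_true(is.na(und$ratio))
  # scale invariance
  a <- coupling_strength(-0.123, 0.206)$ratio
  b <- coupling_strength(-1.23, 2.06)$ratio
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("mixed-model null calibration: fixed-effect p-values are uniform-ish", {
  ps <- vapply(1:20, function(s) {
    d <- simulate_mlm_long("fractions", n_dyads = 40, effects = list(
      event_decel = 0, signal_mhr = 0, signal_event = 0), seed = s)
    td <- tidy(fit_mlm(d, mlm_spec_fractions()))
    td$p_value[td$term == "event_typedecel"]
  }, numeric(1))
  expect_gt(mean(ps < 0.05), -1e-9) # sanity on extraction
  expect_lt(mean(ps < 0.05), 0.3) # no gross anti-conservativeness
  expect_gt(mean(ps > 0.2), 0.4)
})

test_that("planted event-type effect is recovered at cohort scale", {
  hits <- vapply(1:25, function(s) {
    d <- simulate_mlm_long("fractions", n_dyads = 118, seed = s)
    td <- tidy(fit_mlm(d, mlm_spec_fractions()))
    row <- td[td$term == "event_typedecel", ]
    (row$estimate < 0) && (row$p_value < 0.001) &&
      abs(row$estimate - (-0.061)) < 2 * row$std_error
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("planted stress and sex-stress effects on net TE recover their signs", {
  signs <- vapply(1:40, function(s) {
    d <- simulate_mlm_long("te", n_dyads = 118, seed = s)
    td <- tidy(fit_mlm(d, mlm_spec_te()))
    c(td$estimate[td$term == "groupstressed"] > 0,
      td$estimate[td$term == "sexmale:groupstressed"] < 0)
  }, logical(2))
  expect_gte(mean(signs[1, ]), 0.8)
  expect_gte(mean(signs[2, ]), 0.8)
})

test_that("entropy preset yields the coupling-strength table", {
  d <- simulate_mlm_long("entropy", n_dyads = 118, seed = 3)
  fit <- fit_mlm(d, mlm_spec_entropy())
  cs <- coupling_strength_from_mlm(fit)
  expect_true("mhr_decel" %in% cs$conditioning)
  ratio <- cs$ratio[cs$conditioning == "mhr_decel"]
  # planted -0.123 / +0.206 = 0.597
  expect_equal(ratio, 0.597, tolerance = 0.15)
  g <- glance(fit)
  expect_equal(g$n_groups, 118)
  expect_equal(g$n_obs, nrow(d))
})

test_that("covariate adjustment leaves planted effects essentially unchanged", {
  d <- simulate_mlm_long("te", n_dyads = 118, seed = 9)
  set.seed(9)
  ids <- unique(d$dyad_id)
  cov <- tibble::tibble(dyad_id = ids,
                        ga_birth_weeks = rnorm(length(ids), 39.7, 1.3),
                        maternal_age = rnorm(length(ids), 33, 4.5))
  d2 <- dplyr::inner_join(d, cov, by = "dyad_id")
  base <- tidy(fit_mlm(d2, mlm_spec_te()))
  adj <- tidy(fit_mlm(d2, mlm_spec_te(
    covariates = c("ga_birth_weeks", "maternal_age"))))
  b0 <- base$estimate[base$term == "groupstressed"]
  b1 <- adj$estimate[adj$term == "groupstressed"]
  expect_lt(abs(b1 - b0) / abs(b0), 0.25)
})

test_that("net-TE table reports strata and drops planted outliers", {
  set.seed(33)
  n <- 40
  features <- tibble::tibble(
    dyad_id = sprintf("FS-%03d", 1:n),
    nette_none_max = rnorm(n, 0.03, 0.01),
    nette_mhr_decel_max = rnorm(n, 0.0, 0.01))
  features$nette_none_max[5] <- 1.5 # extreme outlier
  cohort <- tibble::tibble(
    dyad_id = features$dyad_id,
    group = factor(rep(c("control", "stressed"), n / 2)),
    sex = factor(rep(c("female", "female", "male", "male"), n / 4)))
  nt <- net_te_table(features, cohort)
  expect_setequal(nt$stratum, c("all", "stressed", "control", "male", "female"))
  expect_equal(nt$n[nt$stratum == "all"], n - 1L) # outlier removed
  expect_lt(nt$nette_none_max[nt$stratum == "all"], 0.05)
  expect_gt(nt$nette_mhr_decel_max[nt$stratum == "all"], 0.2)
})
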