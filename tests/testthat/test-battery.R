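# Correlation battery: method selection, BH-FDR, strata, expected false
# positives.

make_null_cohort <- function(n = 60, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    dyad_id = sprintf("FS-%03d", 1:n),
    group = factor(rep(c("control", "stressed"), n / 2)),
    sex = factor(sample(rep(c("female", "male"), c(n - n %/% 2, n %/% 2)))),
    cortisol = exp(rnorm(n, log(78), 0.8)),
    pss = round(rnorm(n, 16, 6)),
    pdq = round(rnorm(n, 11, 4)),
    bayley_cog = rnorm(n, 100, 15),
    bayley_lang = rnorm(n, 100, 15),
    bayley_motor = rnorm(n, 100, 15))
}

test_that("expected false positives is n * alpha", {
  expect_equal(expected_false_positives(144, 0.05), 7.2)
  expect_equal(expected_false_positives(0, 0.05), 0)
  expect_equal(expected_false_positives(30, 0.05), 1.5)
  expect_error(expected_false_positives(-1), class = "dyadflow_input_error")
})

test_that("method selection is normality-driven and monotone pairs rank first", {
  set.seed(40)
  n <- 50
  cohort <- make_null_cohort(n, seed = 40)
  x <- rnorm(n)
  features <- tibble::tibble(
    dyad_id = cohort$dyad_id,
    f_normal = x,
    f_skewed = exp(x)) # clearly non-normal, monotone in x
  cohort$bayley_cog <- exp(2 * x) + 0 # monotone transform of f_skewed
  recs <- run_correlation_battery(features, cohort,
                                  outcome_cols = c("bayley_cog", "pss"))
  skew <- recs[recs$feature == "f_skewed" & recs$outcome == "bayley_cog", ]
  expect_equal(skew$method, "spearman")
  expect_equal(skew$r, 1, tolerance = 1e-12)
  expect_true(all(skew$q <= recs$q))
  norm_pair <- recs[recs$feature == "f_normal" & recs$outcome == "pss", ]
  expect_equal(norm_pair$method, "pearson")
  # q >= p always; BH is monotone in p
  expect_true(all(recs$q >= recs$p - 1e-12))
  o <- order(recs$p)
  expect_true(all(diff(recs$q[o]) >= -1e-12))
})

test_that("pairs below the minimum n are skipped", {
  cohort <- make_null_cohort(20, seed = 41)
  features <- tibble::tibble(dyad_id = cohort$dyad_id, f = rnorm(20))
  features$f[1:17] <- NA
  recs <- run_correlation_battery(features, cohort, min_n = 5)
  expect_false("f" %in% recs$feature)
})

test_that("strata are re-run as separate BH families", {
  cohort <- make_null_cohort(80, seed = 42)
  features <- tibble::tibble(dyad_id = cohort$dyad_id,
                             f1 = rnorm(80), f2 = rnorm(80))
  recs <- run_correlation_battery(features, cohort,
                                  strata = c("all", "stressed", "control",
                                             "male", "female"))
  expect_setequal(unique(recs$stratum),
                  c("all", "stressed", "control", "male", "female"))
  sub <- recs[recs$stratum == "male", ]
  expect_true(all(sub$n <= sum(cohort$sex == "male")))
  # BH within stratum: the q of the smallest p in a stratum equals
  # p * n_tests / 1 capped by monotonicity
  for (st in c("all", "male")) {
    rr <- recs[recs$stratum == st, ]
    expect_equal(rr$q, p.adjust(rr$p, "BH"), tolerance = 1e-12)
  }
})

test_that("under the global null a 144-test battery rarely discovers anything", {
  n_disc <- vapply(1:8, function(s) {
    cohort <- make_null_cohort(60, seed = 100 + s)
    set.seed(200 + s)
    features <- tibble::as_tibble(
      c(list(dyad_id = cohort$dyad_id),
        setNames(replicate(24, rnorm(60), simplify = FALSE),
                 paste0("f", 1:24))))
    recs <- run_correlation_battery(features, cohort,
                                    outcome_cols = c("cortisol", "pss", "pdq",
                                                     "bayley_cog",
                                                     "bayley_lang",
                                                     "bayley_motor"))
    expect_equal(nrow(recs), 144)
    sum(recs$q < 0.05)
  }, numeric(1))
  expect_gte(mean(n_disc == 0), 0.75)
  # nominal discoveries track the expected count
  expect_lt(mean(n_disc), 1)
})
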