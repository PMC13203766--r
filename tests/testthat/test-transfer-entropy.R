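# KSG transfer entropy against the Gaussian/Granger closed form, surrogate
# bias correction, and net-flow direction.

# linear coupled pair: x AR(1), y_{t+1} = a*y_t + c*x_t + noise
coupled_pair <- function(n, a = 0.5, cc = 0.4, phi = 0.8, seed = 1) {
  set.seed(seed)
  x <- as.numeric(arima.sim(list(ar = phi), n))
  y <- numeric(n)
  e <- rnorm(n)
  for (t in 2:n) y[t] <- a * y[t - 1] + cc * x[t - 1] + e[t]
  list(x = hr_series(x, fs = 1, tau = 1), y = hr_series(y, fs = 1, tau = 1),
       xv = x, yv = y)
}

granger_te <- function(x, y) {
  n <- length(x)
  v1 <- var(resid(lm(y[-1] ~ y[-n])))
  v2 <- var(resid(lm(y[-1] ~ y[-n] + x[-n])))
  0.5 * log(v1 / v2)
}

test_that("raw TE agrees with the Gaussian-Granger oracle within 10%", {
  cp <- coupled_pair(20000, seed = 21)
  oracle <- granger_te(cp$xv, cp$yv)
  te <- transfer_entropy(cp$x, cp$y, entropy_params(max_vectors = 20000))
  expect_gt(oracle, 0.05) # the system genuinely carries information
  expect_lt(abs(te$value_nats - oracle) / oracle, 0.10)
})

test_that("independent AR(1) pairs give raw TE within the surrogate null", {
  set.seed(22)
  n <- 4000
  x <- hr_series(as.numeric(arima.sim(list(ar = 0.8), n)), fs = 1, tau = 1)
  y <- hr_series(as.numeric(arima.sim(list(ar = 0.5), n)), fs = 1, tau = 1)
  p <- entropy_params(n_surrogates = 20, max_vectors = 2000)
  sc <- surrogate_correction(x, y, p)
  # raw TE within the spread of the surrogate distribution around its mean
  expect_lt(abs(sc$te_corrected), 0.02)
})

test_that("surrogate-corrected TE matches the oracle on a coupled system", {
  cp <- coupled_pair(12000, seed = 23)
  oracle <- granger_te(cp$xv, cp$yv)
  sc <- surrogate_correction(cp$x, cp$y,
                             entropy_params(max_vectors = 6000,
                                            n_surrogates = 10))
  expect_lt(abs(sc$te_corrected - oracle) / oracle, 0.12)
  expect_gt(sc$te_corrected, 0)
})

test_that("direction: unidirectional coupling gives TE_x->y > TE_y->x", {
  cp <- coupled_pair(8000, seed = 24)
  p <- entropy_params(max_vectors = 4000)
  fwd <- transfer_entropy(cp$x, cp$y, p)$value_nats
  rev <- transfer_entropy(cp$y, cp$x, p)$value_nats
  expect_gt(fwd, rev)
})

test_that("net TE: antisymmetry, symmetry null, and bound", {
  cp <- coupled_pair(6000, seed = 25)
  p <- entropy_params(max_vectors = 3000, n_surrogates = 5)
  nt <- net_transfer_entropy(cp$x, cp$y, p)
  # |netTE| never exceeds the sum of the directed magnitudes
  expect_lte(abs(nt$net_te), abs(nt$te_mf) + abs(nt$te_fm) + 1e-12)
  expect_equal(nt$net_te, nt$te_mf - nt$te_fm, tolerance = 1e-12)

  # symmetric bidirectional coupling with equal gains: netTE ~ 0
  set.seed(26)
  n <- 6000
  u <- numeric(n)
  w <- numeric(n)
  eu <- rnorm(n)
  ew <- rnorm(n)
  for (t in 2:n) {
    u[t] <- 0.4 * u[t - 1] + 0.3 * w[t - 1] + eu[t]
    w[t] <- 0.4 * w[t - 1] + 0.3 * u[t - 1] + ew[t]
  }
  nts <- net_transfer_entropy(hr_series(u, fs = 1, tau = 1),
                              hr_series(w, fs = 1, tau = 1), p)
  expect_lt(abs(nts$net_te), 0.02)
})

test_that("mismatched scales and missing data are rejected or propagated", {
  a <- hr_series(rnorm(500), fs = 1, tau = 1)
  b <- hr_series(rnorm(500), fs = 1, tau = 2)
  expect_error(transfer_entropy(a, b), class = "dyadflow_input_error")
  short <- hr_series(rnorm(50), fs = 1, tau = 1)
  long <- hr_series(rnorm(50), fs = 1, tau = 1)
  out <- transfer_entropy(short, long, entropy_params())
  expect_true(is.na(out$value_nats))
  nt <- net_transfer_entropy(short, long, entropy_params())
  expect_true(is.na(nt$net_te))
  expect_match(nt$reason, "insufficient")
})

test_that("more surrogates reduce correction variance, not its mean", {
  cp <- coupled_pair(3000, seed = 27)
  p1 <- entropy_params(max_vectors = 1500, n_surrogates = 2)
  p2 <- entropy_params(max_vectors = 1500, n_surrogates = 20)
  # same raw TE either way; corrected values differ only via the bias term
  s1 <- surrogate_correction(cp$x, cp$y, p1)
  s2 <- surrogate_correction(cp$x, cp$y, p2)
  expect_equal(s1$te_raw, s2$te_raw, tolerance = 1e-12)
  expect_equal(s1$te_surrogate_mean, s2$te_surrogate_mean, tolerance = 0.05)
})
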