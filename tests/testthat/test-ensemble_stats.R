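# hand-built ensemble with known counts, used for exact estimator checks
toy_ensemble <- function(counts, dt = 1) {
  structure(list(config = NULL,
                 times = seq(0, by = dt, length.out = ncol(counts)),
                 counts = counts, sample_ids = seq_len(nrow(counts)),
                 seeds = NULL),
            class = "bd_ensemble")
}

test_that("ensemble moments are exact on constructed data", {
  cst <- toy_ensemble(matrix(7, nrow = 5, ncol = 4))
  mom <- ensemble_moments(cst)
  expect_true(all(mom$mean == 7) && all(mom$var == 0))

  x <- matrix(c(1, 2, 3, 4,
                5, 1, 2, 0,
                2, 2, 2, 9), nrow = 3, byrow = TRUE)
  mom <- ensemble_moments(toy_ensemble(x))
  expect_equal(mom$mean, colMeans(x))
  expect_equal(mom$var, apply(x, 2, var))
  expect_error(ensemble_moments(toy_ensemble(x[1, , drop = FALSE])),
               "2 samples")
})

test_that("correlation estimators reduce to known identities", {
  set.seed(99)
  x <- matrix(rpois(200 * 3, 20), nrow = 200)
  ens <- toy_ensemble(x)
  # Cc(t, t) equals the ensemble variance exactly
  cc <- connected_correlation_empirical(ens, 1, 1)
  expect_equal(cc$value, var(x[, 2]))
  expect_equal(pearson_empirical(ens, 1, 1)$value, 1)
  # matches stats::cov / stats::cor at distinct times
  expect_equal(connected_correlation_empirical(ens, 0, 2)$value,
               cov(x[, 1], x[, 3]))
  expect_equal(pearson_empirical(ens, 0, 2)$value, cor(x[, 1], x[, 3]))
  # rescaling invariance of the Pearson estimator
  ens2 <- toy_ensemble(x * 17)
  expect_equal(pearson_empirical(ens2, 0, 2)$value,
               pearson_empirical(ens, 0, 2)$value)
  # shuffling sample order leaves estimates unchanged (no pooling bias)
  ens3 <- toy_ensemble(x[sample(nrow(x)), ])
  expect_equal(connected_correlation_empirical(ens3, 0, 2)$value,
               connected_correlation_empirical(ens, 0, 2)$value)
  # off-grid times rejected, no interpolation
  expect_error(connected_correlation_empirical(ens, 0.5, 2), "grid")
  expect_error(pearson_empirical(toy_ensemble(matrix(3, 5, 2)), 0, 1),
               "zero sample variance")
})

test_that("jackknife stderr shrinks with the sample count", {
  gen <- function(n, seed) {
    set.seed(seed)
    z <- rnorm(n)
    toy_ensemble(cbind(20 + 3 * z, 20 + 3 * z + rnorm(n)))
  }
  se_small <- pearson_empirical(gen(50, 1), 0, 1)$stderr
  se_big <- pearson_empirical(gen(5000, 1), 0, 1)$stderr
  expect_lt(se_big, se_small / 5)
})

test_that("extinction fraction counts final zeros with binomial error", {
  x <- matrix(c(0, 0, 0,
                5, 3, 0,
                5, 3, 1,
                2, 0, 0), nrow = 4, byrow = TRUE)
  ef <- extinction_fraction(toy_ensemble(x))
  expect_equal(ef$fraction, 0.75)
  expect_equal(ef$stderr, sqrt(0.75 * 0.25 / 4))
  # pure-birth ensembles never go extinct
  cfg <- sim_config("refractory", refractory_params(1, 1), n0 = 3, dt = 0.1,
                    t_max = 5, n_samples = 20, seed = 5)
  expect_equal(extinction_fraction(simulate_ensemble(cfg))$fraction, 0)
})

test_that("exponential and power-law fits recover exact inputs", {
  tt <- seq(1, 30, by = 0.5)
  fit <- fit_exponential_rate(tt, exp(0.3 * tt), window = range(tt))
  expect_equal(fit$estimate, 0.3, tolerance = 1e-12)
  expect_equal(fit$diagnostic, 1)
  # default window is the last third
  fit2 <- fit_exponential_rate(tt, exp(0.3 * tt))
  expect_equal(fit2$estimate, 0.3, tolerance = 1e-12)
  expect_gte(fit2$window[1], tt[1] + 2 / 3 * diff(range(tt)) - 1e-9)
  expect_error(fit_exponential_rate(tt, c(-1, exp(0.3 * tt[-1])),
                                    window = range(tt)), "positive")

  t2 <- seq(100, 1000, by = 50)
  pw <- fit_power_law_exponent(t2, sqrt(50 / t2))
  expect_equal(pw$estimate, 0.5, tolerance = 1e-12)
  expect_error(fit_power_law_exponent(seq(100, 500, 50), sqrt(50 / seq(100, 500, 50))),
               "decade")
  # decline-phase rho decays exponentially, not as a power law
  dec <- markov_rates(0.015, 0.03)
  t2d <- seq(60, 600, by = 30)
  rho <- pearson_correlation_markov(dec, 50, 50, t2d)
  pw_fit <- fit_power_law_exponent(t2d, rho)
  exp_fit <- fit_exponential_rate(t2d, rho, window = range(t2d))
  expect_gt(exp_fit$diagnostic, pw_fit$diagnostic)
})

test_that("oscillation-period estimator recovers a constructed period", {
  tt <- seq(0.01, 10, by = 0.01)
  fit <- estimate_oscillation_period(tt, exp(0.4 * tt) * (1 + 0.5 * cos(2 * pi * tt / 1.7)))
  expect_true(fit$detected)
  expect_equal(fit$estimate, 1.7, tolerance = 0.05)
  # a clean exponential yields a flagged no-oscillation result
  fit2 <- estimate_oscillation_period(tt, exp(0.4 * tt))
  expect_false(fit2$detected)
})

test_that("empirical estimators converge to the analytic correlations", {
  crit <- markov_rates(0.03, 0.03)
  cfg <- sim_config("markov", crit, n0 = 50, dt = 1, t_max = 400,
                    n_samples = 500, seed = 1)
  ens <- simulate_ensemble(cfg)
  # constancy in t2 at fixed t1 (critical): estimates mutually consistent
  cc <- lapply(c(100, 200, 400), function(t2)
    connected_correlation_empirical(ens, 50, t2))
  for (i in 1:2) for (j in (i + 1):3) {
    d <- abs(cc[[i]]$value - cc[[j]]$value)
    expect_lt(d, 2 * sqrt(cc[[i]]$stderr^2 + cc[[j]]$stderr^2))
  }
  for (est in cc)
    expect_lt(abs(est$value - connected_correlation_markov(crit, 50, 50, est$t2)),
              3 * est$stderr)
  rp <- pearson_empirical(ens, 25, 100)
  expect_lt(abs(rp$value - 0.5), 2 * rp$stderr)

  # growth phase: log Cc vs (t2 - t1) has slope sigma - kappa, and rho
  # approaches its plateau
  gro <- markov_rates(0.03, 0.015)
  cfg <- sim_config("markov", gro, n0 = 50, dt = 1, t_max = 300,
                    n_samples = 300, seed = 2)
  ensg <- simulate_ensemble(cfg)
  t2s <- seq(120, 300, by = 20)
  ccv <- vapply(t2s, function(t2)
    connected_correlation_empirical(ensg, 100, t2)$value, numeric(1))
  slope <- fit_exponential_rate(t2s, ccv, window = range(t2s))
  expect_equal(slope$estimate, 0.015, tolerance = 0.15)
  rp <- pearson_empirical(ensg, 100, 300)
  expect_lt(abs(rp$value - pearson_correlation_markov(gro, 50, 100, 300)),
            3 * rp$stderr)
})
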