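test_that("step_probability implements 1 - exp(-rate dt)", {
  expect_identical(step_probability(0, 5), 0)
  expect_equal(step_probability(0.03, 1), 0.0295545, tolerance = 1e-7 / 0.03)
  # approaches 1 from below (indistinguishable from 1 in double precision
  # once rate*dt is huge)
  expect_lte(step_probability(50, 100), 1)
  expect_gt(step_probability(50, 100), 1 - 1e-12)
  expect_lt(step_probability(3, 4), 1)
  # strictly increasing in both arguments
  expect_true(all(diff(step_probability(seq(0, 1, 0.1), 0.5)) > 0))
  expect_gt(step_probability(0.1, 2), step_probability(0.1, 1))
  expect_error(step_probability(-1, 1), ">= 0")
})

test_that("sim_config validates its invariants", {
  r <- markov_rates(0.03, 0.015)
  expect_error(sim_config("markov", r, n0 = 50, dt = 1, t_max = 100.5,
                          n_samples = 1, seed = 1), "integer number of steps")
  expect_error(sim_config("markov", markov_rates(2, 2), n0 = 10, dt = 1,
                          t_max = 10, seed = 1), "smaller dt")
  expect_error(sim_config("markov", r, n0 = 50, dt = 1, t_max = 100,
                          n_samples = 1), "seed")
  expect_error(sim_config("refractory", r, n0 = 50, dt = 1, t_max = 100,
                          seed = 1), "refractory_params")
  expect_warning(sim_config("refractory", refractory_params(1, 0.55),
                            n0 = 1, dt = 0.1, t_max = 1, seed = 1), "rounded")
})

test_that("markov simulator honors trajectory invariants and determinism", {
  r0 <- markov_rates(0, 0)
  cfg <- sim_config("markov", r0, n0 = 50, dt = 1, t_max = 20, seed = 4)
  expect_true(all(simulate_markov(cfg)$counts == 50))  # frozen dynamics

  dec <- markov_rates(0.015, 0.03)
  cfg <- sim_config("markov", dec, n0 = 5, dt = 1, t_max = 400,
                    n_samples = 40, seed = 9)
  ens <- simulate_ensemble(cfg)
  # absorbing state: zeros are final
  hit0 <- apply(ens$counts, 1, function(x) {
    i <- which(x == 0)[1]
    is.na(i) || all(x[i:length(x)] == 0)
  })
  expect_true(all(hit0))
  expect_true(any(ens$counts[, ncol(ens$counts)] == 0))
  expect_true(all(ens$counts >= 0) && all(ens$counts == round(ens$counts)))
  expect_true(all(ens$counts[, 1] == 5))
  # determinism: identical config -> identical ensemble
  ens2 <- simulate_ensemble(cfg)
  expect_identical(ens$counts, ens2$counts)
  # single-sample ensemble equals the bare trajectory with the derived seed
  cfg1 <- sim_config("markov", dec, n0 = 5, dt = 1, t_max = 50, seed = 9)
  expect_identical(simulate_ensemble(cfg1)$counts[1, ],
                   as.numeric(simulate_markov(cfg1, sample_id = 1L)$counts))
})

test_that("discrete-time growth ensemble matches the analytic mean", {
  gro <- markov_rates(0.03, 0.015)
  # dt = 0.1 keeps the O(dt) discretization bias well below the SE
  cfg <- sim_config("markov", gro, n0 = 50, dt = 0.1, t_max = 100,
                    n_samples = 300, seed = 17)
  mom <- ensemble_moments(simulate_ensemble(cfg))
  i <- length(mom$times)
  expect_lt(abs(mom$mean[i] - mean_markov(gro, 50, 100)), 3 * mean_se(mom, i))
})

test_that("refractory simulator: frozen before T, non-decreasing, mean matches theory", {
  p <- refractory_params(1, 1)
  cfg <- sim_config("refractory", p, n0 = 50, dt = 0.01, t_max = 10,
                    n_samples = 200, seed = 23)
  ens <- simulate_ensemble(cfg)
  expect_true(all(ens$counts[, ens$times <= 1] == 50))
  expect_true(all(apply(ens$counts, 1, function(x) all(diff(x) >= 0))))
  mom <- ensemble_moments(ens)
  theo <- mean_refractory(p, 50, mom$times, check_convergence = FALSE)
  for (t in c(2, 5, 10)) {
    i <- which(mom$times == t)
    expect_lt(abs(mom$mean[i] - theo[i]), 3 * mean_se(mom, i))
  }
})

test_that("event-driven backend is exact", {
  # pure death from a single cell: extinction time is Exp(kappa); on the
  # grid it is rounded up, so the grid mean is dt / (1 - exp(-kappa dt))
  kap <- 0.5; dt <- 0.1
  cfg <- sim_config("markov", markov_rates(0, kap), n0 = 1, dt = dt,
                    t_max = 40, n_samples = 10000, seed = 31,
                    backend = "event_driven")
  ens <- simulate_ensemble(cfg)
  ext_t <- apply(ens$counts, 1, function(x) ens$times[which(x == 0)[1]])
  expect_true(all(is.finite(ext_t)))
  se <- sd(ext_t) / sqrt(length(ext_t))
  expect_lt(abs(mean(ext_t) - dt / (1 - exp(-kap * dt))), 3 * se)

  # growth-phase moments match the closed forms
  r <- markov_rates(0.4, 0.2)
  cfg <- sim_config("markov", r, n0 = 10, dt = 0.5, t_max = 5,
                    n_samples = 10000, seed = 32, backend = "event_driven")
  mom <- ensemble_moments(simulate_ensemble(cfg))
  i <- length(mom$times)
  expect_lt(abs(mom$mean[i] - mean_markov(r, 10, 5)), 3 * mean_se(mom, i))
  se_var <- mom$var[i] * sqrt(2 / (mom$n_samples - 1))
  expect_lt(abs(mom$var[i] - var_markov(r, 10, 5)), 3 * se_var)

  cfg <- sim_config("markov", markov_rates(0, 0), n0 = 7, dt = 1, t_max = 10,
                    seed = 33, backend = "event_driven")
  expect_true(all(simulate_event_driven(cfg)$counts == 7))
})

test_that("growth-phase samples look like time-shifted exponentials", {
  gro <- markov_rates(0.03, 0.015)
  cfg <- sim_config("markov", gro, n0 = 50, dt = 1, t_max = 400,
                    n_samples = 60, seed = 41)
  ens <- simulate_ensemble(cfg)
  slopes <- apply(ens$counts, 1, function(x) {
    sel <- ens$times >= 200 & x > 500
    if (sum(sel) < 50) return(NA_real_)
    unname(coef(lm(log(x[sel]) ~ ens$times[sel]))[2])
  })
  slopes <- slopes[!is.na(slopes)]
  expect_gt(length(slopes), 50)
  expect_lt(sd(slopes) / mean(slopes), 0.10)
  expect_equal(mean(slopes), 0.015, tolerance = 0.1)
})

test_that("ensemble CSV round-trips and has the documented shape", {
  cfg <- sim_config("markov", markov_rates(0.02, 0.01), n0 = 5, dt = 1,
                    t_max = 10, n_samples = 4, seed = 8)
  ens <- simulate_ensemble(cfg)
  path <- tempfile(fileext = ".csv")
  write_ensemble_csv(ens, path)
  tab <- read_ensemble_csv(path)
  expect_identical(names(tab), c("sample_id", "time", "count"))
  expect_equal(nrow(tab), 4 * 11)
  expect_equal(matrix(tab$count, nrow = 4, byrow = TRUE), unname(ens$counts))
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(sidecar$seed, 8)
  expect_equal(sidecar$rates$sigma, 0.02)
  unlink(c(path, paste0(path, ".json")))
})

test_that("population cap aborts runaway growth with a clear error", {
  cfg <- sim_config("markov", markov_rates(2, 0), n0 = 100, dt = 0.1,
                    t_max = 100, seed = 2, max_pop = 1e4)
  expect_error(simulate_markov(cfg), "max_pop")
})
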