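#' Per-step event probability from a continuous-time rate
#'
#' Discrete-time transition probability corresponding to a rate:
#' `P = 1 - exp(-rate * dt)` (evaluated via `expm1` for accuracy).
#'
#' @param rate Event rate per unit time, >= 0; vectorized.
#' @param dt Time step > 0.
#' @return Probability in `[0, 1)`.
#' @examples
#' step_probability(0.03, 1)  # 0.0295545...
#' @export
step_probability <- function(rate, dt) {
  if (!is.numeric(rate) || any(!is.finite(rate)) || any(rate < 0))
    stop("rate must be finite and >= 0", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single number > 0", call. = FALSE)
  -expm1(-rate * dt)
}

#' Simulation configuration
#'
#' Validated bundle of everything a stochastic run needs. The horizon must
#' be an integer number of steps; for the Markov model the per-step
#' probabilities must satisfy `P_sigma + P_kappa <= 1`; for the refractory
#' model `T` is rounded to the nearest multiple of `dt` (with a warning
#' when the rounding is more than 1e-9 relative).
#'
#' @param model `"markov"` or `"refractory"`.
#' @param rates A [markov_rates()] or [refractory_params()] object matching
#'   `model`.
#' @param n0 Initial number of cells (integer >= 1).
#' @param dt Time step > 0.
#' @param t_max Horizon > 0; `t_max/dt` must be an integer (1e-9 tolerance).
#' @param n_samples Number of trajectories (integer >= 1).
#' @param seed Base RNG seed (required integer); per-sample seeds are
#'   derived deterministically from `(seed, sample_id)`.
#' @param backend `"discrete"` (default) or `"event_driven"` (Markov only).
#' @param max_pop Population cap; runs exceeding it abort with an error
#'   rather than exhausting memory (default 1e7).
#' @return An object of class `sim_config`.
#' @examples
#' sim_config("markov", markov_rates(0.03, 0.015), n0 = 50, dt = 1,
#'            t_max = 100, n_samples = 10, seed = 1)
#' @export
sim_config <- function(model = c("markov", "refractory"), rates, n0, dt, t_max,
                       n_samples = 1L, seed, backend = c("discrete", "event_driven"),
                       max_pop = 1e7) {
  model <- match.arg(model)
  backend <- match.arg(backend)
  if (model == "markov" && !inherits(rates, "markov_rates"))
    stop("model 'markov' needs markov_rates()", call. = FALSE)
  if (model == "refractory" && !inherits(rates, "refractory_params"))
    stop("model 'refractory' needs refractory_params()", call. = FALSE)
  if (model == "refractory" && backend == "event_driven")
    stop("event-driven backend is implemented for the Markov model only",
         call. = FALSE)
  check_n0(n0)
  check_scalar(dt, "dt", lower = 0, strict = TRUE)
  check_scalar(t_max, "t_max", lower = 0, strict = TRUE)
  if (missing(seed) || is.null(seed))
    stop("seed is required (reproducibility contract)", call. = FALSE)
  check_scalar(seed, "seed")
  if (seed != round(seed)) stop("seed must be an integer", call. = FALSE)
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1 ||
      n_samples != round(n_samples))
    stop("n_samples must be a single integer >= 1", call. = FALSE)
  n_steps <- t_max / dt
  if (abs(n_steps - round(n_steps)) > 1e-9 * max(1, abs(n_steps)))
    stop("t_max/dt must be an integer number of steps", call. = FALSE)
  n_steps <- as.integer(round(n_steps))

  T_steps <- NULL
  if (model == "markov") {
    ps <- step_probability(rates$sigma, dt)
    pk <- step_probability(rates$kappa, dt)
    if (ps + pk > 1)
      stop("P_sigma + P_kappa > 1: choose a smaller dt", call. = FALSE)
  } else {
    T_steps <- rates$T / dt
    if (abs(T_steps - round(T_steps)) > 1e-9 * max(1, T_steps))
      warning(sprintf("refractory period T = %g rounded to %g (nearest multiple of dt)",
                      rates$T, round(T_steps) * dt), call. = FALSE)
    T_steps <- as.integer(round(T_steps))
  }
  structure(list(model = model, rates = rates, n0 = as.integer(n0),
                 dt = as.numeric(dt), t_max = as.numeric(t_max),
                 n_steps = n_steps, T_steps = T_steps,
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 backend = backend, max_pop = max_pop),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %s model (%s backend), n0 = %d, dt = %g, t_max = %g, %d samples, seed %d\n",
              x$model, x$backend, x$n0, x$dt, x$t_max, x$n_samples, x$seed))
  invisible(x)
}

# deterministic per-sample seed: two rounds of a Lehmer-style mix, exact in
# doubles (48271 * 2^31 < 2^53)
derive_seed <- function(seed, sample_id) {
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  s <- (s * 48271) %% m
  s <- (s + as.numeric(sample_id)) %% m
  s <- (s * 48271) %% m
  as.integer(s + 1)
}

new_trajectory <- function(times, counts, sample_id, seed_used) {
  structure(list(times = times, counts = counts, sample_id = sample_id,
                 seed_used = seed_used),
            class = "bd_trajectory")
}

#' Discrete-time simulation of the Markovian birth-death model
#'
#' Per step each living cell independently dies with probability `P_kappa
#' = 1 - exp(-kappa dt)`, divides with `P_sigma = 1 - exp(-sigma dt)`, or
#' persists (mutually exclusive outcomes). The per-step death/division
#' counts are drawn from the corresponding multinomial distribution, which
#' is distributionally identical to resolving one uniform draw per cell.
#' Zero is absorbing. Identical `(config, seed, sample_id)` give identical
#' output.
#'
#' @param config A [sim_config()] with `model = "markov"`.
#' @param sample_id Sample index used to derive the per-trajectory seed.
#' @return A `bd_trajectory`: list with `times`, integer `counts`,
#'   `sample_id`, `seed_used`.
#' @export
simulate_markov <- function(config, sample_id = 1L) {
  stopifnot(inherits(config, "sim_config"), config$model == "markov")
  sd_ <- derive_seed(config$seed, sample_id)
  set.seed(sd_)
  ps <- step_probability(config$rates$sigma, config$dt)
  pk <- step_probability(config$rates$kappa, config$dt)
  prob <- c(pk, ps, 1 - pk - ps)
  counts <- integer(config$n_steps + 1L)
  n <- config$n0
  counts[1L] <- n
  for (i in seq_len(config$n_steps)) {
    if (n > 0L) {
      ev <- stats::rmultinom(1L, n, prob)
      n <- n - ev[1L] + ev[2L]
      if (n > config$max_pop)
        stop(sprintf("population exceeded cap max_pop = %g at t = %g",
                     config$max_pop, i * config$dt), call. = FALSE)
    }
    counts[i + 1L] <- n
  }
  new_trajectory(seq(0, config$t_max, by = config$dt), counts, sample_id, sd_)
}

#' Discrete-time simulation of the refractory-period model
#'
#' Cell ages (time since last division) are tracked in units of steps; a
#' cell is eligible once `age * dt >= T` (inclusive threshold, Heaviside
#' `H(0) = 1`). Each eligible cell divides with probability
#' `1 - exp(-gamma0 dt)` per step; a division replaces the mother by two
#' cells of age 0, and newborns cannot divide in the step that created
#' them. There is no death, so counts are non-decreasing, and counts stay
#' exactly `n0` for `t <= T`.
#'
#' @param config A [sim_config()] with `model = "refractory"`.
#' @inheritParams simulate_markov
#' @return A `bd_trajectory`.
#' @export
simulate_refractory <- function(config, sample_id = 1L) {
  stopifnot(inherits(config, "sim_config"), config$model == "refractory")
  sd_ <- derive_seed(config$seed, sample_id)
  set.seed(sd_)
  pg <- step_probability(config$rates$gamma0, config$dt)
  Tn <- config$T_steps
  counts <- numeric(config$n_steps + 1L)
  counts[1L] <- config$n0
  if (Tn == 0L) {
    # pure-birth Markov limit; newborns become eligible the following step
    n <- as.numeric(config$n0)
    for (i in seq_len(config$n_steps)) {
      b <- stats::rbinom(1L, n, pg)
      n <- n + b
      if (n > config$max_pop)
        stop(sprintf("population exceeded cap max_pop = %g", config$max_pop),
             call. = FALSE)
      counts[i + 1L] <- n
    }
  } else {
    # b[j]: cells of age j-1 steps (j = 1..Tn), b[Tn+1]: age >= Tn (eligible)
    b <- numeric(Tn + 1L)
    b[1L] <- config$n0
    for (i in seq_len(config$n_steps)) {
      div <- stats::rbinom(1L, b[Tn + 1L], pg)
      mature_in <- b[Tn]
      b[Tn + 1L] <- b[Tn + 1L] - div + mature_in
      if (Tn > 1L) b[2:Tn] <- b[1:(Tn - 1L)]
      b[1L] <- 2 * div
      nn <- sum(b)
      if (nn > config$max_pop)
        stop(sprintf("population exceeded cap max_pop = %g", config$max_pop),
             call. = FALSE)
      counts[i + 1L] <- nn
    }
  }
  new_trajectory(seq(0, config$t_max, by = config$dt), counts, sample_id, sd_)
}

#' Exact event-driven simulation of the Markovian model
#'
#' Continuous-time validation backend: waiting times between events are
#' exponential with rate `n (sigma + kappa)` and each event is a division
#' with probability `sigma/(sigma + kappa)`. The exact path is resampled
#' onto the uniform output grid by last-value interpolation, so the grid
#' counts have exactly the continuous-time law at the grid times.
#'
#' @inheritParams simulate_markov
#' @return A `bd_trajectory`.
#' @export
simulate_event_driven <- function(config, sample_id = 1L) {
  stopifnot(inherits(config, "sim_config"), config$model == "markov")
  sd_ <- derive_seed(config$seed, sample_id)
  set.seed(sd_)
  sigma <- config$rates$sigma
  kappa <- config$rates$kappa
  times <- seq(0, config$t_max, by = config$dt)
  n <- as.numeric(config$n0)
  if (sigma + kappa == 0) {
    return(new_trajectory(times, rep(config$n0, length(times)), sample_id, sd_))
  }
  pdiv <- sigma / (sigma + kappa)
  ev_t <- 0
  counts <- integer(length(times))
  counts[1L] <- n
  idx <- 2L  # next grid index to fill
  repeat {
    if (n == 0) break
    ev_t <- ev_t + stats::rexp(1L, rate = n * (sigma + kappa))
    while (idx <= length(times) && times[idx] < ev_t) {
      counts[idx] <- n
      idx <- idx + 1L
    }
    if (idx > length(times)) break
    n <- if (stats::runif(1L) < pdiv) n + 1 else n - 1
    if (n > config$max_pop)
      stop(sprintf("population exceeded cap max_pop = %g", config$max_pop),
           call. = FALSE)
  }
  if (idx <= length(times)) counts[idx:length(times)] <- n
  new_trajectory(times, counts, sample_id, sd_)
}

#' Simulate an ensemble of trajectories
#'
#' Runs `n_samples` independent trajectories of the configured model and
#' backend on a shared time grid. Per-sample seeds are derived
#' deterministically from `(seed, sample_id)`, so the ensemble is
#' bit-reproducible for a fixed configuration (including under any
#' sample-level parallel scheme that preserves the seed derivation).
#'
#' @param config A [sim_config()].
#' @return An object of class `bd_ensemble`: list with `config`, `times`,
#'   a `n_samples x length(times)` integer matrix `counts`, `sample_ids`
#'   and `seeds`.
#' @examples
#' cfg <- sim_config("markov", markov_rates(0.03, 0.03), n0 = 50, dt = 1,
#'                   t_max = 50, n_samples = 20, seed = 42)
#' ens <- simulate_ensemble(cfg)
#' @export
simulate_ensemble <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  simfun <- if (config$backend == "event_driven") simulate_event_driven
            else if (config$model == "markov") simulate_markov
            else simulate_refractory
  times <- seq(0, config$t_max, by = config$dt)
  counts <- matrix(0, nrow = config$n_samples, ncol = length(times))
  seeds <- integer(config$n_samples)
  for (s in seq_len(config$n_samples)) {
    tr <- simfun(config, sample_id = s)
    counts[s, ] <- tr$counts
    seeds[s] <- tr$seed_used
  }
  structure(list(config = config, times = times, counts = counts,
                 sample_ids = seq_len(config$n_samples), seeds = seeds),
            class = "bd_ensemble")
}

#' @export
print.bd_ensemble <- function(x, ...) {
  cat(sprintf("bd_ensemble: %d %s trajectories on t in [0, %g] (dt = %g)\n",
              nrow(x$counts), x$config$model, x$config$t_max, x$config$dt))
  invisible(x)
}

#' Write / read an ensemble as CSV (long format)
#'
#' Serializes trajectories as `sample_id,time,count` rows (UTF-8, '.'
#' decimal separator) with the configuration echoed in a JSON sidecar
#' `<path>.json`.
#'
#' @param ens A `bd_ensemble`.
#' @param path Output CSV path.
#' @return `write_ensemble_csv`: the path, invisibly. `read_ensemble_csv`:
#'   a `data.table` with columns `sample_id`, `time`, `count`.
#' @export
write_ensemble_csv <- function(ens, path) {
  stopifnot(inherits(ens, "bd_ensemble"))
  nt <- length(ens$times)
  dt_ <- data.table::data.table(
    sample_id = rep(ens$sample_ids, each = nt),
    time = rep(ens$times, times = nrow(ens$counts)),
    count = as.vector(t(ens$counts)))
  data.table::fwrite(dt_, path)
  cfg <- ens$config
  sidecar <- list(model = cfg$model,
                  rates = unclass(cfg$rates),
                  n0 = cfg$n0, dt = cfg$dt, t_max = cfg$t_max,
                  n_samples = cfg$n_samples, seed = cfg$seed,
                  backend = cfg$backend)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @export
read_ensemble_csv <- function(path) {
  data.table::fread(path)
}
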