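#' Read / write a run configuration
#'
#' Run configurations are flat JSON objects with a `schema_version` field.
#' Recognized keys: `schema_version`, `model`, `sigma`, `kappa`, `gamma0`,
#' `T`, `n0`, `dt`, `t_max`, `n_samples`, `seed`, `backend`. Unknown keys
#' are rejected by name; `seed` is mandatory (reproducibility contract).
#' The representation round-trips losslessly.
#'
#' @param path Path of the JSON configuration file.
#' @return `read_run_config`: a named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop(sprintf("malformed config %s: %s", path,
                                 conditionMessage(e)), call. = FALSE))
  validate_run_config(raw)
}

run_config_keys <- c("schema_version", "model", "sigma", "kappa", "gamma0",
                     "T", "n0", "dt", "t_max", "n_samples", "seed", "backend")

validate_run_config <- function(raw) {
  unknown <- setdiff(names(raw), run_config_keys)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  required <- c("model", "n0", "dt", "t_max", "seed")
  missing_ <- setdiff(required, names(raw))
  if (length(missing_))
    stop(sprintf("missing required config key(s): %s",
                 paste(missing_, collapse = ", ")), call. = FALSE)
  if (is.null(raw$schema_version)) raw$schema_version <- 1L
  if (is.null(raw$n_samples)) raw$n_samples <- 1L
  if (is.null(raw$backend)) raw$backend <- "discrete"
  if (raw$model == "markov") {
    if (is.null(raw$sigma) || is.null(raw$kappa))
      stop("markov model requires keys sigma and kappa", call. = FALSE)
  } else if (raw$model == "refractory") {
    if (is.null(raw$gamma0) || is.null(raw$T))
      stop("refractory model requires keys gamma0 and T", call. = FALSE)
  } else {
    stop(sprintf("unknown model '%s'", raw$model), call. = FALSE)
  }
  structure(raw[intersect(run_config_keys, names(raw))], class = "run_config")
}

#' @param config A `run_config` (or plain named list with the same keys).
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  config <- validate_run_config(unclass(config))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build a [sim_config()] from a run configuration
#' @param config A `run_config`.
#' @return A `sim_config`.
#' @export
as_sim_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rates <- if (config$model == "markov")
    markov_rates(config$sigma, config$kappa)
  else refractory_params(config$gamma0, config$T)
  sim_config(config$model, rates, n0 = config$n0, dt = config$dt,
             t_max = config$t_max, n_samples = config$n_samples,
             seed = config$seed, backend = config$backend)
}

#' Write a report table as CSV and JSON
#'
#' @param table A data frame (e.g. from [reproduce_experiment()]).
#' @param path Output path; `.csv` and `.json` files are written with this
#'   stem (atomically: temp file then rename).
#' @param force Overwrite existing files (default FALSE).
#' @return The CSV path, invisibly.
#' @export
write_results <- function(table, path, force = FALSE) {
  stem <- sub("\\.(csv|json)$", "", path)
  csv <- paste0(stem, ".csv")
  js <- paste0(stem, ".json")
  for (p in c(csv, js)) {
    if (file.exists(p) && !force)
      stop(sprintf("%s exists; use force = TRUE to overwrite", p), call. = FALSE)
  }
  tmp <- paste0(csv, ".tmp")
  utils::write.csv(table, tmp, row.names = FALSE)
  file.rename(tmp, csv)
  tmp <- paste0(js, ".tmp")
  jsonlite::write_json(table, tmp, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  file.rename(tmp, js)
  invisible(csv)
}

report_row <- function(quantity, parameters, analytic, simulated, stderr,
                       nsig) {
  z <- if (is.finite(stderr) && stderr > 0) (simulated - analytic) / stderr
       else NA_real_
  data.frame(quantity = quantity, parameters = parameters,
             analytic = analytic, simulated = simulated, stderr = stderr,
             z = z, pass = is.finite(z) && abs(z) <= nsig,
             stringsAsFactors = FALSE)
}

#' Reproduce figure-level ensemble experiments
#'
#' Re-runs the ensemble experiments behind the three result figures and
#' compares simulated moments/correlations against the analytic formulas
#' (recomputed at run time, never hard-coded):
#' \describe{
#'   \item{fig2}{Mean and variance at selected times for the decline
#'     (`sigma = 0.015, kappa = 0.03`), growth (`0.03, 0.015`) and critical
#'     (`0.03, 0.03`) phases, `n0 = 50`, 300 samples.}
#'   \item{fig3}{Two-time correlations: decline-phase connected correlation
#'     decay, growth-phase Pearson plateau, critical constancy of the
#'     connected correlation in `t2`, critical Pearson
#'     `rho(25, 100) = 1/2` and the critical power-law exponent 1/2.}
#'   \item{fig4}{Refractory model (`gamma0 = 1, T = 1`): late-time
#'     log-slopes of ensemble mean and variance against the Malthusian rate
#'     `s_0` and `2 s_0`, and the mean against the pole expansion.}
#' }
#' Comparisons use 3-sigma bands at full scale, widened to 4-sigma when
#' `scale < 1` (smaller ensembles).
#'
#' @param experiment One of `"fig2"`, `"fig3"`, `"fig4"`.
#' @param seed Base seed (required).
#' @param scale Sample-count scale factor in (0, 1].
#' @return A `data.frame` report table (one row per compared quantity).
#' @export
reproduce_experiment <- function(experiment = c("fig2", "fig3", "fig4"),
                                 seed, scale = 1) {
  experiment <- match.arg(experiment)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0 || scale > 1)
    stop("scale must be in (0, 1]", call. = FALSE)
  nsig <- if (scale < 1) 4 else 3
  out <- switch(experiment,
                fig2 = reproduce_fig2(seed, scale, nsig),
                fig3 = reproduce_fig3(seed, scale, nsig),
                fig4 = reproduce_fig4(seed, scale, nsig))
  attr(out, "experiment") <- experiment
  attr(out, "seed") <- seed
  attr(out, "scale") <- scale
  out
}

fig_phases <- function() list(
  decline = markov_rates(0.015, 0.03),
  growth = markov_rates(0.03, 0.015),
  critical = markov_rates(0.03, 0.03))

reproduce_fig2 <- function(seed, scale, nsig) {
  n0 <- 50L
  ns <- max(20L, as.integer(round(300 * scale)))
  rows <- list()
  for (phase in names(fig_phases())) {
    rates <- fig_phases()[[phase]]
    # dt = 0.1 keeps the O(dt) discrete-time bias well below Monte Carlo noise
    cfg <- sim_config("markov", rates, n0 = n0, dt = 0.1, t_max = 100,
                      n_samples = ns, seed = derive_seed(seed, match(phase, names(fig_phases()))))
    ens <- simulate_ensemble(cfg)
    mom <- ensemble_moments(ens)
    for (t in c(50, 100)) {
      i <- grid_index(ens, t, "t")
      mu_an <- mean_markov(rates, n0, t)
      v_an <- var_markov(rates, n0, t)
      se_mu <- sqrt(mom$var[i] / ns)
      se_v <- mom$var[i] * sqrt(2 / (ns - 1))
      par <- sprintf("%s sigma=%g kappa=%g t=%g", phase, rates$sigma,
                     rates$kappa, t)
      rows[[length(rows) + 1L]] <-
        report_row(paste0("mean_", phase, "_t", t), par, mu_an, mom$mean[i],
                   se_mu, nsig)
      rows[[length(rows) + 1L]] <-
        report_row(paste0("var_", phase, "_t", t), par, v_an, mom$var[i],
                   se_v, nsig)
    }
  }
  do.call(rbind, rows)
}

reproduce_fig3 <- function(seed, scale, nsig) {
  n0 <- 50L
  ns <- max(50L, as.integer(round(500 * scale)))
  rows <- list()
  crit <- fig_phases()$critical
  cfg <- sim_config("markov", crit, n0 = n0, dt = 1, t_max = 1000,
                    n_samples = ns, seed = derive_seed(seed, 11))
  ens <- simulate_ensemble(cfg)
  # constancy of Cc in t2 at fixed t1, and Pearson rho(25,100) = 1/2
  for (t2 in c(100, 200, 400)) {
    cc <- connected_correlation_empirical(ens, 50, t2)
    rows[[length(rows) + 1L]] <- report_row(
      paste0("critical_Cc_t1=50_t2=", t2), "sigma=kappa=0.03",
      connected_correlation_markov(crit, n0, 50, t2), cc$value, cc$stderr, nsig)
  }
  rp <- pearson_empirical(ens, 25, 100)
  rows[[length(rows) + 1L]] <- report_row(
    "critical_pearson_t1=25_t2=100", "sigma=kappa=0.03",
    pearson_correlation_markov(crit, n0, 25, 100), rp$value, rp$stderr, nsig)
  pf <- pearson_powerlaw_fit(ens, 50, t2 = seq(100, 1000, by = 100))
  rows[[length(rows) + 1L]] <- report_row(
    "critical_powerlaw_exponent", "sigma=kappa=0.03 t1=50 t2 in [100,1000]",
    0.5, pf$estimate, pf$stderr, nsig)
  # decline-phase decay of the connected correlation
  dec <- fig_phases()$decline
  cfgd <- sim_config("markov", dec, n0 = n0, dt = 1, t_max = 300,
                     n_samples = ns, seed = derive_seed(seed, 12))
  ensd <- simulate_ensemble(cfgd)
  for (t2 in c(100, 200)) {
    cc <- connected_correlation_empirical(ensd, 50, t2)
    rows[[length(rows) + 1L]] <- report_row(
      paste0("decline_Cc_t1=50_t2=", t2), "sigma=0.015 kappa=0.03",
      connected_correlation_markov(dec, n0, 50, t2), cc$value, cc$stderr, nsig)
  }
  # growth-phase Pearson correlation stays high as t2 grows
  gro <- fig_phases()$growth
  cfgg <- sim_config("markov", gro, n0 = n0, dt = 1, t_max = 300,
                     n_samples = ns, seed = derive_seed(seed, 13))
  ensg <- simulate_ensemble(cfgg)
  rp <- pearson_empirical(ensg, 100, 300)
  rows[[length(rows) + 1L]] <- report_row(
    "growth_pearson_t1=100_t2=300", "sigma=0.03 kappa=0.015",
    pearson_correlation_markov(gro, n0, 100, 300), rp$value, rp$stderr, nsig)
  do.call(rbind, rows)
}

reproduce_fig4 <- function(seed, scale, nsig) {
  params <- refractory_params(1, 1)
  n0 <- 50L
  ns <- max(50L, as.integer(round(200 * scale)))
  cfg <- sim_config("refractory", params, n0 = n0, dt = 0.01, t_max = 25,
                    n_samples = ns, seed = derive_seed(seed, 41))
  ens <- simulate_ensemble(cfg)
  mom <- ensemble_moments(ens)
  s0 <- effective_rate(params)
  rows <- list()
  fit_m <- fit_exponential_rate(mom$times, mom$mean, window = c(15, 25))
  rows[[length(rows) + 1L]] <- report_row(
    "mean_log_slope_vs_s0", "gamma0=1 T=1 window [15,25]", s0,
    fit_m$estimate, fit_m$stderr, nsig)
  fit_v <- fit_exponential_rate(mom$times, mom$var, window = c(15, 25))
  rows[[length(rows) + 1L]] <- report_row(
    "var_log_slope_vs_2s0", "gamma0=1 T=1 window [15,25]", 2 * s0,
    fit_v$estimate, fit_v$stderr, nsig)
  for (t in c(5, 10)) {
    i <- grid_index(ens, t, "t")
    mu_an <- mean_refractory(params, n0, t)
    se_mu <- sqrt(mom$var[i] / ns)
    rows[[length(rows) + 1L]] <- report_row(
      paste0("mean_t", t), "gamma0=1 T=1", mu_an, mom$mean[i], se_mu, nsig)
  }
  do.call(rbind, rows)
}
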