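#' Parameters of the Markovian birth-death model
#'
#' Bundles the per-cell proliferation rate `sigma` and apoptosis rate
#' `kappa` (both transition probabilities per unit time) of the
#' continuous-time birth-death branching process.
#'
#' @param sigma Proliferation rate, a single finite number >= 0.
#' @param kappa Apoptosis rate, a single finite number >= 0.
#' @return An object of class `markov_rates`.
#' @examples
#' markov_rates(sigma = 0.03, kappa = 0.015)
#' @export
markov_rates <- function(sigma, kappa) {
  check_scalar(sigma, "sigma", lower = 0)
  check_scalar(kappa, "kappa", lower = 0)
  structure(list(sigma = as.numeric(sigma), kappa = as.numeric(kappa)),
            class = "markov_rates")
}

#' @export
print.markov_rates <- function(x, ...) {
  cat(sprintf("Markov birth-death rates: sigma = %g, kappa = %g (%s phase)\n",
              x$sigma, x$kappa, classify_phase(x)))
  invisible(x)
}

#' Parameters of the refractory-period (non-Markovian) model
#'
#' After each division both daughter cells have age 0 and cannot divide
#' while their age is below the refractory period `T`; past that age they
#' divide with constant rate `gamma0`. Apoptosis is absent, so `T = 0`
#' reduces the model to a Markovian pure-birth process with rate `gamma0`.
#'
#' @param gamma0 Post-refractory proliferation rate, a single number > 0.
#' @param T Refractory period (time units), a single number >= 0.
#' @return An object of class `refractory_params`.
#' @examples
#' refractory_params(gamma0 = 1, T = 1)
#' @export
refractory_params <- function(gamma0, T) {
  check_scalar(gamma0, "gamma0", lower = 0, strict = TRUE)
  check_scalar(T, "T", lower = 0)
  structure(list(gamma0 = as.numeric(gamma0), T = as.numeric(T)),
            class = "refractory_params")
}

#' @export
print.refractory_params <- function(x, ...) {
  cat(sprintf("Refractory-period model: gamma0 = %g, T = %g\n", x$gamma0, x$T))
  invisible(x)
}

#' Dynamical phase of the birth-death model
#'
#' Classifies parameters into the decline (`sigma < kappa`), growth
#' (`sigma > kappa`) or critical/homeostatic (`sigma == kappa`, exact
#' comparison) phase.
#'
#' @param rates A [markov_rates()] object.
#' @return One of `"decline"`, `"growth"`, `"critical"`.
#' @examples
#' classify_phase(markov_rates(0.03, 0.03))
#' @export
classify_phase <- function(rates) {
  stopifnot(inherits(rates, "markov_rates"))
  if (rates$sigma < rates$kappa) "decline"
  else if (rates$sigma > rates$kappa) "growth"
  else "critical"
}

# scalar validation shared by constructors; strict = TRUE demands > lower
check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  ok <- if (strict) x > lower else x >= lower
  if (!ok)
    stop(sprintf("'%s' must be %s %g", name, if (strict) ">" else ">=", lower),
         call. = FALSE)
  invisible(TRUE)
}
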