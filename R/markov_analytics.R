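#' Mean population of the birth-death model
#'
#' Expected number of cells at time `t` starting from `n0` cells:
#' `n0 * exp((sigma - kappa) * t)`, which reduces to the constant `n0` in
#' the critical (homeostatic) state `sigma == kappa`.
#'
#' @param rates A [markov_rates()] object.
#' @param n0 Initial number of cells (integer >= 1).
#' @param t Time(s) >= 0; vectorized.
#' @return Expected count(s), same length as `t`.
#' @examples
#' mean_markov(markov_rates(0.03, 0.015), n0 = 50, t = 100)
#' @export
mean_markov <- function(rates, n0, t) {
  stopifnot(inherits(rates, "markov_rates"))
  check_n0(n0)
  check_time(t)
  n0 * exp((rates$sigma - rates$kappa) * t)
}

#' Variance of the birth-death population
#'
#' For `sigma != kappa` the variance is
#' `n0 * (sigma + kappa)/(sigma - kappa) * exp(d t) * (exp(d t) - 1)` with
#' `d = sigma - kappa`; at criticality it is `2 * n0 * kappa * t`. The
#' implementation evaluates `expm1` so the 0/0 form at `sigma == kappa` is
#' handled without cancellation, and the two branches agree in the limit.
#'
#' @inheritParams mean_markov
#' @return Variance(s) of the count, same length as `t`.
#' @examples
#' var_markov(markov_rates(0.03, 0.03), n0 = 50, t = 100)  # 2*50*0.03*100
#' @export
var_markov <- function(rates, n0, t) {
  stopifnot(inherits(rates, "markov_rates"))
  check_n0(n0)
  check_time(t)
  sigma <- rates$sigma
  kappa <- rates$kappa
  if (sigma == kappa) return(2 * n0 * kappa * t)
  u <- (sigma - kappa) * t
  # expm1(u)/u -> 1 smoothly as u -> 0 (t = 0 handled explicitly)
  ratio <- ifelse(u == 0, 1, expm1(u) / u)
  n0 * (sigma + kappa) * t * exp(u) * ratio
}

#' Extinction probability of the birth-death model
#'
#' Probability that the population ever reaches the absorbing zero state:
#' 1 when `kappa >= sigma`, and `(kappa/sigma)^n0` in the growth phase.
#' Undefined for `sigma == kappa == 0` (frozen dynamics).
#'
#' @inheritParams mean_markov
#' @return A probability in `[0, 1]`.
#' @examples
#' extinction_probability(markov_rates(0.03, 0.015), n0 = 50)  # ~9e-16
#' @export
extinction_probability <- function(rates, n0) {
  stopifnot(inherits(rates, "markov_rates"))
  check_n0(n0)
  if (rates$sigma == 0 && rates$kappa == 0)
    stop("extinction probability undefined for sigma = kappa = 0 (frozen process)",
         call. = FALSE)
  if (rates$kappa >= rates$sigma) 1 else (rates$kappa / rates$sigma)^n0
}

#' Connected two-time correlation (auto-covariance) of the count
#'
#' `Cc(t1, t2) = Cov(n(t1), n(t2)) = Var(n(t1)) * exp((sigma - kappa) *
#' (t2 - t1))` for `t1 <= t2`. At criticality this is `2 * n0 * kappa * t1`,
#' independent of `t2` (the process only remembers the earlier time).
#'
#' @inheritParams mean_markov
#' @param t1 Earlier time, `0 <= t1 <= t2`.
#' @param t2 Later time(s) `>= t1`; vectorized.
#' @return Covariance value(s).
#' @export
connected_correlation_markov <- function(rates, n0, t1, t2) {
  stopifnot(inherits(rates, "markov_rates"))
  check_n0(n0)
  check_time(t1)
  check_time(t2)
  if (any(t2 < t1))
    stop("t2 must be >= t1 (first argument is the earlier time)", call. = FALSE)
  var_markov(rates, n0, t1) * exp((rates$sigma - rates$kappa) * (t2 - t1))
}

#' Pearson two-time correlation of the count
#'
#' Normalized correlation `rho(t1, t2) = Cc(t1, t2) /
#' sqrt(Var(n(t1)) Var(n(t2)))`, which lies in `[0, 1]` for these models.
#' At criticality `rho = sqrt(t1/t2)`; in the growth phase it tends to
#' `sqrt(1 - exp(-(sigma - kappa) t1))` as `t2 -> Inf` (pass `t2 = Inf` to
#' obtain the limit; in the decline and critical phases the limit is 0).
#'
#' @inheritParams connected_correlation_markov
#' @param t1 Earlier time, strictly positive (zero variance at `t1 = 0`).
#' @return Correlation value(s) in `[0, 1]`.
#' @examples
#' pearson_correlation_markov(markov_rates(0.03, 0.03), 50, t1 = 25, t2 = 100)
#' @export
pearson_correlation_markov <- function(rates, n0, t1, t2) {
  stopifnot(inherits(rates, "markov_rates"))
  check_n0(n0)
  if (!is.numeric(t1) || length(t1) != 1L || !is.finite(t1) || t1 <= 0)
    stop("t1 must be a single time > 0 (variance vanishes at t1 = 0)",
         call. = FALSE)
  if (any(t2 < t1))
    stop("t2 must be >= t1 (first argument is the earlier time)", call. = FALSE)
  d <- rates$sigma - rates$kappa
  out <- numeric(length(t2))
  inf <- is.infinite(t2)
  if (any(inf)) {
    lim <- if (d > 0) sqrt(-expm1(-d * t1)) else 0
    out[inf] <- lim
  }
  if (any(!inf)) {
    tt <- t2[!inf]
    # rho = Var(t1) e^{d (t2-t1)} / sqrt(Var(t1) Var(t2)), evaluated in log
    # space so that large horizons cannot overflow the variances
    rho <- exp(0.5 * log_var_markov(rates, n0, t1) + d * (tt - t1) -
                 0.5 * log_var_markov(rates, n0, tt))
    rho[tt == t1] <- 1
    out[!inf] <- rho
  }
  out
}

# log Var(n(t)) without forming exp((sigma-kappa) t) explicitly
log_var_markov <- function(rates, n0, t) {
  sigma <- rates$sigma
  kappa <- rates$kappa
  d <- sigma - kappa
  if (d == 0) return(log(2 * n0 * kappa * t))
  u <- d * t
  # log[ e^u (e^u - 1) / d ] = 2u + log1p(-e^-u) - log(d)   (u > 0)
  #                          = u + log1p(-e^u) - log(-d)    (u < 0)
  core <- ifelse(u > 0, 2 * u + log1p(-exp(-u)) - log(d),
                 u + log1p(-exp(u)) - log(-d))
  log(n0 * (sigma + kappa)) + core
}

#' Correlation time of the birth-death model
#'
#' In the decline phase correlations decay exponentially with
#' characteristic time `1/(kappa - sigma)`. At criticality the correlation
#' time is infinite; in the growth phase fluctuations never fully
#' decorrelate, so no correlation time exists and a tagged sentinel is
#' returned instead of a number.
#'
#' @param rates A [markov_rates()] object.
#' @return A list with components `tau` (a number, `Inf`, or `NA`) and
#'   `status` (`"finite"`, `"infinite"`, `"undefined"`), of class
#'   `correlation_time`.
#' @examples
#' correlation_time(markov_rates(0.015, 0.03))  # tau = 66.67
#' @export
correlation_time <- function(rates) {
  stopifnot(inherits(rates, "markov_rates"))
  phase <- classify_phase(rates)
  out <- switch(phase,
    decline  = list(tau = 1 / (rates$kappa - rates$sigma), status = "finite"),
    critical = list(tau = Inf, status = "infinite"),
    growth   = list(tau = NA_real_, status = "undefined"))
  structure(out, class = "correlation_time")
}

#' @export
print.correlation_time <- function(x, ...) {
  msg <- switch(x$status,
    finite    = sprintf("correlation time tau = %g", x$tau),
    infinite  = "correlation time is infinite (critical state)",
    undefined = "correlation time undefined (growth phase never fully decorrelates)")
  cat(msg, "\n")
  invisible(x)
}

check_n0 <- function(n0) {
  if (!is.numeric(n0) || length(n0) != 1L || !is.finite(n0) || n0 < 1 ||
      n0 != round(n0))
    stop("n0 must be a single integer >= 1", call. = FALSE)
  invisible(TRUE)
}

check_time <- function(t) {
  if (!is.numeric(t) || length(t) < 1L || any(!is.finite(t)) || any(t < 0))
    stop("times must be finite and >= 0", call. = FALSE)
  invisible(TRUE)
}
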