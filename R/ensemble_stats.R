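#' Ensemble mean and variance series
#'
#' Per-time-point sample mean and unbiased (n-1) sample variance across
#' trajectories. Extinct trajectories are included as zeros: the analytic
#' moments these estimators target are unconditional, averaging over the
#' absorbing state.
#'
#' @param ens A `bd_ensemble` with at least 2 samples.
#' @return A list with `times`, `mean`, `var` and `n_samples`.
#' @export
ensemble_moments <- function(ens) {
  stopifnot(inherits(ens, "bd_ensemble"))
  n <- nrow(ens$counts)
  if (n < 2L) stop("need at least 2 samples for a variance", call. = FALSE)
  mu <- colMeans(ens$counts)
  v <- (colSums(ens$counts^2) - n * mu^2) / (n - 1)
  list(times = ens$times, mean = mu, var = pmax(v, 0), n_samples = n)
}

grid_index <- function(ens, t, name) {
  i <- which(abs(ens$times - t) <= 1e-9 * max(1, abs(t)))
  if (length(i) != 1L)
    stop(sprintf("%s = %g is not on the ensemble time grid (no interpolation)",
                 name, t), call. = FALSE)
  i
}

new_correlation_estimate <- function(t1, t2, value, stderr, n_samples, kind) {
  structure(list(t1 = t1, t2 = t2, value = value, stderr = stderr,
                 n_samples = n_samples, kind = kind),
            class = "correlation_estimate")
}

#' @export
print.correlation_estimate <- function(x, ...) {
  cat(sprintf("%s correlation(t1 = %g, t2 = %g) = %.5g (stderr %.3g, n = %d)\n",
              x$kind, x$t1, x$t2, x$value, x$stderr, x$n_samples))
  invisible(x)
}

#' Empirical connected two-time correlation (auto-covariance)
#'
#' Unbiased sample covariance of the counts at two grid times across
#' trajectories; standard error by delete-one jackknife over samples. At
#' `t1 == t2` it equals the ensemble variance exactly.
#'
#' @param ens A `bd_ensemble` with at least 2 samples.
#' @param t1,t2 Grid times with `t1 <= t2` (off-grid times are an error).
#' @return A `correlation_estimate`.
#' @export
connected_correlation_empirical <- function(ens, t1, t2) {
  stopifnot(inherits(ens, "bd_ensemble"))
  if (t2 < t1) stop("t2 must be >= t1", call. = FALSE)
  n <- nrow(ens$counts)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  x <- ens$counts[, grid_index(ens, t1, "t1")]
  y <- ens$counts[, grid_index(ens, t2, "t2")]
  est <- stats::cov(x, y)
  loo <- loo_cov(x, y)
  se <- jackknife_se(loo)
  new_correlation_estimate(t1, t2, est, se, n, "connected")
}

#' Empirical Pearson two-time correlation
#'
#' Sample covariance normalized by the product of the sample standard
#' deviations at the two times; jackknife standard error. Invariant under
#' rescaling all counts by a positive constant.
#'
#' @inheritParams connected_correlation_empirical
#' @return A `correlation_estimate` with value in `[-1, 1]`.
#' @export
pearson_empirical <- function(ens, t1, t2) {
  stopifnot(inherits(ens, "bd_ensemble"))
  if (t2 < t1) stop("t2 must be >= t1", call. = FALSE)
  n <- nrow(ens$counts)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  x <- ens$counts[, grid_index(ens, t1, "t1")]
  y <- ens$counts[, grid_index(ens, t2, "t2")]
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero sample variance at t1 or t2: Pearson correlation undefined",
         call. = FALSE)
  est <- stats::cor(x, y)
  loo <- loo_cor(x, y)
  se <- jackknife_se(loo)
  new_correlation_estimate(t1, t2, est, se, n, "pearson")
}

# leave-one-out covariances (unbiased), vectorized over left-out index
loo_cov <- function(x, y) {
  n <- length(x)
  Sx <- sum(x); Sy <- sum(y); Sxy <- sum(x * y)
  (Sxy - x * y - (Sx - x) * (Sy - y) / (n - 1)) / (n - 2)
}

loo_cor <- function(x, y) {
  n <- length(x)
  cxy <- loo_cov(x, y)
  cxx <- loo_cov(x, x)
  cyy <- loo_cov(y, y)
  cxy / sqrt(pmax(cxx * cyy, .Machine$double.xmin))
}

jackknife_se <- function(loo) {
  n <- length(loo)
  sqrt((n - 1) / n * sum((loo - mean(loo))^2))
}

#' Fraction of extinct trajectories
#'
#' Fraction of trajectories whose final count is zero (zero is absorbing,
#' so this is the fraction extinct by the horizon), with a binomial (Wald)
#' standard error.
#'
#' @param ens A `bd_ensemble`.
#' @return A list with `fraction`, `stderr` and `n_samples`.
#' @export
extinction_fraction <- function(ens) {
  stopifnot(inherits(ens, "bd_ensemble"))
  n <- nrow(ens$counts)
  p <- mean(ens$counts[, ncol(ens$counts)] == 0)
  list(fraction = p, stderr = sqrt(p * (1 - p) / n), n_samples = n)
}

new_fit_result <- function(estimate, stderr, window, diagnostic,
                           detected = TRUE) {
  structure(list(estimate = estimate, stderr = stderr, window = window,
                 diagnostic = diagnostic, detected = detected),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (!x$detected) {
    cat("no oscillation detected\n")
  } else {
    cat(sprintf("fit: estimate = %.6g (stderr %.3g), window [%g, %g], diagnostic %.4g\n",
                x$estimate, x$stderr, x$window[1], x$window[2], x$diagnostic))
  }
  invisible(x)
}

#' Exponential growth/decay rate by log-linear least squares
#'
#' Least-squares slope of `log(values)` versus `times` on a window
#' (default: the last third of the time range, avoiding early transients).
#'
#' @param times Time grid.
#' @param values Strictly positive series on the window.
#' @param window Length-2 numeric `c(t_lo, t_hi)`, or NULL for the default.
#' @return A `fit_result` with the slope, its standard error, the window
#'   and R^2 as diagnostic.
#' @export
fit_exponential_rate <- function(times, values, window = NULL) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values))
  if (is.null(window))
    window <- c(times[1] + 2 / 3 * diff(range(times)), max(times))
  sel <- times >= window[1] & times <= window[2]
  if (sum(sel) < 3L) stop("window contains fewer than 3 points", call. = FALSE)
  if (any(values[sel] <= 0))
    stop("series must be strictly positive on the fit window", call. = FALSE)
  fit <- stats::lm(log(values[sel]) ~ times[sel])
  sm <- suppressWarnings(summary(fit))  # silence "essentially perfect fit" on exact inputs
  new_fit_result(unname(stats::coef(fit)[2]), sm$coefficients[2, 2], window,
                 sm$r.squared)
}

#' Power-law exponent by log-log least squares
#'
#' Magnitude of the least-squares slope of `log(values)` versus `log(t2)`;
#' requires the `t2` range to span at least one decade.
#'
#' @param t2 Later times (positive, spanning >= one decade).
#' @param values Positive correlation values at those times.
#' @return A `fit_result` (estimate is the magnitude of the slope; R^2 as
#'   diagnostic).
#' @export
fit_power_law_exponent <- function(t2, values) {
  stopifnot(is.numeric(t2), is.numeric(values), length(t2) == length(values))
  if (any(t2 <= 0) || any(values <= 0))
    stop("power-law fit needs positive times and values", call. = FALSE)
  if (max(t2) / min(t2) < 10)
    stop("t2 range must span at least one decade", call. = FALSE)
  fit <- stats::lm(log(values) ~ log(t2))
  sm <- suppressWarnings(summary(fit))  # silence "essentially perfect fit" on exact inputs
  new_fit_result(abs(unname(stats::coef(fit)[2])), sm$coefficients[2, 2],
                 range(t2), sm$r.squared)
}

#' Critical-exponent fit of the empirical Pearson correlation
#'
#' Computes the empirical Pearson correlation `rho(t1, t2)` for a vector of
#' later times, fits `log(rho)` against `log(t2)`, and attaches a
#' delete-one-sample jackknife standard error to the exponent (the `t2`
#' points share samples, so the naive regression error would be
#' miscalibrated).
#'
#' @param ens A `bd_ensemble`.
#' @param t1 Earlier grid time.
#' @param t2 Vector of later grid times spanning at least one decade.
#' @return A `fit_result` whose estimate is the magnitude of the exponent.
#' @export
pearson_powerlaw_fit <- function(ens, t1, t2) {
  stopifnot(inherits(ens, "bd_ensemble"))
  if (max(t2) / min(t2) < 10)
    stop("t2 range must span at least one decade", call. = FALSE)
  n <- nrow(ens$counts)
  x <- ens$counts[, grid_index(ens, t1, "t1")]
  lx <- log(t2)
  xc <- lx - mean(lx)
  denom <- sum(xc^2)
  rho <- numeric(length(t2))
  loo <- matrix(0, n, length(t2))
  for (j in seq_along(t2)) {
    y <- ens$counts[, grid_index(ens, t2[j], "t2")]
    rho[j] <- stats::cor(x, y)
    loo[, j] <- loo_cor(x, y)
  }
  if (any(rho <= 0))
    stop("non-positive empirical correlation in the fit range", call. = FALSE)
  slope <- sum(xc * log(rho)) / denom
  loo_slopes <- as.vector(log(pmax(loo, .Machine$double.xmin)) %*% xc) / denom
  se <- jackknife_se(loo_slopes)
  res <- new_fit_result(abs(slope), se, range(t2), NA_real_)
  res$rho <- rho
  res$t2 <- t2
  res
}

#' Oscillation period from an ensemble variance series
#'
#' Detects the damped proliferation-wave oscillations of the refractory
#' model: the series is detrended by dividing out a fitted exponential,
#' strict local minima falling below 0.75 times a rolling median are kept,
#' and the period is the mean spacing of those minima (standard error from
#' the spacing dispersion). Fewer than two qualifying minima yields a
#' flagged no-oscillation result.
#'
#' @param times Time grid.
#' @param values Variance series (non-negative; zeros before the first
#'   division are ignored).
#' @return A `fit_result`; `detected = FALSE` flags no oscillation, and the
#'   diagnostic is the number of minima found.
#' @export
estimate_oscillation_period <- function(times, values) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values))
  pos <- which(values > 0)
  if (length(pos) < 10L)
    return(new_fit_result(NA_real_, NA_real_, range(times), 0, detected = FALSE))
  tt <- times[pos]
  vv <- values[pos]
  pred <- exp(stats::predict(stats::lm(log(vv) ~ tt)))
  detr <- vv / pred
  k <- max(5L, length(detr) %/% 10L)
  rollmed <- stats::runmed(detr, k = if (k %% 2 == 0) k + 1L else k,
                           endrule = "median")
  i <- 2:(length(detr) - 1L)
  is_min <- detr[i] < detr[i - 1L] & detr[i] < detr[i + 1L] &
            detr[i] < 0.75 * rollmed[i]
  mins <- tt[i[is_min]]
  if (length(mins) < 2L)
    return(new_fit_result(NA_real_, NA_real_, range(times),
                          length(mins), detected = FALSE))
  gaps <- diff(mins)
  per <- mean(gaps)
  se <- if (length(gaps) > 1L) stats::sd(gaps) / sqrt(length(gaps) - 1L) else NA_real_
  new_fit_result(per, se, range(times), length(mins))
}
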