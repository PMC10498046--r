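#' Pole spectrum of the refractory model's mean
#'
#' The Laplace transform of the mean population of the refractory model has
#' simple poles at `s_k = -gamma0 + W_k(2 T gamma0 exp(T gamma0)) / T`,
#' where `W_k` is the k-th branch of the Lambert W function. `s_0` is real
#' and has the strictly largest real part (it is the Malthusian growth
#' rate); the remaining poles come in complex-conjugate pairs
#' `s_{-k} = Conj(s_k)`. Every pole satisfies the characteristic equation
#' `(s + gamma0) exp(s T) = 2 gamma0`.
#'
#' @param params A [refractory_params()] object with `T > 0`.
#' @param K Branch cutoff, integer >= 0; branches `-K..K` are returned.
#' @return An object of class `pole_set`: list with `K`, `k` (indices
#'   `-K..K`) and `poles` (complex vector in the same order).
#' @examples
#' refractory_poles(refractory_params(1, 1), K = 2)
#' @export
refractory_poles <- function(params, K) {
  stopifnot(inherits(params, "refractory_params"))
  if (params$T <= 0)
    stop("poles require T > 0 (for T = 0 use effective_rate())", call. = FALSE)
  if (!is.numeric(K) || length(K) != 1L || K < 0 || K != round(K))
    stop("K must be a single integer >= 0", call. = FALSE)
  g0 <- params$gamma0
  T <- params$T
  x <- 2 * T * g0 * exp(T * g0)
  upper <- vapply(0:K, function(k) -g0 + lambert_w(x, k) / T, complex(1))
  upper[1] <- complex(real = Re(upper[1]))  # principal pole is exactly real
  poles <- c(rev(Conj(upper[-1])), upper)
  structure(list(K = as.integer(K), k = seq.int(-K, K), poles = poles,
                 params = params),
            class = "pole_set")
}

#' @export
print.pole_set <- function(x, ...) {
  cat(sprintf("Pole set (K = %d) of refractory model gamma0 = %g, T = %g\n",
              x$K, x$params$gamma0, x$params$T))
  cat(sprintf("  s_0 = %.6g (Malthusian rate)\n", Re(x$poles[x$K + 1L])))
  if (x$K >= 1)
    cat(sprintf("  s_1 = %.6g %+.6gi\n",
                Re(x$poles[x$K + 2L]), Im(x$poles[x$K + 2L])))
  invisible(x)
}

#' Residual of the characteristic equation at given poles
#'
#' Relative residual `|(s + gamma0) exp(s T) - 2 gamma0| / (2 gamma0)`,
#' used to verify pole accuracy.
#'
#' @param ps A `pole_set` as returned by [refractory_poles()].
#' @return Numeric vector of relative residuals, one per pole.
#' @export
characteristic_residual <- function(ps) {
  stopifnot(inherits(ps, "pole_set"))
  g0 <- ps$params$gamma0
  T <- ps$params$T
  abs((ps$poles + g0) * exp(ps$poles * T) - 2 * g0) / (2 * g0)
}

#' Effective Markovian (Malthusian) growth rate of the refractory model
#'
#' The real dominant pole `s_0`: at long times the mean population grows as
#' `exp(s_0 (t - T))`, so the non-Markovian model is asymptotically
#' indistinguishable from a Markovian model with this effective rate. For
#' `T = 0` it equals `gamma0` exactly.
#'
#' @param params A [refractory_params()] object.
#' @return A single real growth rate.
#' @examples
#' effective_rate(refractory_params(1, 1))  # ~0.3748
#' @export
effective_rate <- function(params) {
  stopifnot(inherits(params, "refractory_params"))
  if (params$T == 0) return(params$gamma0)
  g0 <- params$gamma0
  T <- params$T
  Re(lambert_w(2 * T * g0 * exp(T * g0), 0L)) / T - g0
}

#' Mean population of the refractory model (pole expansion)
#'
#' Evaluates the exact inverse-Laplace pole expansion of the mean,
#' truncated at branches `|k| <= K`:
#' `n0` for `t <= T`, and for `t > T`
#' `n0 * (1 + sum_k A_k exp(s_k (t - T)))` with
#' `A_k = gamma0 / (s_k (1 + T (gamma0 + s_k)))` and the `k = 0` term minus
#' one absorbed into the bracket. Conjugate branch pairs are combined
#' analytically into real terms (`2 Re`), so round-off from imaginary
#' residues cannot accumulate. A tail-convergence check compares the
#' truncation `K` against `ceiling(1.5 K)` and warns when they disagree by
#' more than `1e-4` relative.
#'
#' @param params A [refractory_params()] object with `T > 0` (use
#'   [mean_markov()] with `kappa = 0` for `T = 0`).
#' @param n0 Initial number of cells (integer >= 1), all at age 0.
#' @param t Time(s) >= 0; vectorized.
#' @param K Branch cutoff (default 50).
#' @param check_convergence Compare against the 1.5 K truncation and warn
#'   on disagreement (default TRUE).
#' @return Expected count(s), same length as `t`.
#' @examples
#' mean_refractory(refractory_params(1, 1), n0 = 50, t = c(0.5, 2, 5))
#' @export
mean_refractory <- function(params, n0, t, K = 50L, check_convergence = TRUE) {
  stopifnot(inherits(params, "refractory_params"))
  check_n0(n0)
  check_time(t)
  if (params$T <= 0)
    stop("pole expansion requires T > 0; for T = 0 the mean is n0*exp(gamma0*t)",
         call. = FALSE)
  val <- n0 * mean_refractory_per_ancestor(params, t, K)
  if (check_convergence) {
    K2 <- ceiling(1.5 * K)
    val2 <- n0 * mean_refractory_per_ancestor(params, t, K2)
    rel <- abs(val2 - val) / pmax(abs(val2), 1e-300)
    if (any(rel > 1e-4))
      warning(sprintf(
        "pole-expansion mean not converged at K = %d (max relative change %.2g when K -> %d); increase K",
        K, max(rel), K2), call. = FALSE)
  }
  val
}

# per-ancestor mean via truncated pole expansion; t vectorized
mean_refractory_per_ancestor <- function(params, t, K) {
  g0 <- params$gamma0
  T <- params$T
  ps <- refractory_poles(params, K)
  s <- ps$poles[(K + 1L):(2L * K + 1L)]  # k = 0..K
  A <- g0 / (s * (1 + T * (g0 + s)))
  out <- numeric(length(t))
  pre <- t <= T
  out[pre] <- 1
  if (any(!pre)) {
    dt <- t[!pre] - T
    # conjugate pairs combined analytically: k = 0 once, k >= 1 as 2*Re
    coef <- c(A[1], 2 * A[-1])
    E <- exp(outer(dt, s))                 # length(dt) x (K+1) complex matrix
    sums <- Re(E %*% coef)
    out[!pre] <- drop(sums)                # 1 + (-1 + sum_k A_k e^{s_k dt})
  }
  out
}

#' Oscillation period of the refractory model
#'
#' Damped oscillations of the moments (proliferation "waves" at multiples
#' of the refractory period before desynchronization) have approximate
#' period `2 * pi / Im(s_1)`, with `s_1` the first complex pole. When
#' `gamma0 >> 1/T` the period is close to `T` itself.
#'
#' @param params A [refractory_params()] object with `T > 0`.
#' @return The approximate period (a positive number).
#' @examples
#' oscillation_period(refractory_params(10, 1))  # ~1
#' @export
oscillation_period <- function(params) {
  stopifnot(inherits(params, "refractory_params"))
  if (params$T <= 0)
    stop("no oscillations for T = 0 (Markovian limit)", call. = FALSE)
  ps <- refractory_poles(params, 1L)
  s1 <- ps$poles[ps$K + 2L]
  2 * pi / Im(s1)
}

#' Renewal-equation moments of the refractory model
#'
#' Independent numerical route to the mean and variance of the refractory
#' model, used to cross-validate the pole expansion (and standing in for
#' the analytically unwieldy series form of the variance). Each cell's
#' waiting time to division is `T` plus an exponential of rate `gamma0`,
#' and a division replaces the cell by two cells of age 0; for a single
#' ancestor the mean `m(t)` and the auxiliary second-moment function obey
#' Volterra renewal (convolution) equations
#' \deqn{m(t) = S(t) + 2 \int_0^t m(t-u) f(u) du}
#' \deqn{q(t) = \int_0^t [2 m(t-u)^2 + 2 q(t-u)] f(u) du}
#' with lifetime density `f(u) = gamma0 exp(-gamma0 (u - T))` for `u >= T`
#' (0 before), survival `S(t) = 1` for `t < T`, `exp(-gamma0 (t - T))`
#' after, and per-ancestor variance `v = q + m - m^2`. The convolutions are
#' discretized by the trapezoidal rule on the supplied uniform grid
#' (second-order accurate). Ancestors are independent, so the population
#' mean and variance are `n0 * m` and `n0 * v`.
#'
#' @param params A [refractory_params()] object.
#' @param n0 Initial number of cells (integer >= 1), all at age 0.
#' @param times Uniform time grid starting at 0 (step `h` with
#'   `gamma0 * h < 0.1`); should contain `T` as a grid point for full
#'   accuracy.
#' @return A list with `times`, `mean` and `var` (numeric vectors).
#' @examples
#' rm_ <- renewal_moments(refractory_params(1, 1), n0 = 50,
#'                        times = seq(0, 10, by = 0.01))
#' @export
renewal_moments <- function(params, n0, times) {
  stopifnot(inherits(params, "refractory_params"))
  check_n0(n0)
  if (!is.numeric(times) || length(times) < 3L)
    stop("times must be a numeric grid with at least 3 points", call. = FALSE)
  if (abs(times[1]) > 1e-12) stop("grid must start at 0", call. = FALSE)
  h <- times[2] - times[1]
  if (h <= 0 || max(abs(diff(times) - h)) > 1e-9 * h)
    stop("grid must be uniform", call. = FALSE)
  g0 <- params$gamma0
  T <- params$T
  if (g0 * h >= 0.1)
    stop("step too coarse: need gamma0 * h < 0.1", call. = FALSE)

  N <- length(times)
  u <- times
  post <- u >= T - 1e-12 * max(T, 1)
  jT <- which(post)[1] - 1L              # 0-based index of first node >= T
  f <- ifelse(post, g0 * exp(-g0 * pmax(u - T, 0)), 0)
  S <- ifelse(post, exp(-g0 * pmax(u - T, 0)), 1)

  m <- numeric(N)
  q <- numeric(N)
  m[1] <- 1
  # trapezoid weights live on the integration range [u_jT, t_i]; when
  # T = 0 the j = 0 node multiplies the unknown m_i (implicit, solved for)
  implicit <- jT == 0L
  a <- if (implicit) 0.5 * h * f[1] else 0
  for (i in seq_len(N - 1L)) {           # i is 0-based target index
    ii <- i + 1L                         # R index of t_i
    if (i <= jT) { m[ii] <- S[ii]; next }
    j <- jT:i
    w <- rep(1, length(j)); w[1] <- 0.5; w[length(j)] <- 0.5
    fj <- f[j + 1L]
    mj <- m[i - j + 1L]                  # m(t_i - u_j); j = i term is m(0)
    if (implicit) {
      rest <- sum(w[-1] * fj[-1] * mj[-1])
      m[ii] <- (S[ii] + 2 * h * rest) / (1 - 2 * a)
    } else {
      m[ii] <- S[ii] + 2 * h * sum(w * fj * mj)
    }
  }
  for (i in seq_len(N - 1L)) {
    ii <- i + 1L
    if (i <= jT) { q[ii] <- 0; next }
    j <- jT:i
    w <- rep(1, length(j)); w[1] <- 0.5; w[length(j)] <- 0.5
    fj <- f[j + 1L]
    mj <- m[i - j + 1L]
    qj <- q[i - j + 1L]
    if (implicit) {
      g_rest <- sum(w[-1] * fj[-1] * (2 * mj[-1]^2 + 2 * qj[-1]))
      q[ii] <- (h * g_rest + 2 * a * m[ii]^2) / (1 - 2 * a)
    } else {
      q[ii] <- h * sum(w * fj * (2 * mj^2 + 2 * qj))
    }
  }
  v <- q + m - m^2
  list(times = times, mean = n0 * m, var = n0 * pmax(v, 0))
}
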