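# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they validate.

# Master-equation oracle: integrates dP_n/dt = sigma (n-1) P_{n-1}
# - (sigma+kappa) n P_n + kappa (n+1) P_{n+1}, truncated at n <= n_max,
# with a plain RK4 stepper. Returns mean and variance at time t.
master_equation_moments <- function(sigma, kappa, n0, t, n_max = 200L,
                                    dt = 0.01) {
  P <- numeric(n_max + 1L)        # index i holds P_{i-1}
  P[n0 + 1L] <- 1
  n <- 0:n_max
  deriv <- function(P) {
    up <- c(0, sigma * n[-length(n)] * P[-length(P)])      # from n-1
    down <- c(kappa * n[-1] * P[-1], 0)                    # from n+1
    up + down - (sigma + kappa) * n * P
  }
  steps <- ceiling(t / dt)
  h <- t / steps
  for (i in seq_len(steps)) {
    k1 <- deriv(P)
    k2 <- deriv(P + h / 2 * k1)
    k3 <- deriv(P + h / 2 * k2)
    k4 <- deriv(P + h * k3)
    P <- P + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  m <- sum(n * P)
  list(mean = m, var = sum(n^2 * P) - m^2, mass = sum(P))
}

# Real dominant root of (s + gamma0) * exp(s * T) = 2 * gamma0 by uniroot
# (bisection-style), independent of the Lambert-W route.
s0_root_oracle <- function(gamma0, T) {
  stats::uniroot(function(s) (s + gamma0) * exp(s * T) - 2 * gamma0,
                 lower = 0, upper = gamma0, tol = 1e-12)$root
}

# small helper: standard error of an ensemble mean at one grid index
mean_se <- function(mom, i) sqrt(mom$var[i] / mom$n_samples)
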