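#' Lambert W function (arbitrary branch)
#'
#' Solves `w * exp(w) = z` on branch `k` by Halley iteration, following the
#' standard branch convention (`k = 0` is the principal branch, real for
#' real `z >= -1/e`; branches `k` and `-k` are complex conjugates for real
#' `z > 0`). Only what the pole spectrum of the refractory model needs is
#' supported: real `z > 0` (all branches) plus real `z in (-1/e, 0]` on the
#' principal branch.
#'
#' @param z Argument, a single real number (> 0 for `k != 0`).
#' @param k Branch index, a single integer.
#' @param tol Convergence tolerance on the Newton step.
#' @param maxit Maximum Halley iterations.
#' @return A complex scalar `w` with `w * exp(w) = z` on branch `k`.
#' @examples
#' lambert_w(1)                 # Omega constant, 0.567143...
#' lambert_w(5.43656, k = 1)    # first complex branch
#' @export
lambert_w <- function(z, k = 0L, tol = 1e-14, maxit = 100L) {
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z))
    stop("z must be a single finite real number", call. = FALSE)
  if (length(k) != 1L || k != round(k))
    stop("k must be a single integer", call. = FALSE)
  k <- as.integer(k)
  if (k != 0L && z <= 0)
    stop("non-principal branches implemented for z > 0 only", call. = FALSE)
  if (k == 0L && z < -exp(-1))
    stop("z < -1/e: principal branch is complex there (not needed)", call. = FALSE)

  # initial guess: series near 0 on the principal branch, asymptotic
  # log(z) + 2*pi*i*k - log(log(z) + 2*pi*i*k) otherwise
  if (k == 0L) {
    w <- if (abs(z) < 0.5) {
      as.complex(z * (1 - z + 1.5 * z^2))
    } else {
      as.complex(log1p(z))
    }
  } else {
    L <- complex(real = log(z), imaginary = 2 * pi * k)
    w <- L - log(L)
  }

  for (it in seq_len(maxit)) {
    ew <- exp(w)
    f <- w * ew - z
    wp1 <- w + 1
    # Halley step
    dw <- f / (ew * wp1 - (w + 2) * f / (2 * wp1))
    w <- w - dw
    if (abs(dw) <= tol * (1 + abs(w))) break
  }
  if (abs(w * exp(w) - z) > 1e-10 * max(1, abs(z)))
    stop(sprintf("lambert_w did not converge for z = %g, k = %d", z, k),
         call. = FALSE)
  w
}
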