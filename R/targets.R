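#' Random stable linear target system
#'
#' Draws a single-input single-output linear state-space system
#' `x(k) = A_T x(k-1) + B_T u(k)`, `z(k) = C_T x(k) + noise` with all
#' entries uniform in `[-1, 1]` and `A_T` rescaled so its spectral radius
#' lies below `rho_max` (drawn uniformly in `[rho_max/2, rho_max)` so
#' realisations vary while respecting the bound).
#'
#' @param N state dimension.
#' @param rho_max upper bound on the spectral radius of `A_T`, in (0, 1).
#' @param seed optional integer seed.
#' @return a `linear_target` list with `A`, `B`, `C`.
#' @export
random_stable_linear <- function(N, rho_max = 0.2, seed = NULL) {
  stopifnot(rho_max > 0, rho_max < 1)
  with_seed(seed, {
    A <- random_weight_matrix(N, N)
    rho <- stats::runif(1, rho_max / 2, rho_max * 0.999)
    A <- set_spectral_radius(A, rho)
    structure(list(A = A,
                   B = random_weight_matrix(N, 1L),
                   C = random_weight_matrix(1L, N)),
              class = "linear_target")
  })
}

#' @export
print.linear_target <- function(x, ...) {
  cat(sprintf("Linear target system: %d states, rho(A) = %.4f\n",
              nrow(x$A), spectral_radius(x$A)))
  invisible(x)
}

#' Simulate a linear target system
#'
#' Iterates the state recursion from the zero state and returns the clean
#' output together with a noisy copy at the requested signal-to-noise
#' ratio.
#'
#' @param sys a `linear_target`.
#' @param U input sequence (vector).
#' @param snr linear SNR for the measurement noise; `Inf` for no noise.
#' @param noise_seed optional integer seed for the noise draw.
#' @return list with `z_clean`, `z_noisy` and the state matrix `X`.
#' @export
simulate_linear_target <- function(sys, U, snr = Inf, noise_seed = NULL) {
  stopifnot(inherits(sys, "linear_target"))
  U <- as.numeric(U)
  N <- nrow(sys$A)
  T_len <- length(U)
  X <- matrix(0, T_len, N)
  x <- numeric(N)
  for (k in seq_len(T_len)) {
    x <- sys$A %*% x + sys$B * U[k]
    X[k, ] <- x
  }
  z <- as.numeric(X %*% t(sys$C))
  zn <- if (is.finite(snr)) add_noise_snr(z, snr, seed = noise_seed) else z
  list(z_clean = z, z_noisy = zn, X = X)
}

#' Quadratic sum output map of the linear-nonlinear benchmark
#'
#' Static nonlinear output
#' `y = sum_{i=1}^{39} [0.5 (x_{i+1} - x_i^2)^2 + (0.5 - x_i)^2]`
#' applied row-wise to a state sequence of dimension at least 40.
#'
#' @param X `T` x `dim` state matrix, `dim >= 40`.
#' @return length-`T` nonnegative output vector (before noise).
#' @export
lnl_output <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 40L) stop("the linear-nonlinear output map requires at least 40 states")
  i <- 1:39
  y <- numeric(nrow(X))
  for (k in seq_len(nrow(X))) {
    x <- X[k, ]
    y[k] <- sum(0.5 * (x[i + 1L] - x[i]^2)^2 + (0.5 - x[i])^2)
  }
  y
}

#' NARMA10 recursion
#'
#' Tenth-order nonlinear autoregressive moving-average benchmark:
#' `y(k+1) = 0.3 y(k) + 0.05 y(k) sum_{i=0}^{9} y(k-i) + 1.5 u(k) u(k-9) + 0.1`
#' with zero initial history for both `u` and `y`. The recursion is iterated
#' exactly as written; if `|y|` exceeds `1e3` the trajectory is flagged as
#' divergent via the `"diverged_at"` attribute (no clipping is applied
#' unless `saturate = TRUE`, which wraps the update in `tanh` -- an
#' exploratory option only).
#'
#' @param U input vector (conventionally i.i.d. uniform; the recursion is
#'   known to stay bounded for inputs in `[0, 0.5]` and to diverge almost
#'   surely for inputs in `[0, 1]`).
#' @param saturate logical; apply `tanh` to each update (default `FALSE`).
#' @return length-`T` output vector `y(1..T)` with attribute `diverged_at`
#'   (`NA_integer_` when bounded throughout).
#' @export
narma10 <- function(U, saturate = FALSE) {
  u <- as.numeric(U)
  T_len <- length(u)
  stopifnot(T_len > 10L)
  y <- numeric(T_len)
  diverged_at <- NA_integer_
  for (k in seq_len(T_len - 1L)) {
    ysum <- if (k >= 10L) sum(y[(k - 9L):k]) else sum(y[1:k])
    u9 <- if (k >= 10L) u[k - 9L] else 0
    ynew <- 0.3 * y[k] + 0.05 * y[k] * ysum + 1.5 * u[k] * u9 + 0.1
    if (saturate) ynew <- tanh(ynew)
    y[k + 1L] <- ynew
    if (!is.finite(ynew) || abs(ynew) > 1e3) {
      diverged_at <- k + 1L
      y[(k + 1L):T_len] <- ynew
      break
    }
  }
  attr(y, "diverged_at") <- diverged_at
  y
}

#' Add Gaussian measurement noise at a given signal-to-noise ratio
#'
#' SNR is a linear power ratio: the injected zero-mean Gaussian noise has
#' variance `var(z) / snr`, so e.g. `snr = 25` buries the signal under 4%
#' relative noise power.
#'
#' @param z signal (non-constant numeric vector).
#' @param snr positive linear SNR; `Inf` returns `z` unchanged.
#' @param seed optional integer seed.
#' @return the noisy signal.
#' @export
add_noise_snr <- function(z, snr, seed = NULL) {
  stopifnot(is.numeric(z), snr > 0)
  if (is.infinite(snr)) return(z)
  v <- stats::var(z)
  if (v <= 0) stop("signal is constant; SNR-scaled noise is undefined")
  with_seed(seed, z + stats::rnorm(length(z), 0, sqrt(v / snr)))
}

#' Normalised mean squared error
#'
#' `sum((pred - ref)^2) / sum((ref - mean(ref))^2)`: scale-invariant
#' prediction error; 1 is the score of the constant mean predictor.
#'
#' @param pred predicted sequence.
#' @param ref reference sequence (non-constant).
#' @return a nonnegative scalar.
#' @export
nmse <- function(pred, ref) {
  stopifnot(length(pred) == length(ref))
  denom <- sum((ref - mean(ref))^2)
  if (denom <= 0) stop("reference signal is constant; NMSE is undefined")
  sum((pred - ref)^2) / denom
}
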