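## Run `code` with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Spectral radius of a square matrix
#'
#' Largest eigenvalue modulus, the quantity that governs reservoir stability
#' (echo state property) and memory depth.
#'
#' @param W a square numeric matrix.
#' @return a nonnegative scalar.
#' @export
spectral_radius <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  max(Mod(eigen(W, only.values = TRUE)$values))
}

#' Random dense weight matrix
#'
#' Entries drawn i.i.d. uniformly from a closed interval; the standard
#' initialisation for ESN input, feedback and (before rescaling) reservoir
#' weights.
#'
#' @param rows,cols matrix dimensions (positive integers).
#' @param range length-2 numeric interval, default `c(-1, 1)`.
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @return a `rows` x `cols` numeric matrix.
#' @export
random_weight_matrix <- function(rows, cols, range = c(-1, 1), seed = NULL) {
  stopifnot(length(rows) == 1L, length(cols) == 1L, rows >= 1, cols >= 1,
            length(range) == 2L, range[1] <= range[2])
  with_seed(seed, matrix(stats::runif(rows * cols, range[1], range[2]), rows, cols))
}

#' Rescale a matrix to a target spectral radius
#'
#' @param W square matrix with nonzero spectral radius.
#' @param rho_target desired spectral radius (> 0).
#' @return `W * rho_target / rho(W)`.
#' @export
set_spectral_radius <- function(W, rho_target) {
  stopifnot(rho_target > 0)
  rho <- spectral_radius(W)
  if (rho < 1e-12) {
    stop("matrix has (numerically) zero spectral radius and cannot be rescaled")
  }
  W * (rho_target / rho)
}

#' Construct a random reservoir matrix
#'
#' Draws an `N` x `N` dense reservoir. With `eigenspectrum = "unconstrained"`
#' the entries are uniform in `weight_range` and the matrix is rescaled into
#' the requested spectral-radius interval. With `eigenspectrum = "uniform"`
#' the eigenvalues themselves are drawn uniformly on the complex unit disk
#' (closed under conjugation so the matrix is real), assembled as a real
#' block-diagonal matrix, conjugated by a random orthogonal matrix and then
#' rescaled; this produces the "narrow", uniformly distributed eigenspectrum
#' used in the linear-system benchmark.
#'
#' @param N reservoir size.
#' @param spectral_radius_range interval inside (0, 1); the target radius is
#'   drawn uniformly from it.
#' @param eigenspectrum `"unconstrained"` or `"uniform"`.
#' @param weight_range entry range for the unconstrained draw.
#' @param seed optional integer seed.
#' @return an `N` x `N` matrix with spectral radius in the requested range.
#' @export
make_reservoir <- function(N, spectral_radius_range = c(0.8, 0.9),
                           eigenspectrum = c("unconstrained", "uniform"),
                           weight_range = c(-1, 1), seed = NULL) {
  eigenspectrum <- match.arg(eigenspectrum)
  stopifnot(N >= 1, length(spectral_radius_range) == 2L,
            spectral_radius_range[1] > 0, spectral_radius_range[2] < 1,
            spectral_radius_range[1] <= spectral_radius_range[2])
  with_seed(seed, {
    rho_target <- stats::runif(1, spectral_radius_range[1], spectral_radius_range[2])
    if (eigenspectrum == "unconstrained" || N == 1L) {
      W <- matrix(stats::runif(N * N, weight_range[1], weight_range[2]), N, N)
      if (N == 1L && abs(W) < 1e-12) W[] <- 0.5  # degenerate scalar draw
      return(set_spectral_radius(W, rho_target))
    }
    ## uniformly distributed eigenvalues on the unit disk, conjugate-closed
    n_pairs <- N %/% 2L
    n_real <- N - 2L * n_pairs
    blocks <- vector("list", n_pairs + n_real)
    for (p in seq_len(n_pairs)) {
      repeat {  # uniform on the upper half disk by rejection
        re <- stats::runif(1, -1, 1); im <- stats::runif(1, 0, 1)
        if (re * re + im * im <= 1 && im > 1e-12) break
      }
      blocks[[p]] <- matrix(c(re, -im, im, re), 2, 2)
    }
    if (n_real == 1L) blocks[[n_pairs + 1L]] <- matrix(stats::runif(1, -1, 1), 1, 1)
    D <- matrix(0, N, N)
    at <- 1L
    for (b in blocks) {
      k <- nrow(b)
      D[at:(at + k - 1L), at:(at + k - 1L)] <- b
      at <- at + k
    }
    qr_g <- qr(matrix(stats::rnorm(N * N), N, N))
    Q <- qr.Q(qr_g)
    Q <- Q %*% diag(sign(diag(qr.R(qr_g))), N)  # Haar-distributed orthogonal
    set_spectral_radius(Q %*% D %*% t(Q), rho_target)
  })
}

#' Delay-embed a scalar input sequence
#'
#' Builds the lagged input vector `[u(k), u(k-1), ..., u(k-l)]` at every
#' step, giving the reservoir an explicit short history of the stimulus
#' (time-delay embedding). Pre-history is padded with zeros, consistent with
#' the zero initial state convention.
#'
#' @param u numeric vector.
#' @param l maximum lag (>= 0); the embedded dimension is `l + 1`.
#' @return a `length(u)` x `(l + 1)` matrix whose first column is `u`.
#' @export
delay_embed <- function(u, l) {
  stopifnot(is.numeric(u), length(l) == 1L, l >= 0)
  u <- as.numeric(u)
  T_len <- length(u)
  out <- matrix(0, T_len, l + 1L)
  for (j in 0:l) {
    if (j < T_len) out[(j + 1L):T_len, j + 1L] <- u[1:(T_len - j)]
  }
  out
}

#' Frequency response of a discrete-time linear state-space model
#'
#' Evaluates `C (e^{i omega} I - A)^{-1} B` at each frequency. For a trained
#' linear-reservoir, linear-readout state-feedback ESN use
#' `A = closed_loop_matrix(model)`, `B = W_in`, `C = W_out`.
#'
#' @param A state matrix (stable, spectral radius < 1).
#' @param B input matrix (N x 1).
#' @param C output matrix (1 x N).
#' @param omegas radian frequencies in `[0, pi]`.
#' @return a complex vector, one response per frequency.
#' @export
linear_frf <- function(A, B, C, omegas) {
  A <- as.matrix(A)
  B <- matrix(B, nrow = nrow(A))
  C <- matrix(C, ncol = nrow(A))
  N <- nrow(A)
  vapply(omegas, function(w) {
    M <- diag(exp(1i * w), N) - A
    as.complex(C %*% solve(M, B))
  }, complex(1))
}
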