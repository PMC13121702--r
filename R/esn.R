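#' Echo state network model
#'
#' Container for a discrete-time ESN. Two feedback architectures are
#' supported:
#' \describe{
#'   \item{state feedback}{`x(k) = F((W + W_in W_fb) x(k-1) + W_in u(k))`
#'     with `W_fb` of shape `m x N`, so the feedback reshapes the effective
#'     state-transition matrix `W + W_in W_fb` without touching `W`.}
#'   \item{output feedback}{`x(k) = F(W x(k-1) + W_in u(k) - W_fb y(k-1))`
#'     with `W_fb` of shape `N x 1` and scalar output `y`.}
#' }
#' The readout is either a linear row vector (`y = W_out x`) or a sparse
#' polynomial [sparse_readout].
#'
#' @param W reservoir matrix (`N` x `N`), spectral radius < 1.
#' @param W_in input matrix (`N` x `m`).
#' @param W_fb feedback matrix; `m x N` in state-feedback mode, `N x 1` in
#'   output-feedback mode; may be `NULL` when `feedback_mode = "none"`.
#' @param activation `"identity"` or `"tanh"`.
#' @param feedback_mode `"state"`, `"output"` or `"none"`.
#' @param readout `NULL`, a numeric vector of length `N` (linear readout) or
#'   a [sparse_readout] object.
#' @return an object of class `esn_model`.
#' @export
esn_model <- function(W, W_in, W_fb = NULL,
                      activation = c("identity", "tanh"),
                      feedback_mode = c("state", "output", "none"),
                      readout = NULL) {
  activation <- match.arg(activation)
  feedback_mode <- match.arg(feedback_mode)
  W <- as.matrix(W)
  N <- nrow(W)
  stopifnot(ncol(W) == N)
  W_in <- as.matrix(W_in)
  stopifnot(nrow(W_in) == N)
  m <- ncol(W_in)
  rho <- spectral_radius(W)
  if (rho >= 1) {
    stop(sprintf("reservoir spectral radius %.4f >= 1 violates the echo state property", rho))
  }
  if (feedback_mode == "state") {
    W_fb <- as.matrix(W_fb)
    stopifnot(nrow(W_fb) == m, ncol(W_fb) == N)
  } else if (feedback_mode == "output") {
    W_fb <- matrix(as.numeric(W_fb), N, 1)
  } else {
    W_fb <- NULL
  }
  model <- structure(
    list(N = N, m = m, W = W, W_in = W_in, W_fb = W_fb,
         activation = activation, feedback_mode = feedback_mode,
         readout = readout),
    class = "esn_model")
  validate_readout(model)
  model
}

validate_readout <- function(model) {
  r <- model$readout
  if (is.null(r)) return(invisible(TRUE))
  if (is.numeric(r)) {
    stopifnot(length(r) == model$N)
  } else if (!inherits(r, "sparse_readout")) {
    stop("readout must be NULL, a numeric vector of length N, or a sparse_readout")
  }
  invisible(TRUE)
}

#' @export
print.esn_model <- function(x, ...) {
  cat(sprintf("Echo state network: N = %d neurons, m = %d input(s)\n", x$N, x$m))
  cat(sprintf("  activation: %s | feedback: %s | rho(W) = %.4f\n",
              x$activation, x$feedback_mode, spectral_radius(x$W)))
  if (is.null(x$readout)) {
    cat("  readout: none (untrained)\n")
  } else if (is.numeric(x$readout)) {
    cat("  readout: linear, dense over all states\n")
  } else {
    cat(sprintf("  readout: sparse polynomial, %d term(s)\n", nrow(x$readout$terms)))
  }
  invisible(x)
}

#' Convenience random ESN
#'
#' Draws all weight matrices using the standard conventions: dense
#' asymmetric uniform `[-1, 1]` input and feedback weights, and a reservoir
#' from [make_reservoir].
#'
#' @inheritParams esn_model
#' @param N reservoir size; `m` input dimension.
#' @param spectral_radius_range,eigenspectrum passed to [make_reservoir].
#' @param weight_range entry range for `W_in` and `W_fb`.
#' @param seed optional integer seed.
#' @details In state-feedback mode the effective transition matrix is
#'   `W + W_in W_fb`, so the echo state property must hold for the closed
#'   loop, not just for `W`; with `N`-dimensional uniform draws the rank-one
#'   feedback term alone would typically push the closed-loop spectral
#'   radius well above 1. After drawing, `W_fb` is therefore rescaled (by a
#'   bisection on the closed-loop spectral radius) so that
#'   `rho(W + W_in W_fb)` also falls inside `spectral_radius_range`,
#'   keeping the untrained network stable while preserving the random
#'   direction of the feedback.
#' @return an `esn_model`.
#' @export
random_esn <- function(N, m = 1L, activation = c("identity", "tanh"),
                       feedback_mode = c("state", "output", "none"),
                       spectral_radius_range = c(0.8, 0.9),
                       eigenspectrum = c("unconstrained", "uniform"),
                       weight_range = c(-1, 1), seed = NULL) {
  activation <- match.arg(activation)
  feedback_mode <- match.arg(feedback_mode)
  eigenspectrum <- match.arg(eigenspectrum)
  with_seed(seed, {
    W <- make_reservoir(N, spectral_radius_range, eigenspectrum, weight_range)
    W_in <- random_weight_matrix(N, m, weight_range)
    W_fb <- switch(feedback_mode,
                   state = random_weight_matrix(m, N, weight_range),
                   output = random_weight_matrix(N, 1L, weight_range),
                   none = NULL)
    if (feedback_mode == "state") {
      rho_cl <- stats::runif(1, spectral_radius_range[1], spectral_radius_range[2])
      W_fb <- stabilise_feedback(W, W_in, W_fb, rho_cl)
    }
    esn_model(W, W_in, W_fb, activation, feedback_mode)
  })
}

## Rescale W_fb so that rho(W + W_in * (gamma W_fb)) == rho_target, by
## bisection on gamma in [0, 1]; gamma = 1 is kept when already stable.
stabilise_feedback <- function(W, W_in, W_fb, rho_target) {
  rho_at <- function(g) spectral_radius(W + W_in %*% (g * W_fb))
  if (rho_at(1) <= rho_target) return(W_fb)
  lo <- 0; hi <- 1
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (rho_at(mid) > rho_target) hi <- mid else lo <- mid
  }
  lo * W_fb
}

act_fun <- function(activation) {
  if (activation == "tanh") tanh else identity
}

#' Effective closed-loop transition matrix
#'
#' For a state-feedback ESN the feedback folds into the state transition as
#' `W + W_in W_fb`; this matrix governs the (linearised) closed-loop
#' dynamics.
#'
#' @param model a state-feedback `esn_model`.
#' @return an `N` x `N` matrix.
#' @export
closed_loop_matrix <- function(model) {
  stopifnot(inherits(model, "esn_model"))
  if (model$feedback_mode != "state") {
    stop("closed_loop_matrix is defined for state-feedback models only")
  }
  model$W + model$W_in %*% model$W_fb
}

#' Single reservoir update
#'
#' Advances the reservoir one step. In state-feedback mode
#' `F((W + W_in W_fb) x + W_in u)`; in output-feedback mode
#' `F(W x + W_in u - W_fb y)` where `y` is the fed-back scalar output
#' (teacher signal or the model's own previous prediction).
#'
#' @param model an `esn_model`.
#' @param x current state (length `N`).
#' @param u current input (length `m`).
#' @param y fed-back output, required in output-feedback mode.
#' @return the next state vector.
#' @export
esn_step <- function(model, x, u, y = NULL) {
  stopifnot(length(x) == model$N, length(u) == model$m)
  f <- act_fun(model$activation)
  s <- switch(model$feedback_mode,
    state = closed_loop_matrix(model) %*% x + model$W_in %*% u,
    output = {
      if (is.null(y)) stop("output-feedback mode requires the fed-back output y")
      model$W %*% x + model$W_in %*% u - model$W_fb * y
    },
    none = model$W %*% x + model$W_in %*% u)
  as.numeric(f(s))
}

#' Simulate an ESN over an input sequence
#'
#' Iterates the reservoir from an initial state (zero by default, the
#' standard reservoir-computing convention) and applies the readout to each
#' state. In output-feedback mode the fed-back output is the teacher signal
#' when `teacher` is supplied (teacher forcing) and the model's own previous
#' prediction otherwise (free run).
#'
#' @param model an `esn_model`.
#' @param U input sequence: length-`T` vector (when `m = 1`) or `T` x `m`
#'   matrix.
#' @param x0 initial state, default zero.
#' @param teacher optional length-`T` target sequence for teacher forcing
#'   (output-feedback mode).
#' @param y0 output fed back at the first step in output-feedback mode
#'   (default 0, matching the zero initial state).
#' @return a `trajectory` list with elements `U` (T x m), `X` (T x N) and
#'   `Y` (length T; `NA` when the model has no readout).
#' @export
esn_simulate <- function(model, U, x0 = NULL, teacher = NULL, y0 = 0) {
  stopifnot(inherits(model, "esn_model"))
  U <- input_matrix(U, model$m)
  T_len <- nrow(U)
  stopifnot(T_len >= 1)
  f <- act_fun(model$activation)
  x <- if (is.null(x0)) numeric(model$N) else as.numeric(x0)
  stopifnot(length(x) == model$N)
  X <- matrix(0, T_len, model$N)
  if (model$feedback_mode == "state") {
    A_cl <- closed_loop_matrix(model)
    for (k in seq_len(T_len)) {
      x <- f(A_cl %*% x + model$W_in %*% U[k, ])
      X[k, ] <- x
    }
    Y <- apply_readout(model, X)
  } else if (model$feedback_mode == "none") {
    for (k in seq_len(T_len)) {
      x <- f(model$W %*% x + model$W_in %*% U[k, ])
      X[k, ] <- x
    }
    Y <- apply_readout(model, X)
  } else {
    free_run <- is.null(teacher)
    if (free_run && !is.numeric(model$readout)) {
      stop("free-running output feedback requires a trained linear readout")
    }
    w_out <- if (is.numeric(model$readout)) model$readout else NULL
    Y <- rep(NA_real_, T_len)
    y_fb <- y0
    for (k in seq_len(T_len)) {
      x <- f(model$W %*% x + model$W_in %*% U[k, ] - model$W_fb * y_fb)
      X[k, ] <- x
      if (!is.null(w_out)) Y[k] <- sum(w_out * x)
      y_fb <- if (free_run) Y[k] else teacher[k]
      if (free_run && !is.finite(y_fb)) {
        ## divergence: keep going so the caller sees the non-finite tail
        y_fb <- Y[k] <- Inf
        if (k < T_len) {
          Y[(k + 1):T_len] <- Inf
          X[(k + 1):T_len, ] <- Inf
        }
        break
      }
    }
  }
  structure(list(U = U, X = X, Y = Y), class = "trajectory")
}

input_matrix <- function(U, m) {
  if (is.null(dim(U))) {
    stopifnot(m == 1L)
    U <- matrix(as.numeric(U), ncol = 1L)
  }
  U <- as.matrix(U)
  stopifnot(ncol(U) == m)
  U
}

#' Apply a model's readout to a state sequence
#'
#' @param model an `esn_model`.
#' @param X `T` x `N` state matrix.
#' @return length-`T` output vector (`NA` if the model has no readout).
#' @export
apply_readout <- function(model, X) {
  r <- model$readout
  if (is.null(r)) return(rep(NA_real_, nrow(X)))
  if (is.numeric(r)) return(as.numeric(X %*% r))
  predict(r, X)
}
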