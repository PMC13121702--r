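#' Initialise a recursive-least-squares state
#'
#' @param N regressor dimension.
#' @param lambda regulariser: the initial inverse-correlation matrix is
#'   `P = I / lambda`.
#' @return list of class `rls_state` with `P` and `w` (readout row).
#' @export
rls_init <- function(N, lambda = 1) {
  stopifnot(N >= 1, lambda > 0)
  structure(list(P = diag(N) / lambda, w = numeric(N)), class = "rls_state")
}

#' One recursive-least-squares update
#'
#' Standard RLS with forgetting factor 1:
#' `k = P phi / (1 + phi' P phi)`, `w <- w + e k` with prior error
#' `e = target - w' phi`, and `P <- P - k (phi' P)` (symmetrised).
#'
#' @param state an `rls_state`.
#' @param phi regressor vector.
#' @param target scalar target.
#' @return the updated `rls_state`.
#' @export
rls_step <- function(state, phi, target) {
  phi <- as.numeric(phi)
  Pphi <- as.numeric(state$P %*% phi)
  denom <- 1 + sum(phi * Pphi)
  k <- Pphi / denom
  e <- target - sum(state$w * phi)
  state$w <- state$w + e * k
  P <- state$P - outer(k, Pphi)
  state$P <- (P + t(P)) / 2
  if (!all(is.finite(state$w))) stop("RLS divergence: non-finite readout weights")
  state
}

#' FORCE training of an output-feedback ESN
#'
#' Simulates the reservoir with teacher-forced output feedback (the true
#' target is fed back, not the prediction) while updating the linear
#' readout by recursive least squares at every step. The trained model
#' carries the final readout; evaluation should run free (the model's own
#' prediction fed back), e.g. via [force_evaluate].
#'
#' @param model an output-feedback `esn_model`.
#' @param U training input sequence.
#' @param Z training target sequence (teacher signal).
#' @param lambda RLS regulariser (`P0 = I / lambda`).
#' @return the trained model with attributes `final_state`, `final_target`
#'   (for continuing into a free run) and `train_error` (per-step prior
#'   errors).
#' @export
force_train <- function(model, U, Z, lambda = 1) {
  stopifnot(inherits(model, "esn_model"))
  if (model$feedback_mode != "output") {
    stop("FORCE training is defined for output-feedback models")
  }
  U <- input_matrix(U, model$m)
  Z <- as.numeric(Z)
  T_len <- nrow(U)
  stopifnot(length(Z) == T_len)
  f <- act_fun(model$activation)
  rls <- rls_init(model$N, lambda)
  x <- numeric(model$N)
  y_fb <- 0
  err <- numeric(T_len)
  for (k in seq_len(T_len)) {
    x <- as.numeric(f(model$W %*% x + model$W_in %*% U[k, ] - model$W_fb * y_fb))
    err[k] <- Z[k] - sum(rls$w * x)
    rls <- rls_step(rls, x, Z[k])
    y_fb <- Z[k]  # teacher forcing
  }
  model$readout <- rls$w
  attr(model, "final_state") <- x
  attr(model, "final_target") <- Z[T_len]
  attr(model, "train_error") <- err
  model
}

#' Free-run evaluation of a FORCE-trained model
#'
#' Continues from the training-final reservoir state with the model's own
#' predictions fed back, and scores the result. Divergence (non-finite
#' predictions) is reported, with the NMSE recorded as computed.
#'
#' @param model a FORCE-trained output-feedback `esn_model`.
#' @param U_val validation inputs.
#' @param Z_val_ref validation reference signal.
#' @return list with `nmse`, `Y_val` and logical `diverged`.
#' @export
force_evaluate <- function(model, U_val, Z_val_ref) {
  x0 <- attr(model, "final_state")
  y0 <- attr(model, "final_target")
  if (is.null(x0)) stop("model does not carry a training-final state; train with force_train first")
  traj <- esn_simulate(model, U_val, x0 = x0, y0 = y0)
  diverged <- !all(is.finite(traj$Y))
  val_nmse <- if (diverged) Inf else nmse(traj$Y, Z_val_ref)
  list(nmse = val_nmse, Y_val = traj$Y, diverged = diverged)
}
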