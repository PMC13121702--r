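#' Stage-1 training configuration
#'
#' Collects the Extended Kalman Filter settings used by [africo_stage1].
#' The filter runs on an augmented state holding the reservoir state, the
#' input weights, the state-feedback weights and a provisional linear
#' readout; these knobs control its prior and noise model.
#'
#' @param alpha initial covariance scale: `P(0) = alpha * I`. Moderate
#'   values (the default 1) give stable convergence without task-specific
#'   tuning.
#' @param q_state process-noise variance on the reservoir-state block.
#' @param q_weights process-noise variance on the weight blocks (random-walk
#'   drift allowance).
#' @param r measurement-noise variance; when the data were corrupted at a
#'   known SNR set `r = var(z)/snr`.
#' @param epochs number of passes over the training data (the reservoir
#'   state is reset to zero between passes while weights and covariance
#'   carry over).
#' @param divergence_limit abort threshold on `max(abs(mean))`.
#' @param rho_max_cl stability constraint: upper bound on the spectral
#'   radius of the learned closed loop `W + W_in W_fb`. The feedback
#'   estimate is projected back onto this set (by rescaling `W_fb`)
#'   whenever the state estimate runs away, and once after training, so the
#'   trained network keeps the echo state property. Only relevant for
#'   identity-activation reservoirs (tanh states are bounded regardless).
#' @return a list of class `africo_config`.
#' @export
ekf_config <- function(alpha = 1, q_state = 1e-4, q_weights = 1e-6,
                       r = 1e-2, epochs = 1L, divergence_limit = 1e6,
                       rho_max_cl = 0.98) {
  stopifnot(alpha > 0, q_state >= 0, q_weights >= 0, r > 0, epochs >= 1,
            rho_max_cl > 0, rho_max_cl < 1)
  structure(list(alpha = alpha, q_state = q_state, q_weights = q_weights,
                 r = r, epochs = as.integer(epochs),
                 divergence_limit = divergence_limit, rho_max_cl = rho_max_cl),
            class = "africo_config")
}

## Index layout of the augmented state:
## [ x (N) | vec(W_in) (N*m) | vec(W_fb) (m*N) | W_out (N) ]
ekf_layout <- function(N, m) {
  ix <- 1:N
  iwin <- N + seq_len(N * m)
  iwfb <- N + N * m + seq_len(m * N)
  iout <- N + N * m + m * N + seq_len(N)
  list(ix = ix, iwin = iwin, iwfb = iwfb, iout = iout,
       dim = N + 2L * N * m + N)
}

#' Initialise the augmented EKF state
#'
#' The augmented mean stacks the zero reservoir state, the model's current
#' input and state-feedback weights, and a zero provisional linear readout;
#' the covariance starts as `alpha * I`.
#'
#' @param model a state-feedback `esn_model`.
#' @param config an [ekf_config].
#' @return a list of class `ekf_state` with elements `mean`, `P`, `Qdiag`,
#'   `r`, `layout`, plus cached model fields.
#' @export
ekf_init <- function(model, config = ekf_config()) {
  stopifnot(inherits(model, "esn_model"))
  if (model$feedback_mode != "state") {
    stop("stage-1 EKF adaptation is defined for state-feedback models")
  }
  N <- model$N; m <- model$m
  lay <- ekf_layout(N, m)
  mean <- numeric(lay$dim)
  mean[lay$iwin] <- as.numeric(model$W_in)
  mean[lay$iwfb] <- as.numeric(model$W_fb)
  if (is.numeric(model$readout)) mean[lay$iout] <- model$readout
  Qdiag <- numeric(lay$dim)
  Qdiag[lay$ix] <- config$q_state
  Qdiag[-lay$ix] <- config$q_weights
  structure(list(mean = mean, P = diag(config$alpha, lay$dim),
                 Qdiag = Qdiag, r = config$r, layout = lay,
                 N = N, m = m, W = model$W, activation = model$activation,
                 divergence_limit = config$divergence_limit),
            class = "ekf_state")
}

## Weight blocks of the augmented mean as matrices.
ekf_weights <- function(st) {
  lay <- st$layout
  list(W_in = matrix(st$mean[lay$iwin], st$N, st$m),
       W_fb = matrix(st$mean[lay$iwfb], st$m, st$N),
       W_out = st$mean[lay$iout])
}

#' EKF prediction (time update)
#'
#' Advances the reservoir-state block through the state-feedback update
#' using the weight blocks of the current mean; weights follow a random
#' walk (unchanged mean). The covariance propagates through the exact
#' analytic Jacobian of the augmented transition, which for pre-activation
#' `s = (W + W_in W_fb) x + W_in u` and `D = diag(f'(s))` has state rows
#' `D [ (W + W_in W_fb), kron(v', I_N), kron(x', W_in), 0 ]` with
#' `v = W_fb x + u`, and identity rows for the weight blocks.
#'
#' @param st an `ekf_state`.
#' @param u input vector for this step.
#' @return the updated `ekf_state`.
#' @export
ekf_predict <- function(st, u) {
  lay <- st$layout
  N <- st$N; m <- st$m
  u <- as.numeric(u)
  stopifnot(length(u) == m)
  x <- st$mean[lay$ix]
  wts <- ekf_weights(st)
  A_cl <- st$W + wts$W_in %*% wts$W_fb
  v <- as.numeric(wts$W_fb %*% x) + u
  s <- as.numeric(A_cl %*% x + wts$W_in %*% u)
  if (st$activation == "tanh") {
    x_new <- tanh(s)
    d <- 1 - x_new^2
  } else {
    x_new <- s
    d <- rep(1, N)
  }
  ## State rows of the Jacobian are J_x = D [A_cl | kron(v', I_N) |
  ## kron(x', W_in) | 0]; weight rows are identity. The products below use
  ## this block structure instead of forming J_x, cutting the cost from
  ## N * dim^2 to roughly N^2 * dim per step.
  P <- st$P
  ## M0 = B %*% P with B the unscaled state rows
  M0 <- A_cl %*% P[lay$ix, , drop = FALSE]
  for (j in seq_len(m)) {
    rows_j <- lay$iwin[((j - 1L) * N + 1L):(j * N)]
    M0 <- M0 + v[j] * P[rows_j, , drop = FALSE]
  }
  Kx <- if (m == 1L) matrix(x, 1L) else kronecker(t(x), diag(m))
  M0 <- M0 + wts$W_in %*% (Kx %*% P[lay$iwfb, , drop = FALSE])
  ## C0 = M0 %*% t(B), again blockwise
  C0 <- tcrossprod(M0[, lay$ix, drop = FALSE], A_cl)
  for (j in seq_len(m)) {
    cols_j <- lay$iwin[((j - 1L) * N + 1L):(j * N)]
    C0 <- C0 + v[j] * M0[, cols_j, drop = FALSE]
  }
  C0 <- C0 + tcrossprod(M0[, lay$iwfb, drop = FALSE], Kx) %*% t(wts$W_in)
  TL <- d * C0 * rep(d, each = N)        # D C0 D
  TL <- (TL + t(TL)) / 2
  wi <- (N + 1L):lay$dim
  TR <- d * M0[, wi, drop = FALSE]
  ## weight-block covariance is untouched by the transition; write the new
  ## state blocks into a copy rather than reassembling the full matrix
  P <- st$P
  P[lay$ix, lay$ix] <- TL
  P[lay$ix, wi] <- TR
  P[wi, lay$ix] <- t(TR)
  diag(P) <- diag(P) + st$Qdiag
  st$mean[lay$ix] <- x_new
  st$P <- P
  if (!all(is.finite(x_new)) || max(abs(x_new)) > st$divergence_limit) {
    stop("EKF divergence: non-finite or exploding reservoir state during prediction")
  }
  st
}

#' EKF measurement update
#'
#' Scalar-innovation Kalman update for the bilinear measurement
#' `y = W_out x`, whose Jacobian row touches both the state block
#' (`W_out`) and the provisional-readout block (`x`). Uses the Joseph
#' form and explicit symmetrisation so the covariance stays symmetric
#' positive semi-definite.
#'
#' @param st an `ekf_state`.
#' @param z scalar measurement.
#' @return the updated `ekf_state`, with attributes `innovation` and `S`
#'   stored in fields `last_innovation` and `last_S`.
#' @export
ekf_update <- function(st, z) {
  lay <- st$layout
  x <- st$mean[lay$ix]
  w_out <- st$mean[lay$iout]
  yhat <- sum(w_out * x)
  e <- z - yhat
  ## Pc = P c' with c sparse over the state and readout blocks
  Pc <- st$P[, lay$ix, drop = FALSE] %*% w_out +
        st$P[, lay$iout, drop = FALSE] %*% x
  Pc <- as.numeric(Pc)
  S <- sum(w_out * Pc[lay$ix]) + sum(x * Pc[lay$iout]) + st$r
  if (S <= 0) stop("non-positive innovation variance in EKF update")
  K <- Pc / S
  st$mean <- st$mean + K * e
  ## Joseph form: P <- (I - K c) P (I - K c)' + r K K'
  A <- st$P - tcrossprod(K, Pc)
  Ac <- as.numeric(A[, lay$ix, drop = FALSE] %*% w_out +
                   A[, lay$iout, drop = FALSE] %*% x)
  P <- A - tcrossprod(Ac - st$r * K, K)
  st$P <- (P + t(P)) / 2
  st$last_innovation <- e
  st$last_S <- S
  st
}

## Project the feedback-weight estimate onto the echo-state-property set
## {W_fb : rho(W + W_in W_fb) <= rho_max} by rescaling (no-op when inside).
ekf_project_stability <- function(st, rho_max) {
  lay <- st$layout
  wts <- ekf_weights(st)
  if (spectral_radius(st$W + wts$W_in %*% wts$W_fb) <= rho_max) return(st)
  W_fb <- stabilise_feedback(st$W, wts$W_in, wts$W_fb, rho_max)
  st$mean[lay$iwfb] <- as.numeric(W_fb)
  st
}

#' Stage-1 AFRICO training: joint EKF estimation
#'
#' Runs the Extended Kalman Filter over the training data, jointly
#' estimating the reservoir state, the input weights `W_in`, the
#' state-feedback weights `W_fb` and a provisional linear readout. The
#' reservoir matrix `W` stays fixed throughout. After filtering, the
#' adapted `W_in` and `W_fb` are written back into the model; the
#' provisional readout is discarded (stage 2 refits the readout from
#' scratch) but returned in the trace for diagnostics.
#'
#' @param model a state-feedback `esn_model`.
#' @param U training input sequence (vector or `T` x `m` matrix).
#' @param Z training target sequence (length `T`).
#' @param config an [ekf_config].
#' @param use_compiled run the filter pass through the compiled
#'   (RcppArmadillo) loop; the pure-R step functions [ekf_predict] and
#'   [ekf_update] implement the identical recursion and the two paths are
#'   asserted equal in the test suite.
#' @param warm_start_readout initialise the provisional readout block from
#'   a short ridge regression on an open-loop pre-run (first
#'   `min(500, T)` points) instead of zero. With a zero readout the
#'   measurement Jacobian carries no information about the reservoir state
#'   at the start of filtering, which slows (and for saturating reservoirs
#'   can stall) the joint estimation; the warm start gives the bilinear
#'   measurement model a sensible operating point from the first step.
#'   Ignored when the model already carries a linear readout.
#' @return list with `model` (adapted weights) and `trace`, a data frame
#'   with per-step innovation, innovation variance and parameter norm,
#'   plus attributes `W_out_provisional` and `final_state`.
#' @export
africo_stage1 <- function(model, U, Z, config = ekf_config(),
                          warm_start_readout = TRUE, use_compiled = TRUE) {
  U <- input_matrix(U, model$m)
  Z <- as.numeric(Z)
  T_len <- nrow(U)
  stopifnot(length(Z) == T_len)
  filter_model <- model
  if (warm_start_readout && !is.numeric(model$readout)) {
    T0 <- min(500L, T_len)
    pre <- esn_simulate(model, U[seq_len(T0), , drop = FALSE])
    w0 <- qr.solve(rbind(pre$X, diag(1e-3, model$N)),
                   c(Z[seq_len(T0)], numeric(model$N)))
    filter_model$readout <- as.numeric(w0)
  }
  if (use_compiled) {
    w_out0 <- if (is.numeric(filter_model$readout)) filter_model$readout
              else numeric(model$N)
    res <- .africo_stage1_cpp(model$W, filter_model$W_in, filter_model$W_fb,
                              w_out0, U, Z, config$alpha, config$q_state,
                              config$q_weights, config$r, config$epochs,
                              model$activation == "tanh", config$rho_max_cl,
                              config$divergence_limit)
    model$W_in <- res$W_in
    model$W_fb <- res$W_fb
    trace <- data.frame(step = seq_along(res$innovation),
                        innovation = as.numeric(res$innovation),
                        S = as.numeric(res$S),
                        param_norm = as.numeric(res$param_norm))
    attr(trace, "W_out_provisional") <- as.numeric(res$W_out)
    attr(trace, "final_state") <- as.numeric(res$final_state)
    attr(trace, "state_resets") <- res$resets
    return(list(model = model, trace = trace))
  }
  st <- ekf_init(filter_model, config)
  n_tot <- T_len * config$epochs
  innov <- numeric(n_tot); Svar <- numeric(n_tot); pnorm <- numeric(n_tot)
  i <- 0L
  resets <- 0L
  for (ep in seq_len(config$epochs)) {
    st$mean[st$layout$ix] <- 0  # zero initial state each pass
    for (k in seq_len(T_len)) {
      step_res <- tryCatch({
        st <- ekf_predict(st, U[k, ])
        st <- ekf_update(st, Z[k])
        NULL
      }, error = function(err) err)
      if (!is.null(step_res)) {
        stop(sprintf("stage-1 EKF diverged at epoch %d, step %d: %s",
                     ep, k, conditionMessage(step_res)))
      }
      i <- i + 1L
      innov[i] <- st$last_innovation
      Svar[i] <- st$last_S
      pnorm[i] <- sqrt(sum(st$mean[-st$layout$ix]^2))
      ## soft guard: if the state estimate runs away (transiently unstable
      ## closed loop), re-anchor it at zero and project the feedback
      ## estimate back onto the stability constraint rho(A_cl) <= rho_max_cl
      if (max(abs(st$mean[st$layout$ix])) > 1e3) {
        st$mean[st$layout$ix] <- 0
        st <- ekf_project_stability(st, config$rho_max_cl)
        resets <- resets + 1L
      }
    }
  }
  st <- ekf_project_stability(st, config$rho_max_cl)
  wts <- ekf_weights(st)
  model$W_in <- wts$W_in
  model$W_fb <- wts$W_fb
  trace <- data.frame(step = seq_len(n_tot), innovation = innov,
                      S = Svar, param_norm = pnorm)
  attr(trace, "W_out_provisional") <- wts$W_out
  attr(trace, "final_state") <- st$mean[st$layout$ix]
  attr(trace, "state_resets") <- resets
  list(model = model, trace = trace)
}
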