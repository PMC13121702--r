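#' Two-stage AFRICO training
#'
#' Full training pipeline for a state-feedback ESN:
#' \enumerate{
#'   \item Stage 1 ([africo_stage1]): joint EKF estimation of the input and
#'     state-feedback weights (reservoir matrix fixed).
#'   \item Stage 2: the adapted model is re-simulated from the zero state
#'     over the concatenated training + validation inputs; candidate
#'     monomials up to `max_degree` are enumerated over the reservoir
#'     states and a sparse readout is selected by Orthogonal Forward
#'     Regression with the ERR criterion ([ofr_err_select]), using the
#'     validation segment only for the stopping rule.
#' }
#' The provisional linear readout co-estimated in stage 1 is discarded;
#' stage 2 refits the readout from scratch.
#'
#' @param model a state-feedback `esn_model`.
#' @param U_train,Z_train training input/target sequences.
#' @param U_val,Z_val validation sequences (used only for readout
#'   stopping).
#' @param config an [ekf_config] for stage 1.
#' @param max_degree maximum monomial degree of the readout (1 = linear).
#' @param include_constant include a constant readout term?
#' @param max_terms,patience,err_tol passed to [ofr_err_select].
#' @param washout number of initial training steps excluded from the
#'   readout regression (zero-state transient); the states are still
#'   simulated through them.
#' @param candidate_cap overflow guard for the candidate set.
#' @return the trained `esn_model`, with attributes `stage1_trace`,
#'   `readout_info` (the full [sparse_readout]) and `val_states` (the
#'   free-run validation states, for evaluation).
#' @export
africo_train <- function(model, U_train, Z_train, U_val, Z_val,
                         config = ekf_config(), max_degree = 3L,
                         include_constant = FALSE, max_terms = 300L,
                         patience = 10L, err_tol = 1e-6, washout = 0L,
                         candidate_cap = 2e5) {
  U_train <- input_matrix(U_train, model$m)
  U_val <- input_matrix(U_val, model$m)
  s1 <- africo_stage1(model, U_train, Z_train, config)
  model <- s1$model
  ## collect states: training segment, then validation continuing free-run
  traj <- esn_simulate(model, rbind(U_train, U_val))
  T_tr <- nrow(U_train)
  stopifnot(washout >= 0L, washout < T_tr)
  keep <- (washout + 1L):T_tr
  X_tr <- traj$X[keep, , drop = FALSE]
  X_val <- traj$X[(T_tr + 1L):nrow(traj$X), , drop = FALSE]
  terms <- enumerate_monomials(model$N, max_degree, include_constant,
                               cap = candidate_cap)
  Phi <- design_matrix(terms, X_tr)
  readout <- ofr_err_select(Phi, Z_train[keep], terms = terms,
                            max_terms = max_terms, patience = patience,
                            err_tol = err_tol,
                            validation = list(X = X_val, z = Z_val))
  rm(Phi)
  model$readout <- readout
  attr(model, "stage1_trace") <- s1$trace
  attr(model, "readout_info") <- readout
  attr(model, "val_states") <- X_val
  model
}

#' Free-run validation NMSE of a trained model
#'
#' Simulates the model over the concatenated training + validation inputs
#' from the zero state (so the validation segment continues from the
#' training-final state), applies the readout, and scores the validation
#' prediction against the reference.
#'
#' @param model a trained `esn_model` (state-feedback or input-driven).
#' @param U_train,U_val input sequences.
#' @param Z_val_ref validation reference (clean target when available).
#' @return list with `nmse` and the validation predictions `Y_val`.
#' @export
evaluate_free_run <- function(model, U_train, U_val, Z_val_ref) {
  U_train <- input_matrix(U_train, model$m)
  U_val <- input_matrix(U_val, model$m)
  traj <- esn_simulate(model, rbind(U_train, U_val))
  T_tr <- nrow(U_train)
  Y_val <- traj$Y[(T_tr + 1L):length(traj$Y)]
  list(nmse = nmse(Y_val, Z_val_ref), Y_val = Y_val)
}
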