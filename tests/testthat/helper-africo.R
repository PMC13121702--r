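# Small deterministic model builders shared across test files.

tiny_state_esn <- function(N = 5, m = 1, activation = "identity", seed = 7) {
  random_esn(N, m, activation, "state", c(0.6, 0.8), "unconstrained", seed = seed)
}

# Direct (non-vectorised) simulation oracle for a state-feedback ESN with
# identity activation: x(k) = A_cl x(k-1) + W_in u(k).
oracle_linear_states <- function(model, u) {
  A <- model$W + model$W_in %*% model$W_fb
  x <- numeric(model$N)
  X <- matrix(0, length(u), model$N)
  for (k in seq_along(u)) {
    x <- as.numeric(A %*% x + model$W_in * u[k])
    X[k, ] <- x
  }
  X
}
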