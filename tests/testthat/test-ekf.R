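# Numerical transition function of the augmented EKF state, used to verify
# the analytic Jacobian by central differences.
augmented_transition <- function(theta, model, u) {
  N <- model$N; m <- model$m
  lay <- africo:::ekf_layout(N, m)
  x <- theta[lay$ix]
  W_in <- matrix(theta[lay$iwin], N, m)
  W_fb <- matrix(theta[lay$iwfb], m, N)
  s <- as.numeric((model$W + W_in %*% W_fb) %*% x + W_in %*% u)
  xn <- if (model$activation == "tanh") tanh(s) else s
  c(xn, theta[-lay$ix])
}

numeric_jacobian <- function(f, theta, h = 1e-6) {
  n <- length(theta)
  f0 <- f(theta)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- h
    J[, j] <- (f(theta + e) - f(theta - e)) / (2 * h)
  }
  J
}

analytic_state_jacobian <- function(st) {
  # rebuild the state rows of the Jacobian exactly as ekf_predict does
  lay <- st$layout; N <- st$N; m <- st$m
  x <- st$mean[lay$ix]
  wts <- africo:::ekf_weights(st)
  u <- attr(st, "test_u")
  A_cl <- st$W + wts$W_in %*% wts$W_fb
  v <- as.numeric(wts$W_fb %*% x) + u
  s <- as.numeric(A_cl %*% x + wts$W_in %*% u)
  d <- if (st$activation == "tanh") 1 - tanh(s)^2 else rep(1, N)
  Jx <- cbind(A_cl,
              if (m == 1L) diag(v, N) else kronecker(t(v), diag(N)),
              kronecker(t(x), wts$W_in),
              matrix(0, N, N))
  rbind(d * Jx,
        cbind(matrix(0, lay$dim - N, N), diag(lay$dim - N)))
}

test_that("analytic EKF Jacobians match central finite differences", {
  set.seed(61)
  for (act in c("identity", "tanh")) {
    for (rep in 1:10) {
      m_dim <- sample(1:2, 1)
      model <- random_esn(5, m_dim, act, "state", c(0.5, 0.8), seed = 100 * rep + m_dim)
      st <- ekf_init(model, ekf_config())
      st$mean <- rnorm(st$layout$dim) * 0.5
      u <- rnorm(m_dim)
      attr(st, "test_u") <- u
      J_ana <- analytic_state_jacobian(st)
      J_num <- numeric_jacobian(function(th) augmented_transition(th, model, u), st$mean)
      expect_lt(max(abs(J_num - J_ana)) / max(abs(J_ana)), 1e-6)
    }
  }
})

test_that("prediction keeps weight means fixed and propagates zero covariance to zero", {
  model <- tiny_state_esn(N = 4, seed = 3)
  st <- ekf_init(model, ekf_config(q_state = 0, q_weights = 0))
  st$P[] <- 0
  st2 <- ekf_predict(st, 0.4)
  expect_equal(max(abs(st2$P)), 0)
  expect_equal(st2$mean[-st2$layout$ix], st$mean[-st$layout$ix])
})

test_that("initialisation: alpha scales the identity prior, state block is zero", {
  model <- tiny_state_esn(N = 4, seed = 5)
  st <- ekf_init(model, ekf_config(alpha = 1))
  expect_equal(diag(st$P), rep(1, st$layout$dim))
  expect_identical(st$P, t(st$P))
  expect_equal(st$mean[st$layout$ix], rep(0, 4))
  expect_equal(matrix(st$mean[st$layout$iwin], 4, 1), model$W_in)
  expect_error(ekf_config(alpha = -1))
})

test_that("measurement update follows the scalar Kalman closed form and contracts trace", {
  # 1-dim toy: c = 1, P = 1, R = 1 -> K = 0.5, posterior variance 0.5
  model <- esn_model(matrix(0.1), matrix(1), matrix(0), feedback_mode = "state")
  st <- ekf_init(model, ekf_config(alpha = 1, r = 1))
  st$mean <- c(1, 1, 0, 1)        # x = 1, W_out = 1 -> c = [1, 0, 0, 1]
  st$P <- diag(c(1, 0, 0, 0))     # only state uncertainty
  st2 <- ekf_update(st, 2)        # yhat = 1, e = 1, S = 1 + 1 = 2
  expect_equal(st2$last_S, 2)
  expect_equal(st2$mean[1], 1 + (1 / 2) * 1)  # K_x = 0.5
  expect_equal(st2$P[1, 1], 0.5, tolerance = 1e-12)
  # no-information limit: huge R leaves mean and P essentially unchanged
  st_hi <- ekf_init(model, ekf_config(alpha = 1, r = 1e12))
  st_hi$mean <- c(0.5, 1, 0.2, 0.7)
  before <- st_hi$P
  st_hi2 <- ekf_update(st_hi, 3)
  expect_lt(max(abs(st_hi2$P - before)), 1e-8 * max(abs(before)))
  # trace never increases at an update
  model2 <- tiny_state_esn(N = 5, seed = 8)
  st <- ekf_init(model2, ekf_config())
  st$mean <- rnorm(st$layout$dim)
  st2 <- ekf_update(st, 0.3)
  expect_lte(sum(diag(st2$P)), sum(diag(st$P)) + 1e-12)
})

test_that("covariance stays symmetric PSD through filtering steps", {
  model <- tiny_state_esn(N = 5, activation = "tanh", seed = 19)
  st <- ekf_init(model, ekf_config(r = 0.05))
  set.seed(4)
  for (k in 1:60) {
    st <- ekf_predict(st, runif(1))
    st <- ekf_update(st, sin(k / 5))
    expect_equal(st$P, t(st$P))
    ev_min <- min(eigen(st$P, symmetric = TRUE, only.values = TRUE)$values)
    expect_gt(ev_min, -1e-8 * max(diag(st$P)))
  }
})

test_that("stage 1 leaves weights untouched on identically zero data", {
  model <- tiny_state_esn(N = 4, seed = 23)
  out <- africo_stage1(model, rep(0, 50), rep(0, 50),
                       ekf_config(q_weights = 0), warm_start_readout = FALSE)
  expect_equal(out$model$W_in, model$W_in, tolerance = 1e-10)
  expect_equal(out$model$W_fb, model$W_fb, tolerance = 1e-10)
  expect_equal(nrow(out$trace), 50)
})

test_that("stage 1 recovers the input-output map of a matched state-feedback ESN", {
  # target: a state-feedback ESN of identical dimensions, noiseless data
  target <- random_esn(4, 1, "identity", "state", c(0.5, 0.7), seed = 31)
  target$readout <- c(1, -0.5, 0.25, 0.8)
  set.seed(32)
  u <- runif(900)
  z <- esn_simulate(target, u)$Y
  learner <- random_esn(4, 1, "identity", "state", c(0.5, 0.7), seed = 33)
  s1 <- africo_stage1(learner, u[1:600], z[1:600], ekf_config(r = 1e-4, epochs = 3))
  m2 <- s1$model
  traj <- esn_simulate(m2, u)
  w <- qr.solve(traj$X[1:600, ], z[1:600])
  m2$readout <- as.numeric(w)
  ev <- evaluate_free_run(m2, u[1:600], u[601:900], z[601:900])
  expect_lt(ev$nmse, 1e-3)
})

test_that("innovations shrink over stage-1 training on a linear target", {
  cfg <- experiment_config("exampleA", "africo", N = 20, reps = 1)
  dat <- generate_benchmark(cfg, seed = 7)
  model <- random_esn(20, 1, "identity", "state", c(0.8, 0.9), "uniform", seed = 71)
  s1 <- africo_stage1(model, dat$U_train, dat$Z_train,
                      ekf_config(r = stats::var(dat$Z_train) / 25))
  inn <- abs(s1$trace$innovation)
  n <- length(inn)
  expect_lt(mean(tail(inn, n %/% 10)), mean(head(inn, n %/% 10)))
})
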