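test_that("benchmark generation is reproducible and splits lengths correctly", {
  cfg <- experiment_config("exampleA", "africo", N = 10, train_len = 100, val_len = 40)
  d1 <- generate_benchmark(cfg, seed = 5)
  d2 <- generate_benchmark(cfg, seed = 5)
  expect_identical(d1$Z_train, d2$Z_train)
  expect_equal(nrow(d1$U_train), 100)
  expect_equal(length(d1$Z_val_clean), 40)
  # the noisy and clean validation signals differ by SNR-scaled noise
  noise_var <- stats::var(d1$Z_val - d1$Z_val_clean)
  expect_gt(noise_var, 0)
  d3 <- generate_benchmark(cfg, seed = 6)
  expect_false(identical(d1$Z_train, d3$Z_train))
})

test_that("trials are deterministic given (config, seed)", {
  cfg <- experiment_config("narma10", "africo", N = 8, train_len = 300,
                           val_len = 120, max_terms = 20, epochs = 1)
  t1 <- run_trial(cfg, 42)
  t2 <- run_trial(cfg, 42)
  expect_identical(t1$nmse, t2$nmse)
  expect_identical(t1$n_terms, t2$n_terms)
  expect_lt(t1$nmse, 1)  # beats the mean predictor
})

test_that("batch summaries are recomputable from the per-replicate values", {
  cfg <- experiment_config("narma10", "africo", N = 6, train_len = 250,
                           val_len = 100, max_terms = 15, epochs = 1, reps = 4)
  res <- run_batch(cfg, seed = 2)
  per <- res$per_replicate
  ok <- per$nmse[!per$diverged & is.finite(per$nmse)]
  expect_equal(res$summary$mean, mean(ok))
  expect_equal(res$summary$median, stats::median(ok))
  expect_equal(res$summary$q1, unname(stats::quantile(ok, 0.25)))
  expect_equal(res$summary$sd, stats::sd(ok))
  expect_equal(nrow(per), 4)
  # reps = 1 collapses the summary to the single value
  cfg1 <- experiment_config("narma10", "africo", N = 6, train_len = 250,
                            val_len = 100, max_terms = 15, epochs = 1, reps = 1)
  r1 <- run_batch(cfg1, seed = 3)
  expect_equal(r1$summary$mean, r1$per_replicate$nmse[1])
})

test_that("delay-embedded configurations carry the lags into the model input", {
  cfg <- experiment_config("narma10", "africo", N = 6, train_len = 200,
                           val_len = 80, input_lags = 3, max_terms = 10,
                           epochs = 1)
  dat <- generate_benchmark(cfg, seed = 9)
  expect_equal(ncol(dat$U_train), 4)
  expect_equal(dat$U_train[10, 2], dat$U_train[9, 1])
})

test_that("frequency-response comparison is exact for a copied model and flags nonlinearity", {
  target <- random_stable_linear(6, 0.5, seed = 12)
  # a state-feedback ESN that IS the target: W = A, no feedback, readout C
  model <- esn_model(target$A, target$B, matrix(0, 1, 6),
                     activation = "identity", feedback_mode = "state",
                     readout = as.numeric(target$C))
  cmp <- compare_frf(model, target)
  expect_lt(cmp$max_mag_error, 1e-12)
  expect_lt(max(abs(cmp$phase_diff)), 1e-12)
  # constant gain ratio for scalar A = 0 systems with different gains
  tA <- structure(list(A = matrix(0), B = matrix(2), C = matrix(1)),
                  class = "linear_target")
  mB <- esn_model(matrix(0), matrix(3), matrix(0, 1, 1),
                  activation = "identity", feedback_mode = "state", readout = 1)
  cmpB <- compare_frf(mB, tA)
  expect_equal(cmpB$mag_ratio, rep(1.5, length(cmpB$mag_ratio)))
  mt <- random_esn(4, 1, "tanh", "state", seed = 5)
  mt$readout <- rnorm(4)
  expect_error(compare_frf(mt, tA), "linear")
})

test_that("stage-1 training matches a dimension-matched linear target's frequency response", {
  # noiseless Example-A-style setting: rho(A_T) < 0.2, matched dimensions
  target <- random_stable_linear(8, 0.2, seed = 44)
  set.seed(45)
  u <- runif(1200)
  z <- simulate_linear_target(target, u)$z_clean
  model <- random_esn(8, 1, "identity", "state", c(0.8, 0.9), "uniform", seed = 46)
  s1 <- africo_stage1(model, u[1:900], z[1:900], ekf_config(r = 1e-4, epochs = 3))
  m2 <- s1$model
  X <- esn_simulate(m2, u)$X
  m2$readout <- as.numeric(qr.solve(X[1:900, ], z[1:900]))
  ev <- evaluate_free_run(m2, u[1:900], u[901:1200], z[901:1200])
  expect_lt(ev$nmse, 1e-3)
  cmp <- compare_frf(m2, target, omegas = seq(0, pi, length.out = 64))
  expect_lt(cmp$max_mag_error, 0.05)
})
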