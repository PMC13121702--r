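# africo

Training echo state networks (ESNs) whose **input and state-feedback
pathways adapt to the task**, with a sparse, interpretable polynomial
readout.

## The problem

An ESN drives a fixed random recurrent reservoir with an input signal and
trains only a readout from the reservoir states. That works when the
reservoir's intrinsic dynamics happen to suit the task; it fails when
they do not — for example when the reservoir eigenvalues are confined to
a narrow disk while the target system's dynamics live elsewhere.
Classical output feedback (FORCE training) feeds the scalar output back
into the network, but a rank-one feedback path cannot reshape an
`N`-dimensional state evolution.

This package implements **AFRICO-style two-stage training** for ESNs with
*state* feedback,

```
x(k) = F( (W + W_in W_fb) x(k-1) + W_in u(k) ),   y(k) = Σ_i w_i p_i(x(k))
```

where the feedback matrix `W_fb` (shape `m × N`) folds into the effective
transition matrix `W + W_in W_fb` and can relocate every closed-loop
eigenvalue:

1. **Stage 1** — an Extended Kalman Filter on the augmented state
   `[x; vec(W_in); vec(W_fb); W_out]` jointly estimates the reservoir
   state and the trainable weights (`W` stays fixed), with exact analytic
   Jacobians, Joseph-form updates and an echo-state-property projection
   guard. The inner filter pass is compiled (RcppArmadillo).
2. **Stage 2** — a sparse polynomial readout is selected from all
   monomials up to cubic degree by Orthogonal Forward Regression with the
   Error-Reduction-Ratio criterion (`ERR_i = (w_i'z)² / (w_i'w_i · z'z)`),
   stopped by held-out validation error.

A FORCE baseline (recursive least squares on the readout of an
output-feedback ESN, teacher-forced during training, free-running at
evaluation) and three synthetic benchmarks — random stable linear
systems, a 40-state linear system with a quadratic-sum output, and the
NARMA10 recursion — are included, along with SNR-calibrated noise
injection, NMSE scoring, frequency-response comparison for linear models
and a seeded replicated-experiment harness.

## A worked example

Train on the NARMA10 benchmark (3000 training / 1500 validation points,
measurement noise at SNR 50) with a 20-neuron linear reservoir:

```r
library(africo)
cfg <- experiment_config("narma10", "africo", N = 20, reps = 3)
res <- run_batch(cfg, seed = 1)
print(res)
#> narma10 / africo: N = 20, SNR = 50, 3 replicate(s), 0 divergent
#>   NMSE mean 0.03212 (sd 0.0232), median 0.02038 [q1 0.01878, q3 0.03959], range [0.01719, 0.0588]
```

Each replicate draws a fresh input sequence, noise realisation and
reservoir, runs both training stages and reports the free-running
validation NMSE against the clean target — here a few percent of the
target variance, where 1.0 would be the score of the constant mean
predictor. A single trained model exposes its selected readout terms:

```r
tr <- run_trial(cfg, seed = 42)
print(tr$model$readout)
#> Sparse polynomial readout: 290 term(s), cumulative ERR = 0.9972 (stop: max_terms)
#>   -304 * x11 x18^2   (ERR 0.958)
#>   -1.746 * x4   (ERR 0.00182)
#>   -78.75 * x18^2 x20   (ERR 0.00208)
#>   ...
```

Lower-level entry points: `random_esn()`, `africo_stage1()`,
`ofr_err_select()`, `force_train()`, `narma10()`, `compare_frf()`. See
the methods vignette (`vignettes/africo-methods.Rmd`) for the model, the
training scheme and every numerical convention.

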