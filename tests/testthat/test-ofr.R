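test_that("monomial counts match the closed form and the printed benchmark sizes", {
  expect_equal(count_monomials(1, 1), 1)
  expect_equal(count_monomials(2, 2), 5)
  expect_equal(count_monomials(80, 3), 91880)
  expect_equal(count_monomials(52, 3), 26234)
  expect_equal(count_monomials(11, 3, include_constant = TRUE), 364)
})

test_that("enumeration is exhaustive, graded-lex ordered, and consistent with the count", {
  t22 <- enumerate_monomials(2, 2)
  expect_equal(nrow(t22), 5)
  # x1, x2, x1^2, x1 x2, x2^2
  expect_equal(t22, rbind(c(1, 0), c(2, 0), c(1, 1), c(1, 2), c(2, 2)),
               ignore_attr = TRUE)
  for (N in c(3, 7)) {
    tt <- enumerate_monomials(N, 3)
    expect_equal(nrow(tt), count_monomials(N, 3))
    expect_equal(nrow(unique(tt)), nrow(tt))  # distinct
    deg <- rowSums(tt > 0)
    expect_true(all(diff(deg) >= 0))          # graded
  }
  expect_equal(nrow(enumerate_monomials(52, 3)), 26234)
  expect_error(enumerate_monomials(80, 3, cap = 1000), "cap")
  tc <- enumerate_monomials(2, 2, include_constant = TRUE)
  expect_equal(nrow(tc), 6)
  expect_true(all(tc[1, ] == 0))
})

test_that("design matrix evaluates monomials exactly", {
  X <- matrix(c(2, 3), 1, 2)
  terms <- rbind(c(1, 0), c(1, 2), c(2, 2))
  D <- design_matrix(terms, X)
  expect_equal(as.numeric(D), c(2, 6, 9))
  X2 <- matrix(rnorm(20), 10, 2)
  expect_equal(design_matrix(rbind(c(1, 0)), X2)[, 1], X2[, 1])
  expect_equal(design_matrix(rbind(c(1, 1, 2)), cbind(X2, 1))[, 1], X2[, 1]^2 * X2[, 2])
  expect_true(all(design_matrix(rbind(c(1, 0), c(2, 2)), matrix(0, 4, 2)) == 0))
  expect_error(design_matrix(rbind(c(3, 0)), X2), "beyond")
})

test_that("a perfect regressor is selected first with ERR 1 and zero residual", {
  set.seed(2)
  Phi <- matrix(rnorm(200), 50, 4)
  z <- Phi[, 3] * 2
  ro <- ofr_err_select(Phi, z, err_tol = 1e-10)
  expect_equal(ro$selected[1], 3)
  expect_equal(ro$err[1], 1, tolerance = 1e-12)
  expect_equal(ro$coefficients[1], 2, tolerance = 1e-10)
})

test_that("with orthonormal candidates the selection order sorts squared projections", {
  set.seed(14)
  Q <- qr.Q(qr(matrix(rnorm(40 * 8), 40, 8)))
  z <- rnorm(40)
  ro <- ofr_err_select(Q, z, max_terms = 8, err_tol = 1e-14)
  proj <- as.numeric(crossprod(Q, z))^2
  expect_equal(ro$selected, order(proj, decreasing = TRUE)[seq_along(ro$selected)])
})

test_that("OFR exactly recovers a planted sparse polynomial without noise", {
  set.seed(8)
  Phi <- matrix(rnorm(100 * 20), 100, 20)
  z <- 2 * Phi[, 3] - Phi[, 7] + 0.5 * Phi[, 9]
  ro <- ofr_err_select(Phi, z, err_tol = 1e-12)
  expect_setequal(ro$selected[1:3], c(3, 7, 9))
  coef <- numeric(20); coef[ro$selected] <- ro$coefficients
  expect_equal(coef[c(3, 7, 9)], c(2, -1, 0.5), tolerance = 1e-8)
})

test_that("the ERR identity holds: residual SS equals (1 - sum ERR) * z'z", {
  set.seed(21)
  for (rep in 1:5) {
    Phi <- matrix(rnorm(80 * 15), 80, 15)
    z <- Phi %*% rnorm(15) + rnorm(80)
    ro <- ofr_err_select(Phi, as.numeric(z), max_terms = 10, err_tol = 1e-14)
    pred <- Phi[, ro$selected, drop = FALSE] %*% ro$coefficients
    rss <- sum((z - pred)^2)
    expect_true(all(ro$err >= 0 & ro$err <= 1))
    expect_lte(sum(ro$err), 1 + 1e-10)
    expect_equal(rss, (1 - sum(ro$err)) * sum(z^2),
                 tolerance = 1e-8 * sum(z^2))
    # adding terms never increases the training residual
    expect_true(all(diff(ro$train_nmse) <= 1e-12))
  }
})

test_that("OFR matches exhaustive best-subset search for 1- and 2-term models", {
  set.seed(33)
  for (rep in 1:4) {
    Phi <- matrix(rnorm(60 * 12), 60, 12)
    z <- as.numeric(Phi %*% c(3, rep(0, 10), -2) + 0.05 * rnorm(60))
    rss_of <- function(cols) {
      fit <- lm.fit(Phi[, cols, drop = FALSE], z)
      sum(fit$residuals^2)
    }
    # one term: OFR's first pick must equal the best single column
    ro1 <- ofr_err_select(Phi, z, max_terms = 1)
    best1 <- which.min(vapply(1:12, rss_of, numeric(1)))
    expect_equal(ro1$selected[1], best1)
    # two terms: greedy forward selection conditional on the first pick
    ro2 <- ofr_err_select(Phi, z, max_terms = 2)
    rest <- setdiff(1:12, ro1$selected[1])
    best2 <- rest[which.min(vapply(rest, function(j) rss_of(c(ro1$selected[1], j)),
                                   numeric(1)))]
    expect_equal(ro2$selected[2], best2)
  }
})

test_that("validation stopping truncates at the validation-optimal length", {
  set.seed(55)
  Phi <- matrix(rnorm(200 * 30), 200, 30)
  beta <- c(rnorm(5), rep(0, 25))
  z <- as.numeric(Phi %*% beta + 0.3 * rnorm(200))
  Phi_v <- matrix(rnorm(100 * 30), 100, 30)
  z_v <- as.numeric(Phi_v %*% beta + 0.3 * rnorm(100))
  ro <- ofr_err_select(Phi, z, max_terms = 30, patience = 5,
                       validation = list(Phi = Phi_v, z = z_v))
  k <- length(ro$coefficients)
  expect_lt(k, 30)
  expect_equal(k, which.min(ro$val_nmse))
  # the kept model is at the minimum of the recorded validation curve
  expect_equal(min(ro$val_nmse), ro$val_nmse[k])
})

test_that("degenerate inputs are rejected or flagged", {
  Phi <- matrix(rnorm(40), 20, 2)
  expect_error(ofr_err_select(Phi, rep(1, 20)), "constant")
  expect_error(ofr_err_select(matrix(c(1, Inf), 2, 1), c(1, 2)), "non-finite")
  # collinear duplicate columns: second copy never selected
  P2 <- cbind(Phi[, 1], Phi[, 1])
  expect_warning(ro <- ofr_err_select(P2, Phi[, 1] + 0.01 * rnorm(20),
                                      max_terms = 2, err_tol = 1e-15),
                 "collinear")
  expect_equal(length(ro$coefficients), 1)
})
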