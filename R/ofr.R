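#' Number of candidate monomials
#'
#' Count of distinct monomials in `N` variables with total degree between 1
#' and `max_degree`: `choose(N + d, d) - 1`, plus 1 when the constant term
#' is included.
#'
#' @param N number of variables (reservoir states).
#' @param max_degree maximum total degree.
#' @param include_constant include the degree-0 term?
#' @return an integer count.
#' @export
count_monomials <- function(N, max_degree, include_constant = FALSE) {
  stopifnot(N >= 1, max_degree >= 1)
  choose(N + max_degree, max_degree) - (!include_constant)
}

#' Enumerate candidate monomials
#'
#' All distinct monomials in `N` variables with total degree 1 to
#' `max_degree` (plus the constant when enabled), in graded lexicographic
#' order: `x1, ..., xN, x1^2, x1 x2, ..., xN^2, x1^3, ...`. Each monomial is
#' a row of variable indices, zero-padded to `max_degree` columns (the
#' constant term is an all-zero row).
#'
#' @inheritParams count_monomials
#' @param cap overflow guard: error if the candidate count exceeds this.
#' @return an integer matrix with `count_monomials(...)` rows and
#'   `max_degree` columns.
#' @export
enumerate_monomials <- function(N, max_degree = 3L, include_constant = FALSE,
                                cap = 2e5) {
  stopifnot(N >= 1, max_degree >= 1, max_degree <= 3)
  n_terms <- count_monomials(N, max_degree, include_constant)
  if (n_terms > cap) {
    stop(sprintf("candidate set of %d monomials exceeds the configured cap (%g)",
                 n_terms, cap))
  }
  pad <- function(idx) {
    out <- matrix(0L, nrow(idx), max_degree)
    out[, seq_len(ncol(idx))] <- idx
    out
  }
  blocks <- list()
  if (include_constant) blocks[[length(blocks) + 1L]] <- matrix(0L, 1L, max_degree)
  blocks[[length(blocks) + 1L]] <- pad(matrix(seq_len(N), ncol = 1L))
  if (max_degree >= 2L) {
    i2 <- rep.int(seq_len(N), N:1)
    j2 <- unlist(lapply(seq_len(N), function(i) i:N), use.names = FALSE)
    blocks[[length(blocks) + 1L]] <- pad(cbind(i2, j2))
  }
  if (max_degree >= 3L) {
    reps <- unlist(lapply(seq_len(N), function(i) N - (i:N) + 1L), use.names = FALSE)
    i3 <- rep.int(rep.int(seq_len(N), N:1), reps)
    j3 <- rep.int(unlist(lapply(seq_len(N), function(i) i:N), use.names = FALSE), reps)
    k3 <- unlist(lapply(seq_len(N), function(i) {
      unlist(lapply(i:N, function(j) j:N), use.names = FALSE)
    }), use.names = FALSE)
    blocks[[length(blocks) + 1L]] <- cbind(i3, j3, k3)
  }
  out <- do.call(rbind, blocks)
  dimnames(out) <- NULL
  storage.mode(out) <- "integer"
  stopifnot(nrow(out) == n_terms)
  out
}

#' Monomial design matrix
#'
#' Evaluates each candidate monomial on a state sequence: column `j` at row
#' `k` is the product of the indicated state powers at step `k`.
#'
#' @param terms integer matrix of variable indices as returned by
#'   [enumerate_monomials] (zero entries are ignored; an all-zero row is the
#'   constant term).
#' @param X `T` x `N` state matrix.
#' @return a `T` x `nrow(terms)` numeric matrix.
#' @export
design_matrix <- function(terms, X) {
  X <- as.matrix(X)
  terms <- as.matrix(terms)
  if (any(terms > ncol(X))) stop("monomial refers to a state index beyond ncol(X)")
  out <- matrix(1, nrow(X), nrow(terms))
  for (j in seq_len(nrow(terms))) {
    for (v in terms[j, ]) {
      if (v > 0L) out[, j] <- out[, j] * X[, v]
    }
  }
  out
}

format_monomial <- function(term) {
  v <- term[term > 0L]
  if (length(v) == 0L) return("1")
  tab <- table(v)
  paste(vapply(names(tab), function(nm) {
    p <- tab[[nm]]
    if (p == 1L) sprintf("x%s", nm) else sprintf("x%s^%d", as.integer(nm), p)
  }, character(1)), collapse = " ")
}

#' Orthogonal Forward Regression with the Error-Reduction-Ratio criterion
#'
#' Greedy construction of a sparse linear-in-the-parameters model. At each
#' iteration every unselected candidate column is (implicitly)
#' orthogonalised against the selected basis and its error reduction ratio
#' `ERR_i = (w_i' z)^2 / (w_i' w_i * z' z)` is computed; the maximiser is
#' added (ties broken by lowest index). Selection stops when the best
#' remaining ERR falls below `err_tol`, when `max_terms` is reached, or --
#' when a validation set is supplied -- when validation NMSE has failed to
#' improve for `patience` consecutive terms; the returned model is
#' truncated at the validation-optimal length. Final coefficients are the
#' least-squares solution over the selected raw columns (obtained from the
#' accumulated QR factors). Orthogonalisation uses modified Gram-Schmidt
#' with re-orthogonalisation.
#'
#' @param Phi `T` x `n` candidate regressor matrix.
#' @param z length-`T` target.
#' @param terms optional monomial index matrix (one row per column of
#'   `Phi`), carried into the result.
#' @param max_terms hard cap on selected terms.
#' @param patience validation-stopping patience (consecutive non-improving
#'   terms).
#' @param err_tol stop when the best remaining ERR is below this.
#' @param validation optional `list(Phi = ..., z = ...)` held-out set used
#'   only for stopping.
#' @return a [sparse_readout].
#' @export
ofr_err_select <- function(Phi, z, terms = NULL, max_terms = 300L,
                           patience = 10L, err_tol = 1e-6,
                           validation = NULL) {
  Phi <- as.matrix(Phi)
  z <- as.numeric(z)
  T_len <- nrow(Phi)
  n_cand <- ncol(Phi)
  stopifnot(length(z) == T_len, n_cand >= 1)
  if (!all(is.finite(Phi))) stop("non-finite candidate regressors")
  zz <- sum(z^2)
  if (zz <= 0 || stats::var(z) == 0) stop("target sequence is constant")
  if (is.null(terms)) terms <- matrix(seq_len(n_cand), ncol = 1L)
  max_terms <- min(max_terms, n_cand, T_len)

  ssq0 <- colSums(Phi^2)
  ssq <- ssq0
  num <- as.numeric(crossprod(Phi, z))
  Qb <- matrix(0, T_len, max_terms)       # orthonormal basis
  Rm <- matrix(0, max_terms, max_terms)   # Phi[, sel] = Qb %*% Rm
  g <- numeric(max_terms)                 # Qb' z
  sel <- integer(0)
  errs <- numeric(0)
  train_nmse <- numeric(0)
  val_nmse <- numeric(0)
  have_val <- !is.null(validation)
  if (have_val) {
    ## validation regressors: either a full Phi matrix or (memory-light)
    ## a raw state matrix X from which selected columns are built lazily
    Phi_v <- if (is.null(validation$X)) as.matrix(validation$Phi) else NULL
    z_v <- as.numeric(validation$z)
    n_v <- if (is.null(Phi_v)) nrow(validation$X) else nrow(Phi_v)
    Sv <- matrix(0, n_v, max_terms)
  }
  denom_tr <- sum((z - mean(z))^2)
  best_val <- Inf; best_k <- 0L
  reason <- "max_terms"
  alive <- rep(TRUE, n_cand)

  for (k in seq_len(max_terms)) {
    cand_err <- ifelse(alive & ssq > 1e-12 * pmax(ssq0, 1e-300),
                       num^2 / (ssq * zz), -Inf)
    j <- which.max(cand_err)  # ties: lowest index
    if (!is.finite(cand_err[j]) || cand_err[j] < err_tol) {
      reason <- if (is.finite(cand_err[j])) "err_tol" else "collinear"
      if (!is.finite(cand_err[j])) {
        warning("all remaining candidates are numerically collinear with the selected set")
      }
      break
    }
    ## orthogonalise the chosen raw column against the current basis
    w <- Phi[, j]
    if (k > 1L) {
      Qk <- Qb[, seq_len(k - 1L), drop = FALSE]
      w <- w - Qk %*% crossprod(Qk, w)
      w <- w - Qk %*% crossprod(Qk, w)  # re-orthogonalisation
    }
    nw <- sqrt(sum(w^2))
    if (nw <= 1e-12) { alive[j] <- FALSE; next }
    q <- as.numeric(w) / nw
    Rm[seq_len(k - 1L), k] <- if (k > 1L)
      crossprod(Qb[, seq_len(k - 1L), drop = FALSE], Phi[, j]) else numeric(0)
    Rm[k, k] <- sum(q * Phi[, j])
    g[k] <- sum(q * z)
    Qb[, k] <- q
    sel <- c(sel, j)
    errs <- c(errs, cand_err[j])
    alive[j] <- FALSE
    ## project the remaining candidates off q; because q is orthogonal to
    ## the previous basis, Phi' q equals the orthogonalised inner products
    a <- as.numeric(crossprod(Phi, q))
    num <- num - g[k] * a
    ssq <- pmax(ssq - a^2, 0)
    rss <- zz - sum(g[seq_len(k)]^2)
    train_nmse <- c(train_nmse, max(rss, 0) / denom_tr)
    if (have_val) {
      Sv[, k] <- design_col(validation, terms, j, Phi_v)
      coef_k <- backsolve(Rm[seq_len(k), seq_len(k), drop = FALSE], g[seq_len(k)])
      pred_v <- Sv[, seq_len(k), drop = FALSE] %*% coef_k
      val_nmse <- c(val_nmse, nmse(as.numeric(pred_v), z_v))
      if (val_nmse[k] < best_val - 1e-12) { best_val <- val_nmse[k]; best_k <- k }
      if (k - best_k >= patience) { reason <- "validation"; break }
    }
  }
  k_fit <- length(sel)
  k_star <- if (have_val && best_k > 0L) best_k else k_fit
  if (k_star == 0L) stop("OFR selected no terms")
  keep <- seq_len(k_star)
  coefs <- backsolve(Rm[keep, keep, drop = FALSE], g[keep])
  sparse_readout(terms = terms[sel[keep], , drop = FALSE],
                 coefficients = as.numeric(coefs),
                 err = errs[keep],
                 selected = sel[keep],
                 train_nmse = train_nmse[seq_len(k_fit)],
                 val_nmse = if (have_val) val_nmse[seq_len(k_fit)] else NULL,
                 stop_reason = reason,
                 zz = zz)
}

## column of the validation design matrix for candidate j (lazy build)
design_col <- function(validation, terms, j, Phi_v) {
  if (!is.null(validation$X)) {
    col <- rep(1, nrow(validation$X))
    for (v in terms[j, ]) if (v > 0L) col <- col * validation$X[, v]
    col
  } else {
    Phi_v[, j]
  }
}

#' Sparse polynomial readout
#'
#' Ordered list of selected monomials with least-squares coefficients and
#' per-term error reduction ratios, as produced by [ofr_err_select].
#'
#' @param terms integer monomial index matrix (one row per term).
#' @param coefficients numeric coefficients.
#' @param err per-term ERR values at selection time.
#' @param selected candidate indices in selection order.
#' @param train_nmse,val_nmse per-term NMSE history during selection.
#' @param stop_reason why selection stopped.
#' @param zz target energy used for the ERR normalisation.
#' @return an object of class `sparse_readout`.
#' @export
sparse_readout <- function(terms, coefficients, err,
                           selected = seq_along(coefficients),
                           train_nmse = NULL, val_nmse = NULL,
                           stop_reason = "manual", zz = NA_real_) {
  stopifnot(nrow(terms) == length(coefficients), length(err) == length(coefficients))
  structure(list(terms = as.matrix(terms), coefficients = coefficients,
                 err = err, selected = selected,
                 train_nmse = train_nmse, val_nmse = val_nmse,
                 stop_reason = stop_reason, zz = zz),
            class = "sparse_readout")
}

#' @export
print.sparse_readout <- function(x, ...) {
  k <- length(x$coefficients)
  cat(sprintf("Sparse polynomial readout: %d term(s), cumulative ERR = %.4f (stop: %s)\n",
              k, sum(x$err), x$stop_reason))
  show <- seq_len(min(k, 10L))
  for (i in show) {
    cat(sprintf("  %+ .4g * %s   (ERR %.3g)\n", x$coefficients[i],
                format_monomial(x$terms[i, ]), x$err[i]))
  }
  if (k > 10L) cat(sprintf("  ... and %d more\n", k - 10L))
  invisible(x)
}

#' Predict from a sparse readout
#'
#' @param object a `sparse_readout`.
#' @param X `T` x `N` state matrix.
#' @param ... unused.
#' @return length-`T` prediction vector.
#' @export
predict.sparse_readout <- function(object, X, ...) {
  as.numeric(design_matrix(object$terms, X) %*% object$coefficients)
}
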