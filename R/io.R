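#' Write a time-series CSV
#'
#' Standard on-disk exchange format: header `t,u_1..u_m,z`, one row per
#' step.
#'
#' @param path file path.
#' @param U input sequence (vector or `T` x `m` matrix).
#' @param z output sequence (length `T`).
#' @export
write_timeseries_csv <- function(path, U, z) {
  U <- if (is.null(dim(U))) matrix(as.numeric(U), ncol = 1L) else as.matrix(U)
  stopifnot(nrow(U) == length(z))
  df <- data.frame(t = seq_len(nrow(U)) - 1L, U, z = as.numeric(z))
  names(df) <- c("t", paste0("u_", seq_len(ncol(U))), "z")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a time-series CSV
#'
#' @param path file written by [write_timeseries_csv].
#' @return list with `U` (T x m matrix) and `z` (vector).
#' @export
read_timeseries_csv <- function(path) {
  df <- utils::read.csv(path)
  ucols <- grep("^u_", names(df))
  if (!length(ucols) || !"z" %in% names(df)) {
    stop("expected columns t, u_1..u_m, z")
  }
  list(U = as.matrix(df[, ucols, drop = FALSE]), z = df$z)
}

#' Serialise an ESN model to JSON
#'
#' Stores shapes, activation, feedback mode, row-major flattened weight
#' matrices and the readout (linear vector or sparse term list).
#'
#' @param model an `esn_model`.
#' @param path destination file.
#' @export
write_esn_json <- function(model, path) {
  stopifnot(inherits(model, "esn_model"))
  flat <- function(M) if (is.null(M)) NULL else as.numeric(t(M))  # row-major
  readout <- model$readout
  r_json <- if (is.null(readout)) {
    NULL
  } else if (is.numeric(readout)) {
    list(type = "linear", weights = as.numeric(readout))
  } else {
    list(type = "sparse",
         terms = lapply(seq_along(readout$coefficients), function(i) {
           idx <- readout$terms[i, ]
           list(indices = as.integer(idx[idx > 0L]),
                coefficient = readout$coefficients[i],
                err = readout$err[i])
         }))
  }
  obj <- list(N = model$N, m = model$m, activation = model$activation,
              feedback_mode = model$feedback_mode,
              W = flat(model$W), W_in = flat(model$W_in),
              W_fb = flat(model$W_fb), readout = r_json)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ESN model from JSON
#'
#' @param path file written by [write_esn_json].
#' @return an `esn_model`.
#' @export
read_esn_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  N <- obj$N; m <- obj$m
  unflat <- function(v, nr, nc) matrix(v, nr, nc, byrow = TRUE)
  W <- unflat(obj$W, N, N)
  W_in <- unflat(obj$W_in, N, m)
  W_fb <- switch(obj$feedback_mode,
                 state = unflat(obj$W_fb, m, N),
                 output = unflat(obj$W_fb, N, 1L),
                 none = NULL)
  readout <- NULL
  if (!is.null(obj$readout)) {
    if (identical(obj$readout$type, "linear")) {
      readout <- as.numeric(obj$readout$weights)
    } else {
      tl <- obj$readout$terms
      md <- max(vapply(tl, function(t) length(t$indices), integer(1)))
      terms <- t(vapply(tl, function(t) {
        idx <- as.integer(t$indices)
        c(idx, rep(0L, md - length(idx)))
      }, integer(md)))
      readout <- sparse_readout(
        terms = terms,
        coefficients = vapply(tl, function(t) as.numeric(t$coefficient), numeric(1)),
        err = vapply(tl, function(t) as.numeric(t$err), numeric(1)))
    }
  }
  esn_model(W, W_in, W_fb, activation = obj$activation,
            feedback_mode = obj$feedback_mode, readout = readout)
}
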