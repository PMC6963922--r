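# Dummy response coding: Gansu (0) -> 001, Ningxia (1) -> 010,
# Xinjiang (2) -> 100; i.e. class k lights column 3 - k.
dummy_code <- function(label) {
  Y <- matrix(0, length(label), 3L)
  Y[cbind(seq_along(label), 3L - label)] <- 1
  colnames(Y) <- c("100", "010", "001")
  Y
}

dummy_decode <- function(Yhat) 3L - max.col(Yhat, ties.method = "first")

# SIMPLS (de Jong 1993): sequential rank-one deflation of the
# cross-product S = X'Y. Returns score/weight/loading matrices and the
# per-component cumulative regression coefficients.
simpls <- function(X, Y, a_max) {
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  R <- matrix(0, p, a_max); TT <- matrix(0, n, a_max)
  P <- matrix(0, p, a_max); Q <- matrix(0, q, a_max)
  V <- matrix(0, p, a_max)
  S <- crossprod(X, Y)
  for (a in seq_len(a_max)) {
    r <- svd(S, nu = 1L, nv = 0L)$u[, 1L]
    t_ <- X %*% r
    nt <- sqrt(sum(t_^2))
    if (nt < 1e-12) { a_max <- a - 1L; break }
    t_ <- t_ / nt; r <- r / nt
    p_ <- crossprod(X, t_)
    q_ <- crossprod(Y, t_)
    v <- p_
    if (a > 1L) {
      v <- v - V[, 1:(a - 1L), drop = FALSE] %*%
        crossprod(V[, 1:(a - 1L), drop = FALSE], p_)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; TT[, a] <- t_; P[, a] <- p_; Q[, a] <- q_; V[, a] <- v
  }
  list(R = R[, seq_len(a_max), drop = FALSE],
       scores = TT[, seq_len(a_max), drop = FALSE],
       P = P[, seq_len(a_max), drop = FALSE],
       Q = Q[, seq_len(a_max), drop = FALSE],
       n_comp = a_max)
}

#' Fit a PLS-DA classifier
#'
#' PLS2 regression (SIMPLS) of the centered spectra onto the 3-column
#' dummy response; prediction takes the argmax over the three predicted
#' dummy columns.
#'
#' @param x a `spectrum_table` or samples x variables matrix.
#' @param label origin codes (taken from the table if omitted).
#' @param n_lv number of latent variables; must not exceed the data rank.
#' @return a `plsda_model`.
#' @export
plsda_fit <- function(x, label = NULL, n_lv = 10L) {
  if (inherits(x, "spectrum_table")) {
    label <- label %||% x$label
    x <- x$spectra
  }
  X <- as.matrix(x)
  if (length(unique(label)) < 2L)
    hsi_abort("at least two origin classes must be present for fitting",
              "hsi_invalid_argument")
  rank <- qr(sweep(X, 2L, colMeans(X)))$rank
  if (n_lv > rank)
    hsi_abort(sprintf("n_lv (%d) exceeds the data rank (%d)", n_lv, rank),
              "hsi_rank_error")
  if (n_lv < 1L) hsi_abort("n_lv must be >= 1", "hsi_invalid_argument")
  xc <- colMeans(X); Y <- dummy_code(label); yc <- colMeans(Y)
  fit <- simpls(sweep(X, 2L, xc), sweep(Y, 2L, yc), n_lv)
  B <- fit$R %*% t(fit$Q)
  structure(list(coefficients = B, x_center = xc, y_center = yc,
                 n_lv = fit$n_comp, weights = fit$R, loadings = fit$P,
                 y_loadings = fit$Q, scores = fit$scores,
                 class_codes = colnames(dummy_code(0L))),
            class = "plsda_model")
}

#' Predict origins with a PLS-DA model
#'
#' @param model a `plsda_model`.
#' @param x a `spectrum_table` or matrix over the training wavelengths.
#' @return a `prediction`: list with `label` (argmax class codes),
#'   `scores` (predicted dummy columns), `sample_id`.
#' @export
plsda_predict <- function(model, x) {
  ids <- NULL
  if (inherits(x, "spectrum_table")) { ids <- x$sample_id; x <- x$spectra }
  Yhat <- sweep(as.matrix(x), 2L, model$x_center) %*% model$coefficients
  Yhat <- sweep(Yhat, 2L, model$y_center, `+`)
  structure(list(label = dummy_decode(Yhat), scores = Yhat,
                 sample_id = ids %||% seq_len(nrow(Yhat))),
            class = "prediction")
}

#' Choose the number of latent variables by leave-one-out accuracy
#'
#' Fits n leave-one-out SIMPLS models on the supplied (calibration) data
#' and returns the LV count maximizing LOO classification accuracy, ties
#' broken toward fewer LVs.
#'
#' @param x a `spectrum_table` or matrix.
#' @param label origin codes.
#' @param max_lv largest LV count to consider (capped at the data rank).
#' @return list with `n_lv`, `loo_accuracy` (one value per candidate).
#' @export
plsda_select_lv <- function(x, label = NULL, max_lv = 15L) {
  if (inherits(x, "spectrum_table")) {
    label <- label %||% x$label
    x <- x$spectra
  }
  X <- as.matrix(x)
  n <- nrow(X)
  rank <- qr(sweep(X, 2L, colMeans(X)))$rank
  max_lv <- min(max_lv, rank, n - 2L)
  correct <- matrix(FALSE, n, max_lv)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; li <- label[-i]
    xc <- colMeans(Xi); Y <- dummy_code(li); yc <- colMeans(Y)
    fit <- simpls(sweep(Xi, 2L, xc), sweep(Y, 2L, yc), max_lv)
    xnew <- X[i, ] - xc
    for (a in seq_len(fit$n_comp)) {
      B <- fit$R[, 1:a, drop = FALSE] %*% t(fit$Q[, 1:a, drop = FALSE])
      correct[i, a] <- dummy_decode(matrix(xnew %*% B + yc, 1L)) == label[i]
    }
  }
  acc <- colMeans(correct)
  list(n_lv = which.max(acc), loo_accuracy = acc)
}
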