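#' Principal component analysis of a spectrum table
#'
#' Column-centers the spectra (no scaling) and decomposes by SVD;
#' components are ordered by explained variance.
#'
#' @param x a `spectrum_table` or a samples x variables matrix.
#' @param n_components number of components to keep; reduced with a
#'   warning if it exceeds the data rank.
#' @return a `pca_result`: `loadings` (variables x k), `scores`
#'   (samples x k), `explained_variance` (fractions, descending),
#'   `center`.
#' @export
pca_fit <- function(x, n_components = 3L) {
  X <- if (inherits(x, "spectrum_table")) x$spectra else as.matrix(x)
  if (n_components > min(dim(X)))
    hsi_abort(sprintf("n_components (%d) exceeds min(samples, variables) = %d",
                      n_components, min(dim(X))), "hsi_invalid_argument")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc)
  pos <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * max(sv$d, 1))
  k <- n_components
  if (k > pos) {
    warning(sprintf("rank is %d; reducing n_components from %d", pos, k))
    k <- pos
  }
  ev_all <- sv$d^2 / sum(sv$d^2)
  structure(list(
    loadings = sv$v[, seq_len(k), drop = FALSE],
    scores = sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k),
    explained_variance = ev_all[seq_len(k)],
    center = ctr, n_components = k), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components, explained variance: %s\n",
              x$n_components,
              paste(sprintf("%.2f%%", 100 * x$explained_variance),
                    collapse = ", ")))
  invisible(x)
}
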