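rbf_kernel <- function(D2, gamma) exp(-gamma * D2)

# squared Euclidean distances between rows of A and rows of B
dist2 <- function(A, B = A) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  D2 <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  D2[D2 < 0] <- 0
  D2
}

# one binary C-SVC on a precomputed kernel
svc_binary <- function(K, y, C) {
  sol <- smo_solve(K, as.integer(y), C)
  list(alpha = sol$alpha, b = sol$b, y = as.integer(y))
}

#' Train a multiclass RBF-kernel SVM
#'
#' One-vs-one C-support-vector classification with a Gaussian radial
#' basis kernel `exp(-g * ||x - x'||^2)`; the three pairwise machines vote
#' and ties resolve to the smallest class code. The dual problems are
#' solved by sequential minimal optimization.
#'
#' @param x a `spectrum_table` or samples x variables matrix.
#' @param label origin codes 0:2.
#' @param C penalty parameter (> 0).
#' @param gamma RBF width parameter g (> 0).
#' @return an `svm_model`.
#' @export
svm_fit <- function(x, label = NULL, C = 100, gamma = 1) {
  if (inherits(x, "spectrum_table")) {
    label <- label %||% x$label
    x <- x$spectra
  }
  X <- as.matrix(x)
  if (C <= 0 || gamma <= 0)
    hsi_abort("C and gamma must be positive", "hsi_invalid_argument")
  classes <- sort(unique(label))
  K <- rbf_kernel(dist2(X), gamma)
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  machines <- lapply(pairs, function(pr) {
    sel <- label %in% pr
    yb <- ifelse(label[sel] == pr[1], 1L, -1L)
    m <- svc_binary(K[sel, sel, drop = FALSE], yb, C)
    m$sel <- which(sel); m$pair <- pr
    m
  })
  structure(list(machines = machines, X = X, label = label,
                 C = C, gamma = gamma, classes = classes),
            class = "svm_model")
}

#' @rdname svm_fit
#' @param model an `svm_model`.
#' @export
svm_predict <- function(model, x) {
  ids <- NULL
  if (inherits(x, "spectrum_table")) { ids <- x$sample_id; x <- x$spectra }
  Xn <- as.matrix(x)
  K <- rbf_kernel(dist2(Xn, model$X), model$gamma)
  votes <- matrix(0L, nrow(Xn), length(model$classes))
  colnames(votes) <- model$classes
  for (m in model$machines) {
    f <- K[, m$sel, drop = FALSE] %*% (m$alpha * m$y) + m$b
    win <- ifelse(f >= 0, m$pair[1], m$pair[2])
    for (cl in m$pair)
      votes[, as.character(cl)] <- votes[, as.character(cl)] + (win == cl)
  }
  lab <- model$classes[max.col(votes, ties.method = "first")]
  structure(list(label = as.integer(lab), scores = votes,
                 sample_id = ids %||% seq_len(nrow(Xn))),
            class = "prediction")
}

stratified_folds <- function(label, k, seed) {
  with_seed(seed, {
    fold <- integer(length(label))
    for (cl in unique(label)) {
      idx <- sample(which(label == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Grid search of (C, g) by stratified cross-validation
#'
#' Exhaustive search over integer powers of ten, by default
#' 10^-8 ... 10^8 on both axes (a 17 x 17 grid), scored by mean accuracy
#' over stratified 5-fold cross-validation. Ties break toward the
#' smallest C, then the smallest g. The squared-distance matrix is
#' computed once and re-exponentiated per gamma.
#'
#' @param x a `spectrum_table` or matrix.
#' @param label origin codes.
#' @param cost_grid,gamma_grid candidate values (default `10^(-8:8)`).
#' @param cv_folds folds (default 5); every class must have at least
#'   `cv_folds` samples so each fold sees all classes.
#' @param seed fold-assignment seed.
#' @return list with `C`, `gamma`, `cv_accuracy`, and the full
#'   `accuracy_grid` (gamma x cost).
#' @export
svm_grid_search <- function(x, label = NULL, cost_grid = 10^(-8:8),
                            gamma_grid = 10^(-8:8), cv_folds = 5L,
                            seed = 1L) {
  if (inherits(x, "spectrum_table")) {
    label <- label %||% x$label
    x <- x$spectra
  }
  X <- as.matrix(x)
  tab <- table(label)
  if (any(tab < cv_folds))
    hsi_abort(sprintf(
      "stratification impossible: smallest class has %d samples for %d folds",
      min(tab), cv_folds), "hsi_stratification_error")
  fold <- stratified_folds(label, cv_folds, seed)
  for (f in seq_len(cv_folds))
    if (length(unique(label[fold != f])) < length(unique(label)))
      hsi_abort(sprintf("fold %d is missing a class", f),
                "hsi_stratification_error")
  D2 <- dist2(X)
  acc <- matrix(0, length(gamma_grid), length(cost_grid),
                dimnames = list(gamma = format(gamma_grid, scientific = TRUE),
                                cost = format(cost_grid, scientific = TRUE)))
  classes <- sort(unique(label))
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  for (gi in seq_along(gamma_grid)) {
    K <- rbf_kernel(D2, gamma_grid[gi])
    for (ci in seq_along(cost_grid)) {
      fold_acc <- numeric(cv_folds)
      for (f in seq_len(cv_folds)) {
        tr <- which(fold != f); te <- which(fold == f)
        votes <- matrix(0L, length(te), length(classes))
        for (pr in pairs) {
          sel <- tr[label[tr] %in% pr]
          yb <- ifelse(label[sel] == pr[1], 1L, -1L)
          m <- svc_binary(K[sel, sel, drop = FALSE], yb, cost_grid[ci])
          fte <- K[te, sel, drop = FALSE] %*% (m$alpha * yb) + m$b
          win <- ifelse(fte >= 0, pr[1], pr[2])
          for (cl in pr) {
            j <- match(cl, classes)
            votes[, j] <- votes[, j] + (win == cl)
          }
        }
        pred <- classes[max.col(votes, ties.method = "first")]
        fold_acc[f] <- mean(pred == label[te])
      }
      acc[gi, ci] <- mean(fold_acc)
    }
  }
  best <- which(acc == max(acc), arr.ind = TRUE)
  # ties: smallest C, then smallest g
  best <- best[order(best[, 2], best[, 1]), , drop = FALSE][1L, ]
  list(C = cost_grid[best[2]], gamma = gamma_grid[best[1]],
       cv_accuracy = max(acc), accuracy_grid = acc)
}
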