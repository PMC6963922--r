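test_that("PCA matches a brute-force eigendecomposition", {
  set.seed(11)
  X <- matrix(rnorm(6 * 4), 6, 4)
  p <- pca_fit(X, 4)
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  sc <- Xc %*% ev$vectors
  expect_lt(max(abs(abs(p$scores) - abs(sc[, 1:4]))), 1e-8)
  expect_equal(p$explained_variance, ev$values[1:4] / sum(ev$values),
               tolerance = 1e-10)
  expect_lt(max(abs(colMeans(p$scores))), 1e-10)
  # reconstruction with all components reproduces the centered data
  expect_equal(p$scores %*% t(p$loadings), Xc, tolerance = 1e-8)
})

test_that("PCA handles rank deficiency and degenerate directions", {
  v <- rnorm(5)
  X <- outer(seq_len(8), v) # rank 1
  p <- suppressWarnings(pca_fit(X, 3))
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-12)
  expect_warning(pca_fit(X, 3), "rank")
  expect_error(pca_fit(matrix(0, 3, 2), 5), class = "hsi_invalid_argument")
})

test_that("full-rank PLS-DA equals least squares onto the dummy matrix", {
  set.seed(12)
  X <- matrix(rnorm(20 * 10), 20, 10)
  y <- rep(0:2, length.out = 20)
  m <- plsda_fit(X, y, n_lv = 10)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(oleasterHSI:::dummy_code(y), 2,
              colMeans(oleasterHSI:::dummy_code(y)))
  expect_lt(max(abs(m$coefficients - qr.solve(Xc, Yc))), 1e-8)
})

test_that("PLS-DA separates simple class geometries", {
  # two linearly separable Gaussian clouds in 2-D, one latent variable
  set.seed(13)
  X <- rbind(matrix(rnorm(40, 0, 0.5), 20, 2),
             matrix(rnorm(40, 5, 0.5), 20, 2))
  y <- rep(c(0L, 1L), each = 20)
  m <- plsda_fit(X, y, n_lv = 1)
  expect_equal(mean(plsda_predict(m, X)$label == y), 1)

  # dummy-coding convention: Gansu 001, Ningxia 010, Xinjiang 100
  expect_equal(oleasterHSI:::dummy_code(c(0L, 1L, 2L)),
               matrix(c(0, 0, 1, 0, 1, 0, 1, 0, 0), 3, 3,
                      dimnames = list(NULL, c("100", "010", "001"))))

  # single-variable X equal to a dummy column: regression recovers it
  y3 <- rep(0:2, each = 5)
  xd <- oleasterHSI:::dummy_code(y3)[, 3, drop = FALSE]
  m3 <- plsda_fit(xd + 0, y3, n_lv = 1)
  pred <- plsda_predict(m3, xd)
  expect_lt(max(abs(pred$scores[, 3] - xd[, 1])), 1e-8)
})

test_that("PLS-DA beats the best single-threshold rule on clean spectra", {
  tb <- demo_table()
  m <- plsda_fit(tb, n_lv = 2)
  acc_pls <- mean(plsda_predict(m, tb)$label == tb$label)
  # brute-force oracle: best accuracy of any one-variable, one-threshold,
  # three-way ordered rule
  perms <- list(c(0L, 1L, 2L), c(0L, 2L, 1L), c(1L, 0L, 2L),
                c(1L, 2L, 0L), c(2L, 0L, 1L), c(2L, 1L, 0L))
  best <- 0
  for (j in seq_len(ncol(tb$spectra))) {
    v <- tb$spectra[, j]
    cuts <- unique(quantile(v, seq(0, 1, by = 0.05), names = FALSE))
    for (perm in perms) {
      for (a in cuts) for (b in cuts[cuts >= a]) {
        pred <- ifelse(v <= a, perm[1], ifelse(v <= b, perm[2], perm[3]))
        acc <- mean(pred == tb$label)
        if (acc > best) best <- acc
      }
    }
  }
  expect_gte(acc_pls, best)
})

test_that("latent-variable count is chosen by leave-one-out accuracy", {
  set.seed(14)
  X <- rbind(matrix(rnorm(30, 0, 0.3), 15, 2),
             matrix(rnorm(30, 4, 0.3), 15, 2),
             matrix(rnorm(30, 8, 0.3), 15, 2))
  X[31:45, 1] <- rnorm(15, 0, 0.3) # class 2 at (0, 8): triangle geometry
  y <- rep(0:2, each = 15)
  sel <- plsda_select_lv(X, y, max_lv = 2)
  expect_lte(sel$n_lv, 3)
  expect_equal(max(sel$loo_accuracy), 1)

  sel1 <- plsda_select_lv(X, y, max_lv = 1)
  expect_identical(sel1$n_lv, 1L)
})

test_that("PLS-DA validates rank and class presence", {
  set.seed(15)
  X <- matrix(rnorm(12 * 3), 12, 3)
  y <- rep(0:2, each = 4)
  err <- tryCatch(plsda_fit(X, y, n_lv = 10), error = function(e) e)
  expect_s3_class(err, "hsi_rank_error")
  expect_match(conditionMessage(err), "3")
  expect_error(plsda_fit(X, rep(0L, 12), n_lv = 1),
               class = "hsi_invalid_argument")
})
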