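# Activations for the 1-D conv stack are stored as (n * positions) x
# channels matrices with samples varying fastest, so im2col, pooling and
# flattening are pure index arithmetic.

conv_rows <- function(n, P_out, m) {
  # rows of (sample s, position p + m) for p = 1..P_out, samples fastest
  rep((seq_len(P_out) + m - 1L) * n, each = n) + rep(seq_len(n), P_out)
}

conv_fwd <- function(A, n, P_in, W, b) {
  P_out <- P_in - 2L
  C_in <- ncol(A)
  patch <- cbind(A[conv_rows(n, P_out, 0L), , drop = FALSE],
                 A[conv_rows(n, P_out, 1L), , drop = FALSE],
                 A[conv_rows(n, P_out, 2L), , drop = FALSE])
  Z <- sweep(patch %*% W, 2L, b, `+`)
  list(Z = Z, patch = patch, P_out = P_out, C_in = C_in, P_in = P_in)
}

conv_bwd <- function(dZ, cache, n, W) {
  dW <- crossprod(cache$patch, dZ)
  db <- colSums(dZ)
  dP <- dZ %*% t(W)
  dA <- matrix(0, n * cache$P_in, cache$C_in)
  for (m in 0:2) {
    cols <- m * cache$C_in + seq_len(cache$C_in)
    idx <- conv_rows(n, cache$P_out, m)
    dA[idx, ] <- dA[idx, ] + dP[, cols, drop = FALSE]
  }
  list(dA = dA, dW = dW, db = db)
}

pool_fwd <- function(A, n, P_in) {
  P_out <- P_in %/% 2L
  # rows of positions 1,3,5,... (i1) and 2,4,6,... (i2)
  i1 <- rep((2L * seq_len(P_out) - 2L) * n, each = n) + rep(seq_len(n), P_out)
  i2 <- i1 + n
  A1 <- A[i1, , drop = FALSE]; A2 <- A[i2, , drop = FALSE]
  mask <- A1 >= A2
  list(M = pmax(A1, A2), mask = mask, i1 = i1, i2 = i2,
       P_in = P_in, P_out = P_out)
}

pool_bwd <- function(dM, cache, n, C) {
  dA <- matrix(0, n * cache$P_in, C)
  dA[cache$i1, ] <- dM * cache$mask
  dA[cache$i2, ] <- dM * (1 - cache$mask)
  dA
}

bn_fwd <- function(X, gamma, beta, run_m, run_v, train, momentum = 0.9,
                   eps = 1e-5) {
  if (train) {
    mu <- colMeans(X)
    Xc <- sweep(X, 2L, mu)
    v <- colMeans(Xc^2)
    run_m <- momentum * run_m + (1 - momentum) * mu
    run_v <- momentum * run_v + (1 - momentum) * v
  } else {
    mu <- run_m; v <- run_v
    Xc <- sweep(X, 2L, mu)
  }
  invstd <- 1 / sqrt(v + eps)
  Xhat <- sweep(Xc, 2L, invstd, `*`)
  Y <- sweep(sweep(Xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(Y = Y, Xhat = Xhat, invstd = invstd, run_m = run_m, run_v = run_v)
}

bn_bwd <- function(dY, cache, gamma) {
  N <- nrow(dY)
  dgamma <- colSums(dY * cache$Xhat)
  dbeta <- colSums(dY)
  dXhat <- sweep(dY, 2L, gamma, `*`)
  s1 <- colSums(dXhat)
  s2 <- colSums(dXhat * cache$Xhat)
  dX <- sweep(dXhat, 2L, s1 / N) - sweep(cache$Xhat, 2L, s2 / N, `*`)
  dX <- sweep(dX, 2L, cache$invstd, `*`)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

he_uniform <- function(nrow_, ncol_, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(runif(nrow_ * ncol_, -lim, lim), nrow_, ncol_)
}

#' Specification of the 1-D convolutional network
#'
#' Two Conv1D blocks (64 then 32 kernels of size 3, stride 1, no padding,
#' each followed by ReLU, max-pooling of size/stride 2 and
#' batch-normalization), then dense layers of 512, 128 and 3 units (the
#' first two ReLU + batch-normalized) with a softmax output. Trained by
#' minimizing softmax cross-entropy with stochastic gradient descent
#' (classical momentum 0.9), learning rate 0.0005, batch size 400, 400
#' epochs by default.
#'
#' @param channels conv kernel counts.
#' @param dense hidden dense widths.
#' @param learning_rate,momentum,batch_size,epochs SGD settings.
#' @param seed RNG seed for initialization and shuffling.
#' @return a `cnn_spec` list.
#' @export
cnn_spec <- function(channels = c(64L, 32L), dense = c(512L, 128L),
                     learning_rate = 5e-4, momentum = 0.9,
                     batch_size = 400L, epochs = 400L, seed = 1L) {
  structure(list(channels = as.integer(channels), dense = as.integer(dense),
                 learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "cnn_spec")
}

#' Layer-length arithmetic and network construction
#'
#' With no padding, each conv shortens the sequence by 2 and each pool
#' halves it (floor), so the input must be at least 11 long for the
#' flattened width to be positive.
#'
#' @param spec a [cnn_spec()].
#' @param input_length number of wavelengths fed to the network.
#' @return a `cnn_model` with initialized parameters and a `shapes` list
#'   (`conv1`, `pool1`, `conv2`, `pool2`, `flatten`).
#' @export
cnn_build <- function(spec, input_length) {
  L0 <- as.integer(input_length)
  L1 <- L0 - 2L; P1 <- L1 %/% 2L; L2 <- P1 - 2L; P2 <- L2 %/% 2L
  if (L0 < 11L || P2 < 1L)
    hsi_abort(sprintf(
      "input length %d too short: conv %d -> pool %d -> conv %d -> pool %d (need >= 11)",
      L0, L1, P1, L2, P2), "hsi_architecture_error")
  ch <- spec$channels; dn <- spec$dense
  flat <- P2 * ch[2]
  params <- with_seed(derive_seed(spec$seed, 31L), list(
    W1 = he_uniform(3L, ch[1], 3L), b1 = numeric(ch[1]),
    g1 = rep(1, ch[1]), be1 = numeric(ch[1]),
    W2 = he_uniform(3L * ch[1], ch[2], 3L * ch[1]), b2 = numeric(ch[2]),
    g2 = rep(1, ch[2]), be2 = numeric(ch[2]),
    Wf1 = he_uniform(flat, dn[1], flat), bf1 = numeric(dn[1]),
    g3 = rep(1, dn[1]), be3 = numeric(dn[1]),
    Wf2 = he_uniform(dn[1], dn[2], dn[1]), bf2 = numeric(dn[2]),
    g4 = rep(1, dn[2]), be4 = numeric(dn[2]),
    Wf3 = he_uniform(dn[2], 3L, dn[2]), bf3 = numeric(3L)))
  running <- list(rm1 = numeric(ch[1]), rv1 = rep(1, ch[1]),
                  rm2 = numeric(ch[2]), rv2 = rep(1, ch[2]),
                  rm3 = numeric(dn[1]), rv3 = rep(1, dn[1]),
                  rm4 = numeric(dn[2]), rv4 = rep(1, dn[2]))
  structure(list(spec = spec, input_length = L0,
                 shapes = list(conv1 = L1, pool1 = P1, conv2 = L2,
                               pool2 = P2, flatten = flat),
                 params = params, running = running,
                 x_center = NULL, x_scale = NULL, history = NULL),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  s <- x$shapes
  cat(sprintf(
    "<cnn_model> input %d -> conv %dx%d -> pool %d -> conv %dx%d -> pool %d -> flatten %d -> %s -> 3\n",
    x$input_length, s$conv1, x$spec$channels[1], s$pool1, s$conv2,
    x$spec$channels[2], s$pool2, s$flatten,
    paste(x$spec$dense, collapse = " -> ")))
  invisible(x)
}

cnn_forward <- function(model, X, train = FALSE) {
  p <- model$params; r <- model$running
  n <- nrow(X); sh <- model$shapes
  A0 <- matrix(as.vector(X), n * model$input_length, 1L)
  c1 <- conv_fwd(A0, n, model$input_length, p$W1, p$b1)
  r1 <- pmax(c1$Z, 0)
  pl1 <- pool_fwd(r1, n, sh$conv1)
  b1 <- bn_fwd(pl1$M, p$g1, p$be1, r$rm1, r$rv1, train)
  c2 <- conv_fwd(b1$Y, n, sh$pool1, p$W2, p$b2)
  r2 <- pmax(c2$Z, 0)
  pl2 <- pool_fwd(r2, n, sh$conv2)
  b2 <- bn_fwd(pl2$M, p$g2, p$be2, r$rm2, r$rv2, train)
  Fm <- b2$Y; dim(Fm) <- c(n, sh$flatten)
  z3 <- sweep(Fm %*% p$Wf1, 2L, p$bf1, `+`)
  r3 <- pmax(z3, 0)
  b3 <- bn_fwd(r3, p$g3, p$be3, r$rm3, r$rv3, train)
  z4 <- sweep(b3$Y %*% p$Wf2, 2L, p$bf2, `+`)
  r4 <- pmax(z4, 0)
  b4 <- bn_fwd(r4, p$g4, p$be4, r$rm4, r$rv4, train)
  logits <- sweep(b4$Y %*% p$Wf3, 2L, p$bf3, `+`)
  running <- list(rm1 = b1$run_m, rv1 = b1$run_v, rm2 = b2$run_m,
                  rv2 = b2$run_v, rm3 = b3$run_m, rv3 = b3$run_v,
                  rm4 = b4$run_m, rv4 = b4$run_v)
  list(logits = logits, running = running,
       cache = list(A0 = A0, c1 = c1, r1 = r1, pl1 = pl1, b1 = b1,
                    c2 = c2, r2 = r2, pl2 = pl2, b2 = b2, Fm = Fm,
                    z3 = z3, r3 = r3, b3 = b3, z4 = z4, r4 = r4, b4 = b4,
                    n = n))
}

softmax <- function(L) {
  e <- exp(L - apply(L, 1L, max))
  e / rowSums(e)
}

cnn_loss_grads <- function(model, X, y) {
  fw <- cnn_forward(model, X, train = TRUE)
  n <- nrow(X); p <- model$params; sh <- model$shapes
  probs <- softmax(fw$logits)
  loss <- -mean(log(pmax(probs[cbind(seq_len(n), y + 1L)], 1e-300)))
  dL <- probs
  dL[cbind(seq_len(n), y + 1L)] <- dL[cbind(seq_len(n), y + 1L)] - 1
  dL <- dL / n
  ca <- fw$cache
  g <- list()
  g$Wf3 <- crossprod(ca$b4$Y, dL); g$bf3 <- colSums(dL)
  d <- dL %*% t(p$Wf3)
  bb <- bn_bwd(d, ca$b4, p$g4); g$g4 <- bb$dgamma; g$be4 <- bb$dbeta
  d <- bb$dX * (ca$z4 > 0)
  g$Wf2 <- crossprod(ca$b3$Y, d); g$bf2 <- colSums(d)
  d <- d %*% t(p$Wf2)
  bb <- bn_bwd(d, ca$b3, p$g3); g$g3 <- bb$dgamma; g$be3 <- bb$dbeta
  d <- bb$dX * (ca$z3 > 0)
  g$Wf1 <- crossprod(ca$Fm, d); g$bf1 <- colSums(d)
  d <- d %*% t(p$Wf1)
  dim(d) <- c(n * sh$pool2, model$spec$channels[2])
  bb <- bn_bwd(d, ca$b2, p$g2); g$g2 <- bb$dgamma; g$be2 <- bb$dbeta
  d <- pool_bwd(bb$dX, ca$pl2, n, model$spec$channels[2])
  d <- d * (ca$c2$Z > 0)
  cb <- conv_bwd(d, ca$c2, n, p$W2); g$W2 <- cb$dW; g$b2 <- cb$db
  bb <- bn_bwd(cb$dA, ca$b1, p$g1); g$g1 <- bb$dgamma; g$be1 <- bb$dbeta
  d <- pool_bwd(bb$dX, ca$pl1, n, model$spec$channels[1])
  d <- d * (ca$c1$Z > 0)
  cb <- conv_bwd(d, ca$c1, n, p$W1); g$W1 <- cb$dW; g$b1 <- cb$db
  list(loss = loss, grads = g, running = fw$running)
}

standardize_apply <- function(model, X) {
  sweep(sweep(as.matrix(X), 2L, model$x_center), 2L, model$x_scale, `/`)
}

#' Train the CNN
#'
#' Minimizes softmax cross-entropy by mini-batch SGD with momentum.
#' Inputs are standardized per band with calibration statistics (stored in
#' the model). Validation accuracy is tracked every epoch and the
#' returned model carries the epoch-best parameters on the validation set.
#'
#' @param model a `cnn_model` from [cnn_build()].
#' @param x_cal,y_cal calibration spectra (`spectrum_table` or matrix) and
#'   labels.
#' @param x_val,y_val independent validation data for epoch selection.
#' @param epochs,batch_size optional overrides of the spec; a batch size
#'   exceeding the calibration size is clamped with a warning.
#' @param verbose print progress every 25 epochs.
#' @return the trained `cnn_model` (with `history`).
#' @export
cnn_train <- function(model, x_cal, y_cal = NULL, x_val, y_val = NULL,
                      epochs = NULL, batch_size = NULL, verbose = FALSE) {
  if (inherits(x_cal, "spectrum_table")) {
    y_cal <- y_cal %||% x_cal$label; x_cal <- x_cal$spectra
  }
  if (inherits(x_val, "spectrum_table")) {
    y_val <- y_val %||% x_val$label; x_val <- x_val$spectra
  }
  spec <- model$spec
  epochs <- epochs %||% spec$epochs
  bs <- batch_size %||% spec$batch_size
  n <- nrow(x_cal)
  if (bs > n) {
    warning(sprintf("batch size %d exceeds calibration size %d; clamping",
                    bs, n))
    bs <- n
  }
  model$x_center <- colMeans(x_cal)
  sdv <- apply(x_cal, 2L, sd)
  model$x_scale <- ifelse(sdv < 1e-12, 1, sdv)
  Xc <- standardize_apply(model, x_cal)
  Xv <- standardize_apply(model, x_val)
  vel <- lapply(model$params, function(w) w * 0)
  best <- list(acc = -Inf, vloss = Inf)
  hist_val <- hist_loss <- numeric(epochs)
  with_seed(derive_seed(spec$seed, 77L), {
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        lg <- cnn_loss_grads(model, Xc[idx, , drop = FALSE], y_cal[idx])
        model$running <- lg$running
        for (nm in names(model$params)) {
          vel[[nm]] <- spec$momentum * vel[[nm]] -
            spec$learning_rate * lg$grads[[nm]]
          model$params[[nm]] <- model$params[[nm]] + vel[[nm]]
        }
        ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
      }
      pv <- cnn_forward(model, Xv, train = FALSE)
      probs <- softmax(pv$logits)
      acc <- mean(max.col(probs, ties.method = "first") - 1L == y_val)
      vloss <- -mean(log(pmax(
        probs[cbind(seq_along(y_val), y_val + 1L)], 1e-300)))
      hist_val[ep] <- acc; hist_loss[ep] <- ep_loss / nb
      # epoch-best on validation: accuracy first, ties broken by lower
      # validation cross-entropy (guards against immature early epochs
      # that luck into a perfect score on a small validation set)
      if (acc > best$acc || (acc == best$acc && vloss < best$vloss))
        best <- list(acc = acc, vloss = vloss, params = model$params,
                     running = model$running, epoch = ep)
      if (verbose && ep %% 25L == 0L)
        message(sprintf("epoch %d: loss %.4f, val acc %.3f", ep,
                        ep_loss / nb, acc))
    }
  })
  model$params <- best$params
  model$running <- best$running
  model$history <- list(val_accuracy = hist_val, train_loss = hist_loss,
                        best_epoch = best$epoch, best_val_accuracy = best$acc)
  model
}

#' @rdname cnn_train
#' @param x new spectra (`spectrum_table` or matrix).
#' @export
cnn_predict <- function(model, x) {
  ids <- NULL
  if (inherits(x, "spectrum_table")) { ids <- x$sample_id; x <- x$spectra }
  if (is.null(model$x_center))
    hsi_abort("model has not been trained", "hsi_invalid_argument")
  X <- standardize_apply(model, x)
  fw <- cnn_forward(model, X, train = FALSE)
  probs <- softmax(fw$logits)
  structure(list(label = max.col(probs, ties.method = "first") - 1L,
                 scores = probs, sample_id = ids %||% seq_len(nrow(X))),
            class = "prediction")
}
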