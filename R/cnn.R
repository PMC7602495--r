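# Convolutional feature learners, written as explicit im2col forward /
# backward passes over base matrix ops. Two fixed architectures:
#   raw: per-axis 1D conv (16 kernels, length 25, "same" padding) -> ReLU ->
#        max-pool 4 -> features (3*37*16 = 1776) -> dense 128/64/32/1
#   tnt: 2D conv 32@3x9 (valid) -> ReLU -> 2D conv 16@3x5 (valid) -> ReLU ->
#        features (5*116*16 = 9280) -> dense 128/32/1
# Kernel counts/sizes balance parameter count against the data volumes the
# synthetic cohorts provide.

# ---- im2col helpers ---------------------------------------------------------

# 1D, zero-padded "same": signals = m x len matrix -> (m*len) x klen matrix,
# rows ordered signal-fastest then time
im2col_1d_same <- function(signals, klen) {
  m <- nrow(signals); len <- ncol(signals)
  pad <- (klen - 1L) %/% 2L
  P <- cbind(matrix(0, m, pad), signals, matrix(0, m, pad))
  out <- matrix(0, m * len, klen)
  for (k in seq_len(klen)) out[, k] <- as.vector(P[, k:(k + len - 1L)])
  out
}

# 2D valid: X is n x H x W x C array -> (n*oh*ow) x (kh*kw*C), rows ordered
# (sample, out-row, out-col) with sample fastest; cols ordered (dr, dc, ch)
im2col_2d <- function(X, kh, kw) {
  d <- dim(X); n <- d[1L]; H <- d[2L]; W <- d[3L]; C <- d[4L]
  oh <- H - kh + 1L; ow <- W - kw + 1L
  out <- matrix(0, n * oh * ow, kh * kw * C)
  col <- 0L
  for (ch in seq_len(C)) for (dc in seq_len(kw)) for (dr in seq_len(kh)) {
    col <- col + 1L
    out[, col] <- as.vector(X[, dr:(dr + oh - 1L), dc:(dc + ow - 1L), ch])
  }
  out
}

# scatter-add transpose of im2col_2d (gradient w.r.t. the conv input)
col2im_2d <- function(dcol, n, H, W, C, kh, kw) {
  oh <- H - kh + 1L; ow <- W - kw + 1L
  dX <- array(0, dim = c(n, H, W, C))
  col <- 0L
  for (ch in seq_len(C)) for (dc in seq_len(kw)) for (dr in seq_len(kh)) {
    col <- col + 1L
    dX[, dr:(dr + oh - 1L), dc:(dc + ow - 1L), ch] <-
      dX[, dr:(dr + oh - 1L), dc:(dc + ow - 1L), ch] +
      array(dcol[, col], dim = c(n, oh, ow))
  }
  dX
}

# ---- raw architecture -------------------------------------------------------

RAW_KLEN <- 25L; RAW_NK <- 16L; RAW_POOL <- 4L; RAW_T <- 37L  # 150 %/% 4

# X: n x 3 x 150; returns features n x 1776 plus caches for backprop
cnn_raw_forward <- function(conv, X) {
  n <- dim(X)[1L]
  sig <- rbind(X[, 1L, ], X[, 2L, ], X[, 3L, ])          # (3n) x 150, axis-blocked
  col <- im2col_1d_same(sig, RAW_KLEN)
  Z <- sweep(col %*% conv$K, 2L, conv$b, `+`)            # (3n*150) x 16
  A <- relu(Z)
  m <- 3L * n
  keep <- RAW_T * RAW_POOL
  A3 <- array(A, dim = c(m, 150L, RAW_NK))
  A4 <- array(A3[, seq_len(keep), ], dim = c(m, RAW_POOL, RAW_T, RAW_NK))
  pooled <- A4[, 1L, , ]
  amax <- array(1L, dim = dim(pooled))
  for (j in 2:RAW_POOL) {
    sj <- A4[, j, , ]
    upd <- sj > pooled
    pooled[upd] <- sj[upd]
    amax[upd] <- j
  }
  feat <- cbind(matrix(pooled[seq_len(n), , ], n, RAW_T * RAW_NK),
                matrix(pooled[n + seq_len(n), , ], n, RAW_T * RAW_NK),
                matrix(pooled[2L * n + seq_len(n), , ], n, RAW_T * RAW_NK))
  list(feat = feat, col = col, Z = Z, amax = amax, n = n)
}

cnn_raw_backward <- function(conv, cache, dfeat) {
  n <- cache$n
  m <- 3L * n
  dpool <- array(0, dim = c(m, RAW_T, RAW_NK))
  for (a in 1:3) {
    dpool[(a - 1L) * n + seq_len(n), , ] <-
      array(dfeat[, (a - 1L) * RAW_T * RAW_NK + seq_len(RAW_T * RAW_NK)],
            dim = c(n, RAW_T, RAW_NK))
  }
  # route gradient to the argmax position within each pool group
  S <- as.vector(slice.index(dpool, 1L))
  G <- as.vector(slice.index(dpool, 2L))
  Fm <- as.vector(slice.index(dpool, 3L))
  keep <- RAW_T * RAW_POOL
  lin <- S + (as.vector(cache$amax) - 1L) * m + (G - 1L) * m * RAW_POOL +
    (Fm - 1L) * m * keep
  dkeep <- numeric(m * keep * RAW_NK)
  dkeep[lin] <- as.vector(dpool)
  dA3 <- array(0, dim = c(m, 150L, RAW_NK))
  dA3[, seq_len(keep), ] <- array(dkeep, dim = c(m, keep, RAW_NK))
  dZ <- matrix(dA3, m * 150L, RAW_NK) * (cache$Z > 0)
  list(dK = crossprod(cache$col, dZ), db = colSums(dZ))
}

# ---- tnt architecture -------------------------------------------------------

TNT_K1 <- c(3L, 9L, 1L, 32L)   # kh, kw, in-ch, out-ch
TNT_K2 <- c(3L, 5L, 32L, 16L)
TNT_O1 <- c(7L, 120L)
TNT_O2 <- c(5L, 116L)

cnn_tnt_forward <- function(conv, X) {
  n <- dim(X)[1L]
  X4 <- array(X, dim = c(n, 9L, 128L, 1L))
  col1 <- im2col_2d(X4, TNT_K1[1L], TNT_K1[2L])
  Z1 <- sweep(col1 %*% conv$K1, 2L, conv$b1, `+`)
  A1 <- relu(Z1)
  A1a <- array(A1, dim = c(n, TNT_O1[1L], TNT_O1[2L], TNT_K1[4L]))
  col2 <- im2col_2d(A1a, TNT_K2[1L], TNT_K2[2L])
  Z2 <- sweep(col2 %*% conv$K2, 2L, conv$b2, `+`)
  A2 <- relu(Z2)
  feat <- matrix(array(A2, dim = c(n, TNT_O2[1L] * TNT_O2[2L] * TNT_K2[4L])),
                 n, TNT_O2[1L] * TNT_O2[2L] * TNT_K2[4L])
  list(feat = feat, col1 = col1, Z1 = Z1, col2 = col2, Z2 = Z2, n = n)
}

cnn_tnt_backward <- function(conv, cache, dfeat) {
  n <- cache$n
  dA2 <- matrix(array(dfeat, dim = c(n * TNT_O2[1L] * TNT_O2[2L], TNT_K2[4L])),
                n * TNT_O2[1L] * TNT_O2[2L], TNT_K2[4L])
  dZ2 <- dA2 * (cache$Z2 > 0)
  dK2 <- crossprod(cache$col2, dZ2)
  db2 <- colSums(dZ2)
  dcol2 <- dZ2 %*% t(conv$K2)
  dA1 <- col2im_2d(dcol2, n, TNT_O1[1L], TNT_O1[2L], TNT_K1[4L],
                   TNT_K2[1L], TNT_K2[2L])
  dZ1 <- matrix(dA1, n * TNT_O1[1L] * TNT_O1[2L], TNT_K1[4L]) * (cache$Z1 > 0)
  list(dK1 = crossprod(cache$col1, dZ1), db1 = colSums(dZ1),
       dK2 = dK2, db2 = db2)
}

# ---- autoencoder pre-training of conv kernels -------------------------------

# three-layer autoencoder (input, ReLU encoding, linear decoding) on patch
# samples; the encoder weights initialize the convolution kernels
pretrain_kernels <- function(patches, n_units, epochs = 10L, batch = 50L,
                             lr = 1e-3) {
  d <- ncol(patches)
  W1 <- glorot_mat(d, n_units); b1 <- rep(0, n_units)
  W2 <- glorot_mat(n_units, d); b2 <- rep(0, d)
  opt <- rmsprop_new()
  for (ep in seq_len(epochs)) {
    ord <- sample(nrow(patches))
    for (b0 in seq(1L, length(ord), by = batch)) {
      bi <- ord[b0:min(b0 + batch - 1L, length(ord))]
      Xb <- patches[bi, , drop = FALSE]
      Z1 <- sweep(Xb %*% W1, 2L, b1, `+`); A1 <- relu(Z1)
      out <- sweep(A1 %*% W2, 2L, b2, `+`)
      dout <- 2 * (out - Xb) / length(bi)
      dW2 <- crossprod(A1, dout); db2 <- colSums(dout)
      dA1 <- dout %*% t(W2); dZ1 <- dA1 * (Z1 > 0)
      dW1 <- crossprod(Xb, dZ1); db1 <- colSums(dZ1)
      W1 <- rmsprop_step(opt, "W1", W1, dW1, lr)
      b1 <- rmsprop_step(opt, "b1", b1, db1, lr)
      W2 <- rmsprop_step(opt, "W2", W2, dW2, lr)
      b2 <- rmsprop_step(opt, "b2", b2, db2, lr)
    }
  }
  list(W = W1, b = b1)
}

sample_rows <- function(m, k) m[sample(nrow(m), min(k, nrow(m))), , drop = FALSE]

# ---- training ---------------------------------------------------------------

cnn_forward_scores <- function(model, X, masks = NULL, feat_mask = NULL) {
  cf <- if (model$arch == "raw") cnn_raw_forward(model$conv, X)
        else cnn_tnt_forward(model$conv, X)
  feat <- cf$feat
  if (!is.null(feat_mask)) feat <- feat * feat_mask
  fwd <- dense_forward(model$head, feat, masks)
  list(cf = cf, fwd = fwd,
       scores = as.vector(fwd$as[[length(model$head$layers) + 1L]]))
}

# one rmsprop step on a minibatch (conv + dense head)
cnn_train_batch <- function(model, X, y, opt, dropout = 0.2, lr = 1e-3) {
  nb <- dim(X)[1L]
  feat_mask <- matrix(stats::rbinom(nb * model$head$sizes[1L], 1L, 1 - dropout) /
                        (1 - dropout), nb, model$head$sizes[1L])
  masks <- make_masks(model$head, nb, dropout)
  fw <- cnn_forward_scores(model, X, masks, feat_mask)
  bk <- dense_backward(model$head, fw$fwd, y, masks)
  model$head <- net_apply_grads(model$head, bk$grads, opt, "h", lr)
  dfeat <- bk$d_input * feat_mask
  if (model$arch == "raw") {
    g <- cnn_raw_backward(model$conv, fw$cf, dfeat)
    model$conv$K <- rmsprop_step(opt, "cK", model$conv$K, g$dK, lr)
    model$conv$b <- rmsprop_step(opt, "cb", model$conv$b, g$db, lr)
  } else {
    g <- cnn_tnt_backward(model$conv, fw$cf, dfeat)
    model$conv$K1 <- rmsprop_step(opt, "cK1", model$conv$K1, g$dK1, lr)
    model$conv$b1 <- rmsprop_step(opt, "cb1", model$conv$b1, g$db1, lr)
    model$conv$K2 <- rmsprop_step(opt, "cK2", model$conv$K2, g$dK2, lr)
    model$conv$b2 <- rmsprop_step(opt, "cb2", model$conv$b2, g$db2, lr)
  }
  model
}

cnn_predict_scores <- function(model, X, chunk = 200L) {
  n <- dim(X)[1L]
  out <- numeric(n)
  for (i0 in seq(1L, n, by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, n)
    Xi <- if (model$arch == "raw") X[ii, , , drop = FALSE] else X[ii, , , drop = FALSE]
    out[ii] <- cnn_forward_scores(model, Xi)$scores
  }
  out
}

cnn_feature_dim <- function(arch) {
  if (arch == "raw") 3L * RAW_T * RAW_NK else prod(TNT_O2) * TNT_K2[4L]
}

train_cnn_core <- function(X, y, arch, subjects = NULL, max_epochs = 15L,
                           patience = 5L, ae_epochs = 10L, dropout = 0.2,
                           lr = 1e-3, batch = 50L, ae_patches = 4000L) {
  n <- dim(X)[1L]
  conv <- if (arch == "raw") {
    sig <- rbind(X[, 1L, ], X[, 2L, ], X[, 3L, ])
    pat <- sample_rows(im2col_1d_same(sig, RAW_KLEN), ae_patches)
    enc <- pretrain_kernels(pat, RAW_NK, epochs = ae_epochs)
    list(K = enc$W, b = enc$b)
  } else {
    sub <- sample(n, min(n, 200L))
    X4 <- array(X[sub, , , drop = FALSE], dim = c(length(sub), 9L, 128L, 1L))
    pat1 <- sample_rows(im2col_2d(X4, TNT_K1[1L], TNT_K1[2L]), ae_patches)
    enc1 <- pretrain_kernels(pat1, TNT_K1[4L], epochs = ae_epochs)
    A1 <- relu(sweep(im2col_2d(X4, TNT_K1[1L], TNT_K1[2L]) %*% enc1$W,
                     2L, enc1$b, `+`))
    A1a <- array(A1, dim = c(length(sub), TNT_O1[1L], TNT_O1[2L], TNT_K1[4L]))
    pat2 <- sample_rows(im2col_2d(A1a, TNT_K2[1L], TNT_K2[2L]), ae_patches)
    enc2 <- pretrain_kernels(pat2, TNT_K2[4L], epochs = ae_epochs)
    list(K1 = enc1$W, b1 = enc1$b, K2 = enc2$W, b2 = enc2$b)
  }
  hidden <- if (arch == "raw") c(128L, 64L, 32L) else c(128L, 32L)
  head <- dense_net_new(c(cnn_feature_dim(arch), hidden, 1L))
  model <- list(arch = arch, conv = conv, head = head)
  opt <- rmsprop_new()
  vi <- val_split_idx(y, subjects, 0.2)
  ti <- setdiff(seq_len(n), vi)
  best <- list(loss = Inf, model = model, epoch = 0L)
  stall <- 0L
  history <- numeric(0)
  for (ep in seq_len(max_epochs)) {
    ord <- sample(ti)
    for (b0 in seq(1L, length(ord), by = batch)) {
      bi <- ord[b0:min(b0 + batch - 1L, length(ord))]
      model <- cnn_train_batch(model, X[bi, , , drop = FALSE], y[bi], opt,
                               dropout, lr)
    }
    vloss <- bce_loss(cnn_predict_scores(model, X[vi, , , drop = FALSE]), y[vi])
    history <- c(history, vloss)
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, model = model, epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  c(best$model, list(epoch = best$epoch, history = history))
}

# conv-stage features (the "learned feature set"): max-pool output for raw,
# second conv output for tnt
cnn_extract_features <- function(model, X, chunk = 200L) {
  n <- dim(X)[1L]
  out <- matrix(0, n, cnn_feature_dim(model$arch))
  for (i0 in seq(1L, n, by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, n)
    cf <- if (model$arch == "raw") cnn_raw_forward(model$conv, X[ii, , , drop = FALSE])
          else cnn_tnt_forward(model$conv, X[ii, , , drop = FALSE])
    out[ii, ] <- cf$feat
  }
  out
}
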