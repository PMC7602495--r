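# Minimal feedforward network engine: dense ReLU layers with a sigmoid head,
# binary cross-entropy loss, rmsprop updates, inverted dropout, and
# validation-based epoch selection. Sized for the small nets this package
# uses (<= a few hundred thousand parameters), all in base matrix ops.

glorot_mat <- function(fan_in, fan_out) {
  l <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -l, l), fan_in, fan_out)
}

relu <- function(z) pmax(z, 0)

dense_net_new <- function(sizes) {
  n_lay <- length(sizes) - 1L
  layers <- vector("list", n_lay)
  for (i in seq_len(n_lay)) {
    layers[[i]] <- list(W = glorot_mat(sizes[i], sizes[i + 1L]),
                        b = rep(0, sizes[i + 1L]),
                        act = if (i == n_lay) "sigmoid" else "relu")
  }
  structure(list(layers = layers, sizes = sizes), class = "dense_net")
}

# forward pass; when training, `masks` holds inverted-dropout masks per
# hidden layer (same shape as that layer's activation)
dense_forward <- function(net, X, masks = NULL) {
  as <- list(X)
  zs <- list()
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    z <- sweep(as[[i]] %*% ly$W, 2L, ly$b, `+`)
    a <- if (ly$act == "relu") relu(z) else 1 / (1 + exp(-z))
    if (!is.null(masks) && i < length(net$layers)) a <- a * masks[[i]]
    zs[[i]] <- z
    as[[i + 1L]] <- a
  }
  list(zs = zs, as = as)
}

dense_predict <- function(net, X) {
  as.vector(dense_forward(net, X)$as[[length(net$layers) + 1L]])
}

# gradients for sigmoid + binary cross-entropy; returns per-layer dW/db and
# the gradient w.r.t. the input (for conv layers stacked underneath)
dense_backward <- function(net, fwd, y, masks = NULL) {
  n_lay <- length(net$layers)
  nb <- nrow(fwd$as[[1L]])
  out <- fwd$as[[n_lay + 1L]]
  delta <- (out - y) / nb           # d BCE / d z for the sigmoid head
  grads <- vector("list", n_lay)
  for (i in n_lay:1) {
    grads[[i]] <- list(dW = crossprod(fwd$as[[i]], delta),
                       db = colSums(delta))
    if (i > 1L) {
      delta <- delta %*% t(net$layers[[i]]$W)
      delta <- delta * (fwd$zs[[i - 1L]] > 0)
      if (!is.null(masks)) delta <- delta * masks[[i - 1L]]
    } else {
      delta <- delta %*% t(net$layers[[1L]]$W)
    }
  }
  list(grads = grads, d_input = delta)
}

rmsprop_new <- function() new.env(parent = emptyenv())

rmsprop_step <- function(state, key, param, grad, lr = 1e-3,
                         rho = 0.9, eps = 1e-8) {
  r <- if (is.null(state[[key]])) grad^2 * (1 - rho) else
    rho * state[[key]] + (1 - rho) * grad^2
  state[[key]] <- r
  param - lr * grad / (sqrt(r) + eps)
}

net_apply_grads <- function(net, grads, opt, prefix, lr = 1e-3) {
  for (i in seq_along(net$layers)) {
    net$layers[[i]]$W <- rmsprop_step(opt, paste0(prefix, "W", i),
                                      net$layers[[i]]$W, grads[[i]]$dW, lr)
    net$layers[[i]]$b <- rmsprop_step(opt, paste0(prefix, "b", i),
                                      net$layers[[i]]$b, grads[[i]]$db, lr)
  }
  net
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# stratified validation index: by subject when given, else by class
val_split_idx <- function(y, subjects = NULL, frac = 0.2) {
  n <- length(y)
  strata <- if (!is.null(subjects)) subjects else y
  idx <- integer(0)
  for (s in unique(strata)) {
    i <- which(strata == s)
    k <- max(1L, floor(length(i) * frac))
    idx <- c(idx, sample(i, k))
  }
  sort(idx)
}

make_masks <- function(net, nb, p = 0.2) {
  lapply(seq_len(length(net$layers) - 1L), function(i)
    matrix(stats::rbinom(nb * net$sizes[i + 1L], 1L, 1 - p) / (1 - p),
           nb, net$sizes[i + 1L]))
}

# full MLP training loop; returns the best-validation-epoch network
train_dense_net <- function(X, y, hidden = c(128L, 32L), subjects = NULL,
                            batch = 50L, dropout = 0.2, lr = 1e-3,
                            max_epochs = 30L, patience = 5L, val_frac = 0.2) {
  net <- dense_net_new(c(ncol(X), hidden, 1L))
  opt <- rmsprop_new()
  vi <- val_split_idx(y, subjects, val_frac)
  ti <- setdiff(seq_len(nrow(X)), vi)
  Xv <- X[vi, , drop = FALSE]; yv <- y[vi]
  Xt <- X[ti, , drop = FALSE]; yt <- y[ti]
  best <- list(loss = Inf, net = net, epoch = 0L)
  history <- numeric(0)
  stall <- 0L
  for (ep in seq_len(max_epochs)) {
    ord <- sample(length(yt))
    for (b0 in seq(1L, length(ord), by = batch)) {
      bi <- ord[b0:min(b0 + batch - 1L, length(ord))]
      masks <- if (dropout > 0) make_masks(net, length(bi), dropout) else NULL
      fwd <- dense_forward(net, Xt[bi, , drop = FALSE], masks)
      bk <- dense_backward(net, fwd, yt[bi], masks)
      net <- net_apply_grads(net, bk$grads, opt, "d", lr)
    }
    vloss <- bce_loss(dense_predict(net, Xv), yv)
    history <- c(history, vloss)
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, net = net, epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  list(net = best$net, epoch = best$epoch, val_loss = best$loss,
       history = history)
}
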