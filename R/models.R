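#' Train a supervised window classifier
#'
#' Two classifiers are supported: a random forest of 100 trees (baseline) and
#' a multi-layer perceptron with fully connected layers of 128, 32 and 1
#' units (ReLU, ReLU, sigmoid) trained with binary cross-entropy, rmsprop,
#' batch size 50 and dropout 0.2 after the hidden layers. The MLP's epoch
#' count is chosen on a validation subset (20% of training windows,
#' subject-stratified when `subjects` is given) with early stopping.
#' Training is deterministic given `seed`.
#'
#' @param X feature matrix (`n x d`), no NaN/Inf.
#' @param y binary labels (0/1); both classes must be present.
#' @param kind `"rf"` or `"mlp"`.
#' @param seed integer seed.
#' @param subjects optional per-row subject ids for the validation split.
#' @param max_epochs,patience MLP epoch-selection controls.
#' @return an object of class `tremor_model`.
#' @export
train_classifier <- function(X, y, kind = c("rf", "mlp"), seed = 1L,
                             subjects = NULL, max_epochs = 30L, patience = 5L) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (anyNA(X) || any(!is.finite(X))) stop("features contain NaN/Inf")
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  set.seed(seed)
  scaler <- NULL
  fit <- switch(kind,
    rf = randomForest::randomForest(x = X, y = factor(y, levels = c(0L, 1L)),
                                    ntree = 100L),
    mlp = {
      # z-score inputs on training statistics (stored for prediction)
      ctr <- colMeans(X)
      scl <- pmax(apply(X, 2L, stats::sd), 1e-8)
      scaler <- list(center = ctr, scale = scl)
      Xs <- scale(X, center = ctr, scale = scl)
      train_dense_net(Xs, y, hidden = c(128L, 32L), subjects = subjects,
                      max_epochs = max_epochs, patience = patience)
    })
  structure(list(kind = kind, fit = fit, d = ncol(X), scaler = scaler,
                 meta = list(seed = seed, n_train = nrow(X))),
            class = "tremor_model")
}

#' Train a convolutional feature-learner classifier
#'
#' `arch = "raw"` consumes raw windows (`n x 3 x 150`): one per-axis 1D
#' convolution (same padding), ReLU, max-pooling, then four dense layers with
#' a sigmoid head. `arch = "tnt"` consumes the stacked factorized spectra
#' (`n x 9 x 128`: total/tremor/non-tremor for each axis): two 2D
#' convolutions whose second output is the learned feature set, then a dense
#' head. Both train with binary cross-entropy, rmsprop, batch 50 and dropout
#' 0.2; convolution kernels are initialized from a three-layer autoencoder
#' fit on patches, remaining layers Glorot-uniform; the epoch count is chosen
#' on a validation subset.
#'
#' @param x input array (`n x 3 x 150` for raw, `n x 9 x 128` for tnt).
#' @param y binary labels.
#' @param arch `"raw"` or `"tnt"`.
#' @param seed integer seed.
#' @param subjects optional per-row subject ids for the validation split.
#' @param max_epochs,patience,ae_epochs training controls.
#' @return an object of class `tremor_model` (kind `cnn_raw` / `cnn_tnt`).
#' @export
train_cnn <- function(x, y, arch = c("raw", "tnt"), seed = 1L, subjects = NULL,
                      max_epochs = 15L, patience = 5L, ae_epochs = 10L) {
  arch <- match.arg(arch)
  y <- as.integer(y)
  d <- dim(x)
  want <- if (arch == "raw") c(3L, 150L) else c(9L, 128L)
  if (length(d) != 3L || d[2L] != want[1L] || d[3L] != want[2L])
    stop(sprintf("arch '%s' expects n x %d x %d input, got %s",
                 arch, want[1L], want[2L], paste(d, collapse = " x ")))
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  set.seed(seed)
  fit <- train_cnn_core(x, y, arch, subjects = subjects,
                        max_epochs = max_epochs, patience = patience,
                        ae_epochs = ae_epochs)
  structure(list(kind = paste0("cnn_", arch), fit = fit, d = want,
                 meta = list(seed = seed, n_train = d[1L],
                             feature_dim = cnn_feature_dim(arch))),
            class = "tremor_model")
}

#' Stack factorized spectra into CNN-T/NT input
#'
#' Rearranges an `ntf_result` into the `n x 9 x 128` array the tnt
#' architecture expects (rows: total, tremor, non-tremor for x, then y, z).
#'
#' @param ntf an `ntf_result`.
#' @return `n x 9 x 128` array.
#' @export
stack_tnt_input <- function(ntf) {
  n <- dim(ntf$spectra)[1L]
  out <- array(0, dim = c(n, 9L, 128L))
  r <- 0L
  for (a in 1:3) for (k in 1:3) {
    r <- r + 1L
    out[, r, ] <- ntf$spectra[, a, k, ]
  }
  out
}

#' Predict tremor scores
#'
#' Per-window pseudo-probabilities in \[0, 1\] (sigmoid output for the neural
#' models, tree-vote fraction for the forest).
#'
#' @param model a `tremor_model`.
#' @param inputs feature matrix or input array matching the model's contract.
#' @return numeric vector of scores in \[0, 1\].
#' @export
predict_scores <- function(model, inputs) {
  if (!inherits(model, "tremor_model")) stop("not a tremor_model")
  if (model$kind %in% c("rf", "mlp")) {
    X <- as.matrix(inputs)
    if (ncol(X) != model$d)
      stop(sprintf("model expects %d features, got %d", model$d, ncol(X)))
    if (model$kind == "rf")
      as.vector(stats::predict(model$fit, X, type = "prob")[, "1"])
    else
      dense_predict(model$fit$net,
                    scale(X, center = model$scaler$center,
                          scale = model$scaler$scale))
  } else {
    d <- dim(inputs)
    if (length(d) != 3L || d[2L] != model$d[1L] || d[3L] != model$d[2L])
      stop("input array does not match the model's contract")
    cnn_predict_scores(model$fit, inputs)
  }
}

#' Extract the learned CNN features
#'
#' The conv-stage output the architectures treat as their feature set
#' (max-pool output for raw: 1776 values; second conv output for tnt: 9280).
#'
#' @param model a cnn `tremor_model`.
#' @param inputs matching input array.
#' @return `n x feature_dim` matrix.
#' @export
cnn_features <- function(model, inputs) {
  if (!model$kind %in% c("cnn_raw", "cnn_tnt")) stop("not a cnn model")
  cnn_extract_features(model$fit, inputs)
}

#' @export
print.tremor_model <- function(x, ...) {
  cat(sprintf("<tremor_model> %s, trained on %d windows (seed %d)\n",
              x$kind, x$meta$n_train, x$meta$seed))
  invisible(x)
}
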