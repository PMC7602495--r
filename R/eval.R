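#' Leave-one-subject-out folds
#'
#' One fold per subject; the held-out subject contributes no training data.
#' Fold order follows sorted subject ids, so it is independent of input
#' ordering.
#'
#' @param subjects vector of subject ids (one per window, or unique ids).
#' @return list of folds, each a list with `test` (one id) and `train`
#'   (the remaining ids).
#' @export
loso_folds <- function(subjects) {
  ids <- sort(unique(as.character(subjects)))
  if (length(ids) < 2L) stop("LOSO needs at least 2 subjects")
  lapply(ids, function(s) list(test = s, train = setdiff(ids, s)))
}

#' ROC metrics: AUC and FPR at 0.90 TPR
#'
#' Empirical ROC by sliding the threshold over all distinct score values;
#' AUC by the trapezoidal rule (equivalently the Mann-Whitney statistic),
#' FPR at TPR = 0.90 by linear interpolation between adjacent ROC points.
#' Both metrics are invariant to strictly monotone transforms of the scores.
#'
#' @param scores numeric scores (higher = more tremor-like).
#' @param labels binary labels; both classes must be present.
#' @return list with `auc` and `fpr_at_090_tpr`.
#' @export
roc_metrics <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC metrics undefined: labels contain a single class")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # collapse tied scores into single ROC points
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1L - y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  k <- which(tpr >= 0.9)[1L]
  fpr09 <- if (tpr[k] == 0.9 || k == 1L) fpr[k] else {
    w <- (0.9 - tpr[k - 1L]) / (tpr[k] - tpr[k - 1L])
    fpr[k - 1L] + w * (fpr[k] - fpr[k - 1L])
  }
  list(auc = auc, fpr_at_090_tpr = fpr09)
}

#' Significance of an AUC difference (Hanley-McNeil)
#'
#' Standard error of each AUC from the Hanley-McNeil formula
#' `SE^2 = (A(1-A) + (n+ - 1)(Q1 - A^2) + (n- - 1)(Q2 - A^2)) / (n+ n-)`
#' with `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`, and a two-sided z-test on the
#' difference of independent AUCs.
#'
#' @param auc_a,auc_b the two AUCs, each in (0, 1).
#' @param n_pos,n_neg class counts (>= 2 each).
#' @return two-sided p-value.
#' @export
hanley_auc_significance <- function(auc_a, auc_b, n_pos, n_neg) {
  if (n_pos < 2L || n_neg < 2L) stop("need at least 2 cases per class")
  if (any(c(auc_a, auc_b) <= 0 | c(auc_a, auc_b) >= 1))
    stop("AUCs must lie strictly inside (0, 1)")
  se <- function(a) {
    q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
    sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) + (n_neg - 1) * (q2 - a^2)) /
           (n_pos * n_neg))
  }
  z <- (auc_a - auc_b) / sqrt(se(auc_a)^2 + se(auc_b)^2)
  2 * stats::pnorm(-abs(z))
}

#' Percentage of tremor time per period
#'
#' The monitoring biomarker: for each consecutive period of `period_s`
#' seconds, 100 times the fraction of windows predicted as tremor. With
#' `period_s = NULL` the whole session forms one period. Empty periods are
#' excluded.
#'
#' @param window_preds binary per-window predictions, time-ordered.
#' @param period_s period length in seconds, or `NULL` for whole-session.
#' @param start_s per-window start times; defaults to a 1-s hop from 0.
#' @return data frame with `period_start` and `percent`.
#' @export
percent_tremor <- function(window_preds, period_s = NULL, start_s = NULL) {
  n <- length(window_preds)
  if (is.null(start_s)) start_s <- seq_len(n) - 1
  if (is.null(period_s)) {
    return(data.frame(period_start = min(start_s),
                      percent = 100 * mean(window_preds)))
  }
  bin <- floor(start_s / period_s)
  agg <- tapply(window_preds, bin, mean)
  data.frame(period_start = as.numeric(names(agg)) * period_s,
             percent = 100 * as.vector(agg))
}

#' Map a tremor percentage to a weak label (and back)
#'
#' Forward map: < 33% is *almost none*, 33-66% (inclusive) *half the time*,
#' > 66% *almost always*. The inverse returns the range midpoints 16.6, 50
#' and 83.3.
#'
#' @param pct percentage in \[0, 100\] (vectorized).
#' @return weak label string(s).
#' @export
percent_to_weak_label <- function(pct) {
  if (any(pct < 0 | pct > 100)) stop("percentage must lie in [0, 100]")
  ifelse(pct < 33, "almost_none",
         ifelse(pct <= 66, "half_the_time", "almost_always"))
}

#' @rdname percent_to_weak_label
#' @param label weak label string(s).
#' @export
weak_label_to_percent <- function(label) {
  c(almost_none = 16.6, half_the_time = 50, almost_always = 83.3)[label]
}

#' Agreement between predicted and reported weak labels
#'
#' Spearman's rank correlation (average ranks for ties) between two ordinal
#' label sequences, with the t-approximation p-value. A constant sequence
#' leaves the correlation undefined (`rho = NA`, flagged).
#'
#' @param predicted,reported weak label vectors (strings from
#'   [weak_label_levels] or ordinal 0/1/2), length >= 3.
#' @param alpha significance level reported against (default 0.005).
#' @return list with `rho`, `p`, `significant`, `defined`.
#' @export
weak_agreement <- function(predicted, reported, alpha = 0.005) {
  to_ord <- function(x) if (is.character(x) || is.factor(x))
    match(as.character(x), weak_label_levels) - 1L else as.numeric(x)
  a <- to_ord(predicted); b <- to_ord(reported)
  if (length(a) < 3L || length(a) != length(b))
    stop("need >= 3 paired intervals")
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12)
    return(list(rho = NA_real_, p = NA_real_, significant = FALSE,
                defined = FALSE))
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value,
       significant = is.finite(ct$p.value) && ct$p.value < alpha,
       defined = TRUE)
}

#' Leave-one-subject-out evaluation of a feature set + classifier
#'
#' Trains one model per fold and reports per-subject AUC and FPR@0.9TPR on
#' the held-out subject's windows; the aggregate is the mean of per-subject
#' AUCs (not the pooled-window AUC).
#'
#' @param X feature matrix over all windows (`n x d`).
#' @param y binary window labels.
#' @param subjects per-window subject ids.
#' @param kind classifier kind for [train_classifier()].
#' @param seed integer seed.
#' @param ... passed to [train_classifier()].
#' @return list with `per_subject` (data frame: subject, auc, fpr) and
#'   `mean_auc`.
#' @export
loso_evaluate <- function(X, y, subjects, kind = "mlp", seed = 1L, ...) {
  X <- as.matrix(X)
  folds <- loso_folds(subjects)
  rows <- lapply(folds, function(f) {
    tr <- subjects %in% f$train
    te <- subjects == f$test
    if (length(unique(y[te])) < 2L)
      return(data.frame(subject = f$test, auc = NA_real_, fpr = NA_real_))
    m <- train_classifier(X[tr, , drop = FALSE], y[tr], kind = kind,
                          seed = seed, subjects = subjects[tr], ...)
    rm <- roc_metrics(predict_scores(m, X[te, , drop = FALSE]), y[te])
    data.frame(subject = f$test, auc = rm$auc, fpr = rm$fpr_at_090_tpr)
  })
  per <- do.call(rbind, rows)
  list(per_subject = per, mean_auc = mean(per$auc, na.rm = TRUE))
}
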