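#' Weak diary label levels
#'
#' The three self-report options for a 5-minute interval, in increasing order
#' of tremor amount.
#' @export
weak_label_levels <- c("almost_none", "half_the_time", "almost_always")

#' Select training instances from one weakly labeled interval
#'
#' Stratified selection: *almost none* keeps the bottom 50% of windows by
#' score, labeled 0; *almost always* the top 50%, labeled 1; *half the time*
#' the bottom 25% labeled 0 and the top 25% labeled 1. Counts use `floor`
#' with a minimum of 1; sorting is stable, ties resolved by window index,
#' and no window can receive both labels.
#'
#' @param scores per-window tremor scores within the interval (length >= 4).
#' @param label one of [weak_label_levels].
#' @return list with `indices` (into `scores`) and `labels` (0/1).
#' @export
select_instances <- function(scores, label) {
  label <- match.arg(label, weak_label_levels)
  n <- length(scores)
  if (n < 4L) stop("interval has fewer than 4 windows; skip it")
  ord <- order(scores, seq_len(n))   # ascending, ties by index
  bottom <- function(k) ord[seq_len(k)]
  top <- function(k) ord[n - seq_len(k) + 1L]
  if (label == "almost_none") {
    k <- max(1L, n %/% 2L)
    list(indices = bottom(k), labels = rep(0L, k))
  } else if (label == "almost_always") {
    k <- max(1L, n %/% 2L)
    list(indices = top(k), labels = rep(1L, k))
  } else {
    k <- max(1L, n %/% 4L)
    list(indices = c(bottom(k), top(k)),
         labels = c(rep(0L, k), rep(1L, k)))
  }
}

#' Attach window indices to weak-label entries
#'
#' A window belongs to an entry iff its start time lies in
#' `[start, end)` and subject and hand match.
#'
#' @param entries data frame with columns `subject`, `hand`, `start`, `end`,
#'   `label`.
#' @param meta data frame with per-window columns `subject`, `hand`,
#'   `start_s`.
#' @return `entries` with a list-column `window_idx`.
#' @export
assign_entry_windows <- function(entries, meta) {
  entries$window_idx <- lapply(seq_len(nrow(entries)), function(i) {
    which(meta$subject == entries$subject[i] &
            meta$hand == entries$hand[i] &
            meta$start_s >= entries$start[i] &
            meta$start_s < entries$end[i])
  })
  entries
}

# predicted weak label (ordinal 0/1/2) for a set of window scores
predict_entry_ordinal <- function(scores, threshold = 0.5) {
  pct <- 100 * mean(scores > threshold)
  match(percent_to_weak_label(pct), weak_label_levels) - 1L
}

# Spearman agreement between predicted and reported weak labels over entries
entry_agreement <- function(model, features, entries, given_ord) {
  pred <- vapply(seq_len(nrow(entries)), function(i) {
    idx <- entries$window_idx[[i]]
    predict_entry_ordinal(predict_scores(model, features[idx, , drop = FALSE]))
  }, numeric(1))
  if (length(pred) < 2L || anyNA(pred) ||
      stats::sd(pred) < 1e-12 || stats::sd(given_ord) < 1e-12) return(0)
  stats::cor(pred, given_ord, method = "spearman")
}

#' Multiple-instance training from weak 5-minute labels
#'
#' The stratified MIL loop: windows inside each weakly labeled interval are
#' ranked by the current model's scores, [select_instances()] picks
#' pseudo-labeled windows per interval, and the base classifier is retrained
#' on the union of the selections (latest selections only). Because no model
#' exists at the start, the first ranking uses the unsupervised factorized
#' tremor energy. The iteration count is selected on a validation subset of
#' entries (20%, subject-stratified): the loop keeps the iteration whose
#' predicted weak labels correlate best (Spearman) with the reported ones,
#' and stops early once the criterion has not improved for `patience`
#' consecutive iterations.
#'
#' @param entries weak-label entries (see [assign_entry_windows()]; the
#'   list-column is added here if absent). Entries with fewer than 4 windows
#'   are skipped with a warning.
#' @param features `n x d` feature matrix over all windows.
#' @param meta per-window data frame (`subject`, `hand`, `start_s`).
#' @param energies per-window tremor energies from [factorize_windows()].
#' @param base base classifier kind (`"mlp"` or `"rf"`).
#' @param max_iters maximum rescoring iterations after the initial
#'   energy-ranked training (default 10); `max_iters = 0` trains once on the
#'   energy-initialized selection.
#' @param seed integer seed.
#' @param val_frac fraction of entries held out for iteration selection.
#' @param patience stop after this many non-improving iterations.
#' @return list with the selected `model`, `selected_iteration` (1 = the
#'   energy-initialized training), `val_trace`, and `models` (one per
#'   iteration run).
#' @export
mil_train <- function(entries, features, meta, energies, base = "mlp",
                      max_iters = 10L, seed = 1L, val_frac = 0.2,
                      patience = 2L) {
  if (nrow(entries) == 0L) stop("no weak-label entries")
  if (is.null(entries$window_idx)) entries <- assign_entry_windows(entries, meta)
  nw <- vapply(entries$window_idx, length, integer(1))
  if (any(nw < 4L)) {
    warning(sprintf("skipping %d entries with fewer than 4 windows", sum(nw < 4L)))
    entries <- entries[nw >= 4L, , drop = FALSE]
  }
  if (nrow(entries) == 0L) stop("no usable weak-label entries")
  given_ord <- match(entries$label, weak_label_levels) - 1L
  if (length(unique(given_ord)) == 1L)
    warning("all weak labels identical; training anyway")
  set.seed(seed)
  vi <- val_split_idx(given_ord, entries$subject, val_frac)
  ti <- setdiff(seq_len(nrow(entries)), vi)
  if (length(vi) == 0L || length(ti) == 0L) { ti <- seq_len(nrow(entries)); vi <- ti }
  train_entries <- entries[ti, , drop = FALSE]
  val_entries <- entries[vi, , drop = FALSE]

  retrain <- function(scores, iter) {
    rows <- integer(0); labs <- integer(0)
    for (i in seq_len(nrow(train_entries))) {
      idx <- train_entries$window_idx[[i]]
      sel <- select_instances(scores[idx], train_entries$label[i])
      rows <- c(rows, idx[sel$indices])
      labs <- c(labs, sel$labels)
    }
    keep <- !duplicated(rows)   # a window selected by two entries keeps its first label
    rows <- rows[keep]; labs <- labs[keep]
    if (length(unique(labs)) < 2L) {
      warning("degenerate selection (single class); duplicating opposite label")
      labs[1L] <- 1L - labs[1L]
    }
    train_classifier(features[rows, , drop = FALSE], labs, kind = base,
                     seed = seed + iter,
                     subjects = meta$subject[rows])
  }

  models <- list(); val_trace <- numeric(0)
  scores <- as.numeric(energies)
  best <- 0L; stall <- 0L
  for (iter in seq_len(max_iters + 1L)) {
    model <- retrain(scores, iter)
    models[[iter]] <- model
    val_trace[iter] <- entry_agreement(model, features, val_entries, given_ord[vi])
    if (iter == 1L || val_trace[iter] > max(val_trace[seq_len(iter - 1L)]) + 1e-9) {
      best <- iter; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
    scores <- predict_scores(model, features)
  }
  list(model = models[[best]], selected_iteration = best,
       val_trace = val_trace, models = models)
}
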