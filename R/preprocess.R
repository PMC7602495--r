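#' Accelerometer recording container
#'
#' Holds a triaxial wrist accelerometer recording for one hand of one subject.
#' Samples are stored as an `n x 3` matrix (columns x, y, z) in the units of
#' the input file (typically g); all downstream methods are scale-covariant,
#' so no unit conversion is forced.
#'
#' @param data numeric `n x 3` matrix of acceleration samples.
#' @param sample_rate sampling rate in Hz (positive).
#' @param subject_id subject identifier.
#' @param hand `"left"` or `"right"`.
#' @param start_time session-relative start time in seconds.
#' @param units unit string recorded in metadata (default `"g"`).
#' @return an object of class `accel_recording`.
#' @export
accel_recording <- function(data, sample_rate, subject_id = "s1",
                            hand = c("left", "right"), start_time = 0,
                            units = "g") {
  hand <- match.arg(hand)
  data <- unname(as.matrix(data))
  if (ncol(data) != 3L) stop("accelerometer data must have 3 columns (x, y, z)")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a positive scalar")
  if (anyNA(data)) stop("recording contains NA samples; split gaps before ingest")
  structure(
    list(data = data, sample_rate = sample_rate, subject_id = subject_id,
         hand = hand, start_time = start_time, units = units),
    class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> subject %s, %s hand: %d samples @ %g Hz (%.1f s), units %s\n",
              x$subject_id, x$hand, nrow(x$data), x$sample_rate,
              nrow(x$data) / x$sample_rate, x$units))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `accel_recording`.
#' @return duration in seconds.
#' @export
recording_duration <- function(rec) nrow(rec$data) / rec$sample_rate

#' Tremor event intervals
#'
#' Half-open `[start, end)` intervals in seconds marking tremor events for one
#' hand. Overlapping or abutting intervals are merged on construction.
#'
#' @param start,end numeric vectors of interval bounds in seconds.
#' @param hand `"left"` or `"right"`.
#' @return an object of class `tremor_intervals` (a data frame with columns
#'   `start`, `end` and a `hand` attribute).
#' @export
tremor_intervals <- function(start = numeric(), end = numeric(),
                             hand = c("left", "right")) {
  hand <- match.arg(hand)
  if (length(start) != length(end)) stop("start and end must have equal length")
  if (any(end <= start)) stop("every interval must satisfy end > start")
  df <- data.frame(start = as.numeric(start), end = as.numeric(end))
  if (nrow(df) > 1L) {
    df <- df[order(df$start), , drop = FALSE]
    merged <- df[1L, , drop = FALSE]
    for (i in seq_len(nrow(df))[-1L]) {
      k <- nrow(merged)
      if (df$start[i] <= merged$end[k]) {
        merged$end[k] <- max(merged$end[k], df$end[i])
      } else {
        merged <- rbind(merged, df[i, ])
      }
    }
    df <- merged
  }
  rownames(df) <- NULL
  structure(df, hand = hand, class = c("tremor_intervals", "data.frame"))
}

#' Total tremor time covered by an interval set
#' @param tiv a `tremor_intervals` object.
#' @param from,to optional clip range in seconds.
#' @return summed interval length in seconds.
#' @export
interval_total_time <- function(tiv, from = -Inf, to = Inf) {
  if (nrow(tiv) == 0L) return(0)
  s <- pmax(tiv$start, from); e <- pmin(tiv$end, to)
  sum(pmax(e - s, 0))
}

#' Load a recording from a CSV file
#'
#' Reads a `t,x,y,z` CSV (time in seconds, monotonically increasing) and infers
#' the sampling rate as the median of `1/diff(t)`. Files whose sample spacing
#' drifts by more than 1% from the median rate are rejected.
#'
#' @param path path to the CSV file.
#' @param fmt input format; only `"csv"` is supported.
#' @param subject_id,hand,units metadata attached to the recording; when a
#'   JSON sidecar `<path>.json` exists its fields take precedence.
#' @return an [accel_recording()].
#' @export
load_recording <- function(path, fmt = c("csv"), subject_id = "s1",
                           hand = "left", units = "g") {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "numeric")
  need <- c("t", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("recording CSV must have columns t,x,y,z")
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad))
    stop(sprintf("malformed/NaN row at data line %d of %s", bad[1L], path))
  dt <- diff(df$t)
  if (any(dt <= 0))
    stop(sprintf("non-monotonic time at data line %d", which(dt <= 0)[1L] + 1L))
  med_dt <- stats::median(dt)
  if (any(abs(dt - med_dt) > 0.01 * med_dt))
    stop("sample spacing drifts by more than 1%; fix timestamps before ingest")
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$subject_id)) subject_id <- meta$subject_id
    if (!is.null(meta$hand)) hand <- meta$hand
    if (!is.null(meta$units)) units <- meta$units
  }
  accel_recording(as.matrix(df[c("x", "y", "z")]), sample_rate = 1 / med_dt,
                  subject_id = subject_id, hand = hand,
                  start_time = df$t[1L], units = units)
}

#' Write a recording to CSV (with JSON metadata sidecar)
#'
#' Full-precision writer; `load_recording()` round-trips its output
#' bit-identically.
#'
#' @param rec an `accel_recording`.
#' @param path output CSV path; a `<path>.json` sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  n <- nrow(rec$data)
  t <- rec$start_time + (seq_len(n) - 1L) / rec$sample_rate
  lines <- c("t,x,y,z",
             sprintf("%.17g,%.17g,%.17g,%.17g",
                     t, rec$data[, 1L], rec$data[, 2L], rec$data[, 3L]))
  writeLines(lines, path)
  jsonlite::write_json(
    list(subject_id = rec$subject_id, hand = rec$hand, units = rec$units,
         sample_rate = rec$sample_rate),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Downsample a recording to 50 Hz
#'
#' All analysis runs at 50 Hz (tremor and its first two harmonics live well
#' below the 25 Hz Nyquist). Exact 2:1 inputs (100 Hz devices) are decimated by
#' 2 with a zero-phase FIR anti-alias filter; other rational rates go through
#' polyphase resampling.
#'
#' @param rec an `accel_recording` with `sample_rate >= 50`.
#' @return the recording at 50 Hz.
#' @export
resample_to_50hz <- function(rec) {
  fs <- rec$sample_rate
  if (fs < 50 - 1e-9) stop("unsupported rate: need sample_rate >= 50 Hz")
  if (abs(fs - 50) < 1e-9) return(rec)
  q <- fs / 50
  out <- if (abs(q - round(q)) < 1e-6) {
    apply(rec$data, 2L, function(v) signal::decimate(v, round(q), ftype = "fir"))
  } else {
    if (abs(fs - round(fs)) > 1e-6)
      stop("unsupported rate: need an integer or integer-multiple-of-50 rate")
    apply(rec$data, 2L, function(v) signal::resample(v, 50, round(fs)))
  }
  accel_recording(out, 50, rec$subject_id, rec$hand, rec$start_time, rec$units)
}

#' Remove gravity with a zero-phase high-pass filter
#'
#' Third-order Butterworth high-pass at 0.3 Hz, applied forward-backward
#' (zero-phase) per axis so that tremor event boundaries are not shifted by
#' group delay. Analysis is offline, so the non-causal filter is appropriate.
#'
#' @param rec an `accel_recording` at 50 Hz, at least 3 s long.
#' @param cutoff_hz high-pass cutoff (default 0.3 Hz).
#' @return the filtered recording (same length).
#' @export
highpass_gravity <- function(rec, cutoff_hz = 0.3) {
  if (abs(rec$sample_rate - 50) > 1e-9) stop("highpass_gravity expects a 50 Hz recording")
  n <- nrow(rec$data)
  if (n < 150L) stop("recording too short to filter (need >= 3 s)")
  bf <- signal::butter(3, cutoff_hz / 25, type = "high")
  # odd-reflection padding tames the forward-backward edge transients
  p <- min(n - 1L, 500L)
  out <- apply(rec$data, 2L, function(v) {
    vp <- c(2 * v[1L] - v[(p + 1L):2L], v, 2 * v[n] - v[(n - 1L):(n - p)])
    signal::filtfilt(bf, vp)[(p + 1L):(p + n)]
  })
  accel_recording(out, 50, rec$subject_id, rec$hand, rec$start_time, rec$units)
}

#' Slice a recording into 3-second windows with 1-second hop
#'
#' Windows are 150 samples at 50 Hz with a two-second overlap. The first
#' window starts at the first sample; a trailing partial window is discarded.
#' A recording shorter than 3 s yields an empty window set.
#'
#' @param rec a filtered 50 Hz `accel_recording`.
#' @return an object of class `window_set`: list with `windows`
#'   (`n x 150 x 3` array), `start_s`, optional `label`, `subject_id`, `hand`.
#' @export
make_windows <- function(rec) {
  if (abs(rec$sample_rate - 50) > 1e-9) stop("make_windows expects a 50 Hz recording")
  n <- nrow(rec$data)
  len <- 150L; hop <- 50L
  n_win <- if (n < len) 0L else (n - len) %/% hop + 1L
  w <- array(0, dim = c(n_win, len, 3L))
  starts <- numeric(n_win)
  for (i in seq_len(n_win)) {
    i0 <- (i - 1L) * hop
    w[i, , ] <- rec$data[(i0 + 1L):(i0 + len), ]
    starts[i] <- rec$start_time + i0 / 50
  }
  structure(list(windows = w, start_s = starts, label = NULL,
                 subject_id = rec$subject_id, hand = rec$hand,
                 sample_rate = 50),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  lab <- if (is.null(x$label)) "unlabeled" else
    sprintf("%d tremor / %d total", sum(x$label), length(x$label))
  cat(sprintf("<window_set> subject %s, %s hand: %d windows of 150 samples (%s)\n",
              x$subject_id, x$hand, n_windows(x), lab))
  invisible(x)
}

#' Number of windows in a window set
#' @param ws a `window_set`.
#' @return integer count.
#' @export
n_windows <- function(ws) dim(ws$windows)[1L]

#' Attach binary tremor labels to windows
#'
#' A window is labeled tremor (1) iff strictly more than 50% of its 3 s
#' (i.e. > 1.5 s) overlaps tremor intervals; exactly 50% counts as non-tremor.
#'
#' @param ws a `window_set`.
#' @param tiv a `tremor_intervals` object for the same hand.
#' @return `ws` with an integer `label` vector.
#' @export
label_windows <- function(ws, tiv) {
  if (!identical(attr(tiv, "hand"), ws$hand))
    stop(sprintf("hand mismatch: windows are %s, intervals are %s",
                 ws$hand, attr(tiv, "hand")))
  ws$label <- as.integer(window_overlap(ws$start_s, tiv) > 1.5)
  ws
}

# total overlap (seconds) of each [start, start+3) window with the intervals
window_overlap <- function(start_s, tiv) {
  ov <- numeric(length(start_s))
  for (k in seq_len(nrow(tiv))) {
    ov <- ov + pmax(0, pmin(start_s + 3, tiv$end[k]) - pmax(start_s, tiv$start[k]))
  }
  ov
}

#' Concatenate window sets
#' @param ... `window_set` objects (labels must be all present or all absent).
#' @return a combined `window_set`; `subject_id`/`hand` become per-window
#'   vectors in `$subject` and `$hand_of` when they differ.
#' @export
bind_window_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !inherits(sets[[1L]], "window_set"))
    sets <- sets[[1L]]
  w <- do.call(rbind, lapply(sets, function(s) matrix(s$windows, n_windows(s), 450L)))
  out <- structure(list(
    windows = array(w, dim = c(nrow(w), 150L, 3L)),
    start_s = unlist(lapply(sets, `[[`, "start_s")),
    label = if (all(vapply(sets, function(s) !is.null(s$label), TRUE)))
      unlist(lapply(sets, `[[`, "label")) else NULL,
    subject_id = NA_character_, hand = NA_character_, sample_rate = 50),
    class = "window_set")
  out$subject <- unlist(lapply(sets, function(s) rep(s$subject_id, n_windows(s))))
  out$hand_of <- unlist(lapply(sets, function(s) rep(s$hand, n_windows(s))))
  out
}
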