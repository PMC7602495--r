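#' Spectral energy in the 3-9 Hz tremor band
#'
#' Sum over axes of the squared amplitude-spectrum bins between 3 and 9 Hz —
#' the single-feature benchmark (tremor energy concentrates in this band,
#' normal movement below 3 Hz).
#'
#' @param window `150 x 3` matrix.
#' @return non-negative scalar.
#' @export
energy_3_9 <- function(window) {
  sp <- amplitude_spectrum(window, taper = "hamming")
  band <- freq_grid() >= 3 & freq_grid() <= 9
  sum(sp[, band]^2)
}

# ---- baseline (356-dimensional) feature set ---------------------------------

# 16 time-domain features of one channel
time_feats_16 <- function(x) {
  n <- length(x)
  q <- stats::quantile(x, c(0.25, 0.75, 0.2, 0.4, 0.6, 0.8), names = FALSE, type = 7)
  mag <- abs(x)
  ent <- if (max(mag) > min(mag)) {
    br <- seq(min(mag), max(mag), length.out = 17L)
    h <- tabulate(findInterval(mag, br, rightmost.closed = TRUE), nbins = 16L)
    p <- h / sum(h)
    p <- p[p > 0]
    -sum(p * log(p))
  } else 0
  arc <- tryCatch({
    if (stats::sd(x) < 1e-12) c(0, 0) else {
      a <- stats::ar.yw(x, aic = FALSE, order.max = 2L, demean = TRUE)$ar
      c(a, 0, 0)[1:2]
    }
  }, error = function(e) c(0, 0))
  c(mean = mean(x), sd = stats::sd(x), median = stats::median(x),
    max = max(x), min = min(x), sma = mean(mag), energy = sum(x^2) / n,
    iqr25 = q[1L], iqr75 = q[2L],
    ecdf20 = q[3L], ecdf40 = q[4L], ecdf60 = q[5L], ecdf80 = q[6L],
    entropy = ent, ar1 = arc[1L], ar2 = arc[2L])
}

skew_kurt <- function(x) {
  m <- mean(x); v <- mean((x - m)^2)
  if (v < 1e-24) return(c(skewness = 0, kurtosis = 0))
  c(skewness = mean((x - m)^3) / v^1.5,
    kurtosis = mean((x - m)^4) / v^2 - 3)
}

# 27 frequency-domain features of one channel's amplitude spectrum
freq_feats_27 <- function(spec, grid) {
  f16 <- time_feats_16(spec)
  tot <- sum(spec)
  dom <- grid[which.max(spec)]
  avg <- if (tot > 0) sum(grid * spec) / tot else 0
  pow <- mean(spec^2)
  sk <- skew_kurt(spec)
  bands <- floor(grid / (25 / 6))          # 6 equal-width bands over 0-25 Hz
  bands[bands > 5] <- 5
  be <- vapply(0:5, function(b) sum(spec[bands == b]^2), numeric(1))
  names(be) <- paste0("band", 1:6)
  # frequency-domain entropy uses the normalized spectrum, not a histogram
  ent <- if (tot > 0) {
    p <- spec / tot
    p <- p[p > 0]
    -sum(p * log(p))
  } else 0
  f16["entropy"] <- ent
  c(f16, domfreq = dom, avgfreq = avg, specpow = pow, sk, be)
}

cor0 <- function(a, b) {
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(0)
  stats::cor(a, b)
}

#' The 356-dimensional baseline feature set
#'
#' 16 time-domain features (mean, sd, median, max, min, signal magnitude
#' area, energy, two IQR quantiles, four ECDF quantiles, entropy, two
#' Yule-Walker AR coefficients) and 27 frequency-domain features (the same 16
#' on the FFT magnitude plus dominant frequency, spectral centroid, spectral
#' power, skewness, kurtosis and six equal-width band energies), computed on
#' each of X, Y, Z and the magnitude channel of both acceleration and jerk
#' (first difference times sample rate), plus 12 inter-axis correlations
#' (3 axis pairs for acceleration, jerk and their FFT magnitudes):
#' (16 + 27) x 4 x 2 + 12 = 356. Constant channels get correlation 0 and AR
#' coefficients 0, so the vector is always finite.
#'
#' @param window `150 x 3` matrix.
#' @return named numeric vector of length 356 (names stable across runs).
#' @export
baseline_features <- function(window) {
  window <- as.matrix(window)
  if (nrow(window) != 150L || ncol(window) != 3L)
    stop("window must be 150 samples x 3 axes")
  grid <- freq_grid()
  jerk <- diff(window) * 50
  sigs <- list(acc = window, jerk = jerk)
  out <- numeric(0)
  for (sn in names(sigs)) {
    s <- sigs[[sn]]
    chans <- list(x = s[, 1L], y = s[, 2L], z = s[, 3L],
                  mag = sqrt(rowSums(s^2)))
    for (cn in names(chans)) {
      v <- chans[[cn]]
      tf <- time_feats_16(v)
      names(tf) <- paste(sn, cn, "t", names(tf), sep = "_")
      ff <- freq_feats_27(amp_spectrum_1d(v, taper = "hamming"), grid)
      names(ff) <- paste(sn, cn, "f", names(ff), sep = "_")
      out <- c(out, tf, ff)
    }
  }
  pairs <- list(xy = c(1L, 2L), xz = c(1L, 3L), yz = c(2L, 3L))
  for (sn in names(sigs)) {
    s <- sigs[[sn]]
    for (pn in names(pairs)) {
      p <- pairs[[pn]]
      out[paste("corr", sn, pn, sep = "_")] <- cor0(s[, p[1L]], s[, p[2L]])
    }
  }
  for (sn in names(sigs)) {
    s <- sigs[[sn]]
    sp <- apply(s, 2L, amp_spectrum_1d, taper = "hamming")
    for (pn in names(pairs)) {
      p <- pairs[[pn]]
      out[paste("corr_fft", sn, pn, sep = "_")] <- cor0(sp[, p[1L]], sp[, p[2L]])
    }
  }
  out
}

#' 36 MFCCs of a raw window
#'
#' 12 cepstral coefficients (c1-c12; c0 excluded) per axis, computed from the
#' Hamming-tapered amplitude spectrum, concatenated X, Y, Z.
#'
#' @param window `150 x 3` matrix.
#' @return named numeric vector of length 36.
#' @export
mfcc_features <- function(window) {
  sp <- amplitude_spectrum(window, taper = "hamming")
  out <- as.vector(t(mfcc_from_spectrum(sp)))
  names(out) <- paste0(rep(c("x", "y", "z"), each = 12L), "_c", rep(1:12, 3L))
  out
}

#' 108 MFCCs of the factorized spectra (MFCC-T/NT)
#'
#' The cepstral pipeline (mel filterbank, log, DCT; the FFT stage is skipped
#' because the spectra are given) applied to each of the total, tremor and
#' non-tremor spectra of each axis: 12 coefficients x 3 spectra x 3 axes.
#'
#' @param triple_spectra `3 axes x 3 kinds x 128` array (one window's slice
#'   of an `ntf_result$spectra`), kinds ordered total, tremor, nontremor.
#' @return named numeric vector of length 108 (axis-major, then kind).
#' @export
mfcc_tnt_features <- function(triple_spectra) {
  if (!all(dim(triple_spectra) == c(3L, 3L, 128L)))
    stop("expected a 3 x 3 x 128 spectra slice (axes x total/tremor/nontremor x freq)")
  kinds <- c("tot", "trem", "ntrem")
  out <- numeric(0)
  for (a in 1:3) for (k in 1:3) {
    cc <- mfcc_from_spectrum(triple_spectra[a, k, ])
    names(cc) <- paste0(c("x", "y", "z")[a], "_", kinds[k], "_c", 1:12)
    out <- c(out, cc)
  }
  out
}

#' Compute a feature matrix for a window set
#'
#' Front end over the individual feature-set functions; returns an
#' `n_windows x d` matrix with stable column names and the window metadata
#' attached as attributes.
#'
#' @param ws a `window_set`.
#' @param set one of `"energy"` (d = 1), `"psd"` (384), `"baseline"` (356),
#'   `"mfcc"` (36), `"mfcc_tnt"` (108).
#' @param ntf an `ntf_result` for the same windows; required for
#'   `"mfcc_tnt"`.
#' @return feature matrix with attributes `set_id`, `subject_id`, `hand`,
#'   `start_s`.
#' @export
compute_features <- function(ws, set = c("energy", "psd", "baseline", "mfcc", "mfcc_tnt"),
                             ntf = NULL) {
  set <- match.arg(set)
  n <- n_windows(ws)
  rows <- switch(set,
    energy = lapply(seq_len(n), function(i)
      c(energy_3_9 = energy_3_9(ws$windows[i, , ]))),
    psd = lapply(seq_len(n), function(i) {
      p <- welch_psd(ws$windows[i, , ])
      v <- as.vector(t(p))
      names(v) <- paste0(rep(c("x", "y", "z"), each = 128L), "_psd", rep(1:128, 3L))
      v
    }),
    baseline = lapply(seq_len(n), function(i) baseline_features(ws$windows[i, , ])),
    mfcc = lapply(seq_len(n), function(i) mfcc_features(ws$windows[i, , ])),
    mfcc_tnt = {
      if (is.null(ntf)) stop("mfcc_tnt features need an ntf_result (argument `ntf`)")
      if (dim(ntf$spectra)[1L] != n) stop("ntf result does not match the window set")
      lapply(seq_len(n), function(i) mfcc_tnt_features(ntf$spectra[i, , , ]))
    })
  m <- do.call(rbind, rows)
  if (n == 0L) m <- matrix(numeric(), 0L, 0L)
  structure(m, set_id = set, subject_id = ws$subject_id, hand = ws$hand,
            start_s = ws$start_s)
}
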