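#' The shared 128-point frequency grid
#'
#' Every spectral representation in the package (amplitude spectra, Welch PSD,
#' the factorization dictionaries, and the stacked CNN inputs) lives on one
#' grid: a 150-sample, 50 Hz window is tapered and zero-padded to 256 points,
#' and the one-sided bins 0..127 cover 0 to 24.8 Hz in steps of 50/256 Hz.
#'
#' @return numeric vector of 128 frequencies in Hz.
#' @export
freq_grid <- function() (0:127) * (50 / 256)

# core amplitude spectrum for a single channel of length <= 256
amp_spectrum_1d <- function(x, taper = c("hamming", "none")) {
  taper <- match.arg(taper)
  n <- length(x)
  if (n > 256L) stop("channel longer than the 256-point FFT frame")
  w <- if (taper == "hamming") {
    0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
  } else rep(1, n)
  xt <- x * w
  X <- stats::fft(c(xt, rep(0, 256L - n)))
  2 * Mod(X[1:128]) / sum(w)
}

#' Per-axis amplitude spectrum of a 3-s window
#'
#' One-sided amplitude spectrum of each axis on the shared [freq_grid()].
#' Scaled so a unit-amplitude sinusoid peaks near 1 regardless of taper.
#'
#' @param window `150 x 3` matrix (one window's samples).
#' @param taper `"hamming"` (default) or `"none"`.
#' @return `3 x 128` matrix (rows = axes x, y, z).
#' @export
amplitude_spectrum <- function(window, taper = c("hamming", "none")) {
  taper <- match.arg(taper)
  window <- as.matrix(window)
  if (nrow(window) != 150L || ncol(window) != 3L)
    stop("window must be 150 samples x 3 axes")
  t(apply(window, 2L, amp_spectrum_1d, taper = taper))
}

#' Amplitude spectra of every window in a window set
#' @param ws a `window_set`.
#' @param taper passed to [amplitude_spectrum()].
#' @return `n x 3 x 128` array.
#' @export
window_spectra <- function(ws, taper = "hamming") {
  n <- n_windows(ws)
  out <- array(0, dim = c(n, 3L, 128L))
  for (i in seq_len(n)) out[i, , ] <- amplitude_spectrum(ws$windows[i, , ], taper)
  out
}

#' Welch one-sided power spectral density
#'
#' Averaged modified periodogram over 75-sample Hamming segments with 50%
#' overlap, zero-padded onto the shared 256-point frame, per axis. Density
#' scaling: a white-noise input of variance s^2 has expected level
#' 2*s^2/fs per bin (one-sided).
#'
#' @param window `150 x 3` matrix.
#' @return `3 x 128` matrix of PSD values on [freq_grid()].
#' @export
welch_psd <- function(window) {
  window <- as.matrix(window)
  if (nrow(window) != 150L || ncol(window) != 3L)
    stop("window must be 150 samples x 3 axes")
  seg_len <- 75L
  starts <- c(1L, 38L, 76L)  # 50% overlap over the 150 samples
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(seg_len) - 1L) / (seg_len - 1L))
  u <- sum(w^2)
  psd1 <- function(x) {
    acc <- numeric(128L)
    for (s in starts) {
      seg <- x[s:(s + seg_len - 1L)] * w
      X <- stats::fft(c(seg, rep(0, 256L - seg_len)))
      acc <- acc + 2 * Mod(X[1:128])^2 / (50 * u)
    }
    acc / length(starts)
  }
  t(apply(window, 2L, psd1))
}
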