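# Mel filterbank + DCT cepstral pipeline, rescaled to the 0-25 Hz band of a
# 50 Hz accelerometer signal (speech-convention bands do not apply here).

mel_of <- function(f) 2595 * log10(1 + f / 700)
hz_of <- function(m) 700 * (10^(m / 2595) - 1)

# 26 triangular filters, mel-spaced over 0.3-25 Hz, evaluated on the shared
# grid as continuous triangles (no integer-bin snapping, so no empty filters)
mel_filterbank <- function(n_filters = 26L, f_lo = 0.3, f_hi = 25) {
  grid <- freq_grid()
  edges <- hz_of(seq(mel_of(f_lo), mel_of(f_hi), length.out = n_filters + 2L))
  fb <- matrix(0, n_filters, 128L)
  for (j in seq_len(n_filters)) {
    l <- edges[j]; c <- edges[j + 1L]; r <- edges[j + 2L]
    up <- (grid - l) / (c - l)
    down <- (r - grid) / (r - c)
    fb[j, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# orthonormal DCT-II matrix (n x n)
dct2_matrix <- function(n) {
  k <- 0:(n - 1L)
  C <- sqrt(2 / n) * cos(pi * outer(k, k + 0.5) / n)
  C[1L, ] <- C[1L, ] / sqrt(2)
  C
}

the_fb <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- mel_filterbank()
    cache
  }
})
the_dct <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- dct2_matrix(26L)
    cache
  }
})

#' Cepstral coefficients of a 128-point amplitude spectrum
#'
#' Applies the package's mel filterbank (26 triangular filters over
#' 0.3-25 Hz) to the power spectrum, takes logs (floored at 1e-10) and an
#' orthonormal DCT-II, and keeps coefficients c1-c12. c0 is excluded, which
#' makes the coefficients invariant to overall signal scale.
#'
#' @param spectrum length-128 non-negative amplitude spectrum on
#'   [freq_grid()], or an `n x 128` matrix.
#' @return length-12 vector (or `n x 12` matrix) of cepstral coefficients.
#' @export
mfcc_from_spectrum <- function(spectrum) {
  S <- if (is.matrix(spectrum)) spectrum else matrix(spectrum, nrow = 1L)
  if (ncol(S) != 128L) stop("spectrum must have 128 points")
  e <- S^2 %*% t(the_fb())
  ce <- log(pmax(e, 1e-10)) %*% t(the_dct())
  out <- ce[, 2:13, drop = FALSE]
  if (is.matrix(spectrum)) out else drop(out)
}
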