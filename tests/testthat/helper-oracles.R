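# Independent oracles used across test files.

# dominant frequency of a real signal by plain FFT argmax
fft_peak <- function(x, fs) {
  n <- length(x)
  a <- Mod(stats::fft(x))[seq_len(n %/% 2)]
  ((which.max(a[-1]) )) * fs / n   # skip DC
}

# amplitude of the FFT bin nearest f for a real signal
fft_amp_at <- function(x, fs, f) {
  n <- length(x)
  k <- round(f * n / fs)
  2 * Mod(stats::fft(x))[k + 1L] / n
}

# AUC as the Mann-Whitney statistic, brute force over all +/- pairs
mw_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  g <- outer(sp, sn, ">"); e <- outer(sp, sn, "==")
  (sum(g) + 0.5 * sum(e)) / (length(sp) * length(sn))
}

# Spearman rho from average ranks, direct formula
rank_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# 150 x 3 window with a sinusoid on one axis
sine_window <- function(f, axis = 1L, amp = 1, fs = 50) {
  w <- matrix(0, 150L, 3L)
  w[, axis] <- amp * sin(2 * pi * f * (0:149) / fs)
  w
}

# minimal window_set wrapper around an n x 150 x 3 array
as_window_set <- function(arr, subject = "t", hand = "left") {
  structure(list(windows = arr, start_s = seq_len(dim(arr)[1L]) - 1,
                 label = NULL, subject_id = subject, hand = hand,
                 sample_rate = 50),
            class = "window_set")
}

# windows of a pure tremor signal (f0 + 2 harmonics, random phases)
tremor_window_array <- function(n, f0, amps = c(0.2, 0.1, 0.05), noise = 0.01) {
  tt <- (0:149) / 50
  arr <- array(0, dim = c(n, 150L, 3L))
  for (j in seq_len(n)) for (a in 1:3) {
    v <- stats::rnorm(150, sd = noise)
    for (k in 1:3)
      v <- v + amps[k] * sin(2 * pi * k * f0 * (tt + j) + stats::runif(1, 0, 2 * pi))
    arr[j, , a] <- v
  }
  arr
}
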