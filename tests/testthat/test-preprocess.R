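test_that("CSV loading infers the rate, rejects bad rows, and round-trips", {
  tmp <- tempfile(fileext = ".csv")
  t <- (0:299) / 100
  writeLines(c("t,x,y,z", sprintf("%g,%g,%g,%g", t, sin(t), cos(t), t * 0)), tmp)
  rec <- load_recording(tmp)
  expect_equal(rec$sample_rate, 100, tolerance = 1e-9)
  expect_equal(nrow(rec$data), 300L)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("t,x,y,z", "0,1,1,1", "0.01,NaN,1,1", "0.02,1,1,1"), bad)
  expect_error(load_recording(bad), "row|line 2")

  nonmono <- tempfile(fileext = ".csv")
  writeLines(c("t,x,y,z", "0,1,1,1", "0.02,1,1,1", "0.01,1,1,1"), nonmono)
  expect_error(load_recording(nonmono), "monotonic")

  # synthetic writer output round-trips bit-identically
  g <- gen_recording(subject_profile("rt", tremor_prevalence = 0.3), 60, seed = 4)
  out <- tempfile(fileext = ".csv")
  write_recording(g$recording, out)
  back <- load_recording(out)
  expect_identical(back$data, unname(g$recording$data))
  expect_equal(back$sample_rate, 100, tolerance = 1e-9)
  expect_identical(back$subject_id, "rt")
})

test_that("downsampling to 50 Hz preserves duration and in-band content", {
  g <- gen_recording(subject_profile("a", tremor_prevalence = 0), 60, seed = 1)
  r50 <- resample_to_50hz(g$recording)
  expect_equal(r50$sample_rate, 50)
  expect_equal(nrow(r50$data), nrow(g$recording$data) / 2)
  expect_identical(resample_to_50hz(r50), r50)  # already 50 Hz

  low <- accel_recording(matrix(0, 100, 3), 25)
  expect_error(resample_to_50hz(low), "unsupported")

  # 5 Hz sine at 100 Hz: peak stays at 5 Hz, amplitude within 2%
  t <- (0:999) / 100
  rec <- accel_recording(cbind(sin(2 * pi * 5 * t), 0 * t, 0 * t), 100)
  v <- resample_to_50hz(rec)$data[, 1]
  expect_equal(fft_peak(v, 50), 5, tolerance = 0.11)
  expect_equal(fft_amp_at(v, 50, 5), 1, tolerance = 0.02)
})

test_that("gravity high-pass removes DC and sub-0.3 Hz drift, keeps tremor band", {
  n <- 6000  # 120 s at 50 Hz
  mid <- 2000:4000  # 40-80 s: past the filter transient
  const <- accel_recording(matrix(1, n, 3), 50)
  hp <- highpass_gravity(const)
  expect_lt(max(abs(hp$data[mid, ])), 1e-6)

  t <- (seq_len(n) - 1) / 50
  s5 <- accel_recording(cbind(sin(2 * pi * 5 * t), 0 * t, 0 * t), 50)
  amp <- sqrt(2) * sqrt(mean(highpass_gravity(s5)$data[mid, 1]^2))
  expect_equal(amp, 1, tolerance = 0.01)

  slow <- accel_recording(cbind(sin(2 * pi * 0.05 * t), 0 * t, 0 * t), 50)
  att <- sqrt(mean(highpass_gravity(slow)$data[mid, 1]^2)) * sqrt(2)
  expect_lt(20 * log10(att), -40)

  expect_error(highpass_gravity(accel_recording(matrix(0, 100, 3), 50)), "short")

  # linearity: highpass(a x) = a highpass(x)
  set.seed(2)
  x <- matrix(rnorm(n * 3), n, 3)
  h1 <- highpass_gravity(accel_recording(3.7 * x, 50))$data
  h2 <- 3.7 * highpass_gravity(accel_recording(x, 50))$data
  expect_equal(h1, h2, tolerance = 1e-10)
})

test_that("residual sub-0.3 Hz energy after filtering is below 1%", {
  g <- gen_recording(subject_profile("d", tremor_prevalence = 0,
                                     adl_level = 0), 240, seed = 6,
                     transient_rate = 0, noise_sd = 0)
  r <- resample_to_50hz(g$recording)
  mid <- 2001:10000  # 40-200 s, past the filter transient
  band_energy <- function(v) {
    v <- v[mid]
    n <- length(v); f <- (0:(n - 1)) * 50 / n
    a <- Mod(stats::fft(v))^2
    sum(a[f > 1e-9 & f < 0.3])
  }
  before <- sum(sapply(1:3, function(a) band_energy(r$data[, a] - mean(r$data[, a]))))
  after <- sum(sapply(1:3, function(a) band_energy(highpass_gravity(r)$data[, a])))
  expect_lt(after, 0.01 * before)
})

test_that("windowing yields 150-sample windows on a 1-s hop, partials dropped", {
  mk <- function(T) accel_recording(matrix(rnorm(round(T * 50) * 3), ncol = 3), 50)
  ws10 <- make_windows(mk(10))
  expect_equal(n_windows(ws10), 8L)
  expect_equal(dim(ws10$windows)[2], 150L)
  expect_equal(diff(ws10$start_s), rep(1, 7))
  expect_equal(n_windows(make_windows(mk(2.9))), 0L)

  # brute-force count oracle on random durations
  set.seed(3)
  for (T in runif(10, 2, 40)) {
    n_samp <- round(T * 50)
    brute <- 0L; i <- 0L
    while (i + 150L <= n_samp) { brute <- brute + 1L; i <- i + 50L }
    expect_equal(n_windows(make_windows(mk(T))), brute)
  }
})

test_that("windows are labeled tremor only above 50% overlap", {
  rec <- accel_recording(matrix(0, 500, 3), 50)  # 10 s -> 8 windows at 0..7 s
  ws <- make_windows(rec)
  tiv <- tremor_intervals(c(0, 5.4), c(4, 6.9), hand = "left")
  lab <- label_windows(ws, tiv)$label
  # brute-force overlap via 1-ms discretization
  grid <- seq(0, 10, by = 1e-3)
  inside <- (grid >= 0 & grid < 4) | (grid >= 5.4 & grid < 6.9)
  brute <- sapply(0:7, function(s)
    as.integer(sum(inside[grid >= s & grid < s + 3]) * 1e-3 > 1.5))
  expect_equal(lab, brute)

  # exact boundary cases: 1.6 s overlap -> 1, 1.5 -> 0, 1.4 -> 0
  ov <- function(len) label_windows(ws, tremor_intervals(0, len, hand = "left"))$label[1]
  expect_equal(ov(1.6), 1L)
  expect_equal(ov(1.5), 0L)
  expect_equal(ov(1.4), 0L)

  expect_equal(label_windows(ws, tremor_intervals(hand = "left"))$label, rep(0L, 8))
  expect_error(label_windows(ws, tremor_intervals(0, 1, hand = "right")), "hand")
})

test_that("amplitude spectra live on the shared 128-point grid", {
  expect_length(freq_grid(), 128L)
  expect_equal(freq_grid()[2] - freq_grid()[1], 50 / 256)

  z <- amplitude_spectrum(matrix(0, 150, 3))
  expect_equal(dim(z), c(3L, 128L))
  expect_true(all(z == 0))

  sp <- amplitude_spectrum(sine_window(5))
  expect_lt(abs(freq_grid()[which.max(sp[1, ])] - 5), 50 / 256 + 1e-9)
  expect_true(all(sp[2:3, ] < 1e-10))
})
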