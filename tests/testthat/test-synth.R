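test_that("generated recordings honor the profile and are seed-deterministic", {
  prof <- subject_profile("g", f0 = 5.5, tremor_prevalence = 0.4)
  g1 <- gen_recording(prof, 120, seed = 60)
  g2 <- gen_recording(prof, 120, seed = 60)
  expect_identical(g1$recording$data, g2$recording$data)
  expect_identical(as.data.frame(g1$intervals), as.data.frame(g2$intervals))
  expect_equal(g1$recording$sample_rate, 100)

  # prevalence 0: no intervals, tremor band stays at the noise floor
  quiet <- gen_recording(subject_profile("q", tremor_prevalence = 0,
                                         adl_level = 0.05), 120, seed = 61,
                         transient_rate = 0)
  expect_equal(nrow(quiet$intervals), 0L)
  band_rms <- function(v, lo, hi) {
    n <- length(v); f <- (0:(n - 1)) * 100 / n
    sqrt(sum(Mod(stats::fft(v))[f >= lo & f <= hi]^2) / n^2)
  }
  v <- quiet$recording$data[, 1]
  expect_lt(band_rms(v, 3, 9), 3 * band_rms(v, 15, 25))

  expect_error(gen_recording(prof, 30, seed = 1), "60 s")
  expect_error(subject_profile("x", f0 = 12), "3, 9")
  expect_error(subject_profile("x", tremor_prevalence = 1.2), "0, 1")
})

test_that("burst spectra peak at the profile's base frequency", {
  prof <- subject_profile("b", f0 = 6.2, tremor_prevalence = 0.5,
                          adl_level = 0.02)
  g <- gen_recording(prof, 300, seed = 62, transient_rate = 0)
  long <- g$intervals[g$intervals$end - g$intervals$start > 4, ]
  expect_gt(nrow(long), 0)
  for (k in seq_len(min(3, nrow(long)))) {
    i0 <- floor(long$start[k] * 100) + 150
    seg <- g$recording$data[i0:(i0 + 255), 1]
    expect_lt(abs(fft_peak(seg - mean(seg), 100) - 6.2), 0.45)
  }
})

test_that("weak labels are the mapped true fractions when noise is off", {
  prof <- subject_profile("w", tremor_prevalence = 0.5, label_noise = 0)
  g <- gen_recording(prof, 1800, seed = 63)
  wl <- gen_weak_labels(g$intervals, 1800, entry_period_s = 300, prof, seed = 1)
  expect_equal(nrow(wl), 6L)
  expect_true(all(wl$end - wl$start == 300))
  # overlap-fraction oracle per entry
  for (i in seq_len(nrow(wl))) {
    frac <- interval_total_time(g$intervals, wl$start[i], wl$end[i]) / 300
    expect_equal(wl$label[i], percent_to_weak_label(100 * frac))
  }
  # fully covered interval maps to almost_always
  tiv <- tremor_intervals(0, 600, hand = "left")
  wl2 <- gen_weak_labels(tiv, 600, 300, prof, seed = 1)
  expect_true(all(wl2$label == "almost_always"))
  expect_error(gen_weak_labels(tiv, 200, 300, prof), "no diary entry")
})

test_that("cohorts span low and high prevalence and track their profiles", {
  coh <- gen_cohort(6, seed = 2, config = cohort_config(duration_s = 300))
  expect_length(coh$subjects, 6L)
  recs <- unlist(lapply(coh$subjects, function(s)
    list(s$left$recording, s$right$recording)), recursive = FALSE)
  expect_length(recs, 12L)
  prevs <- vapply(coh$subjects, function(s) s$profile$tremor_prevalence, 0)
  expect_true(any(prevs <= 0.05) && any(prevs >= 0.60))

  # empirical tremor fraction close to the configured prevalence (1-h recording)
  prof <- subject_profile("e", tremor_prevalence = 0.35,
                          tremor_burst_duration = 10)
  g <- gen_recording(prof, 3600, seed = 64)
  frac <- interval_total_time(g$intervals, 0, 3600) / 3600
  expect_lt(abs(frac - 0.35), 0.05)
})

test_that("generated window labels obey the >50% overlap rule exactly", {
  prof <- subject_profile("c", tremor_prevalence = 0.4)
  g <- gen_recording(prof, 180, seed = 65)
  ws <- label_windows(make_windows(highpass_gravity(resample_to_50hz(g$recording))),
                      g$intervals)
  grid <- seq(0, 180, by = 1e-3)
  inside <- rep(FALSE, length(grid))
  for (k in seq_len(nrow(g$intervals)))
    inside <- inside | (grid >= g$intervals$start[k] & grid < g$intervals$end[k])
  brute <- vapply(ws$start_s, function(s)
    as.integer(sum(inside[grid >= s & grid < s + 3]) * 1e-3 > 1.5), 0L)
  expect_equal(ws$label, brute)
})

test_that("a cohort writes to plain-text files and reads back", {
  coh <- gen_cohort(2, seed = 3, config = cohort_config(duration_s = 300))
  dir <- tempfile()
  write_cohort(coh, dir)
  files <- list.files(dir)
  expect_true("manifest.json" %in% files)
  expect_length(grep("_intervals\\.json$", files), 4L)
  rec <- load_recording(file.path(dir, "s01_left.csv"))
  expect_identical(rec$subject_id, "s01")
  expect_identical(rec$hand, "left")
  tiv <- read_intervals(file.path(dir, "s01_left_intervals.json"))
  expect_equal(as.data.frame(tiv), as.data.frame(coh$subjects[[1]]$left$intervals))
  wl <- read_weak_labels(file.path(dir, "s01_left_weak.json"))
  expect_equal(wl$label, coh$subjects[[1]]$left$weak_labels$label)

  back <- read_cohort(dir)
  expect_length(back$subjects, 2L)
  expect_identical(back$subjects[[2]]$right$recording$data,
                   coh$subjects[[2]]$right$recording$data)
  expect_equal(nrow(back$weak_labels), nrow(coh$weak_labels))
})
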