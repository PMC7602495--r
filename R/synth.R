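# Synthetic cohort generator. Emulates the statistical structure the pipeline
# assumes: gravity with slow orientation drift (< 0.3 Hz), background
# activities of daily living (ADL) with energy below 3 Hz, tremor bursts as
# amplitude-modulated sinusoids at a per-subject base frequency in 3-9 Hz with
# two harmonics, broadband sensor noise, and 5-minute self-report entries
# derived from the true tremor fraction with optional one-level label noise.

seed_mix <- function(seed, k) as.integer((as.numeric(seed) * 7919 + k) %% 2147483647)

#' Subject profile for the synthetic generator
#'
#' @param subject_id subject identifier.
#' @param f0 tremor base frequency in Hz (4-8 by default; must lie in 3-9).
#' @param harmonic_amps amplitudes (signal units, typically g) of the f0,
#'   2*f0 and 3*f0 components.
#' @param tremor_prevalence expected fraction of time spent in tremor bursts.
#' @param tremor_burst_duration mean burst length in seconds.
#' @param adl_level RMS of the sub-3 Hz background-motion component.
#' @param label_noise probability that a diary entry is off by one level.
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, f0 = 5, harmonic_amps = c(0.2, 0.1, 0.05),
                            tremor_prevalence = 0.3, tremor_burst_duration = 10,
                            adl_level = 0.08, label_noise = 0) {
  if (f0 < 3 || f0 > 9) stop("f0 must lie in [3, 9] Hz")
  if (length(harmonic_amps) != 3L || any(harmonic_amps < 0))
    stop("harmonic_amps must be 3 non-negative values")
  if (tremor_prevalence < 0 || tremor_prevalence > 1)
    stop("tremor_prevalence must lie in [0, 1]")
  if (label_noise < 0 || label_noise > 1) stop("label_noise must lie in [0, 1]")
  structure(list(subject_id = subject_id, f0 = f0,
                 harmonic_amps = harmonic_amps,
                 tremor_prevalence = tremor_prevalence,
                 tremor_burst_duration = tremor_burst_duration,
                 adl_level = adl_level, label_noise = label_noise),
            class = "subject_profile")
}

# band-limited (0-3 Hz) background motion at the requested RMS
adl_component <- function(n, fs, rms) {
  if (rms <= 0) return(numeric(n))
  bf <- signal::butter(4, 3 / (fs / 2), type = "low")
  v <- signal::filtfilt(bf, stats::rnorm(n))
  v * rms / stats::sd(v)
}

# Hann-shaped on/off ramps (0.5 s) around a flat top
burst_envelope <- function(n_samp, fs) {
  ramp <- min(round(0.5 * fs), n_samp %/% 2L)
  env <- rep(1, n_samp)
  if (ramp > 0L) {
    r <- 0.5 - 0.5 * cos(pi * (seq_len(ramp) - 0.5) / ramp)
    env[seq_len(ramp)] <- r
    env[n_samp - seq_len(ramp) + 1L] <- r
  }
  env
}

#' Generate one synthetic wrist recording with ground-truth tremor intervals
#'
#' Produces a 100 Hz triaxial recording: gravity offset with slow orientation
#' drift, sub-3 Hz ADL motion, brief broadband ADL transients (impacts and
#' abrupt manipulations, whose energy spills into the 3-9 Hz tremor band the
#' way real daily activities do), Poisson-started tremor bursts (sinusoid at
#' f0 with 2f0/3f0 harmonics, random phase per axis, Hann on/off ramps) and
#' white sensor noise. The returned interval set is the exact burst extents.
#' Deterministic for a given seed.
#'
#' @param profile a [subject_profile()].
#' @param duration_s recording length in seconds (>= 60).
#' @param seed integer seed.
#' @param hand `"left"` or `"right"`.
#' @param noise_sd sensor-noise standard deviation (default 0.01 g).
#' @param transient_rate expected broadband ADL transients per second
#'   (default 0.1, i.e. one jolt every 10 s of active wear).
#' @return list with `recording` (an `accel_recording` at 100 Hz) and
#'   `intervals` (a `tremor_intervals`).
#' @export
gen_recording <- function(profile, duration_s = 600, seed = 1L,
                          hand = c("left", "right"), noise_sd = 0.01,
                          transient_rate = 0.1) {
  if (!inherits(profile, "subject_profile")) stop("invalid profile")
  if (duration_s < 60) stop("duration_s must be at least 60 s")
  hand <- match.arg(hand)
  set.seed(seed)
  fs <- 100L
  n <- as.integer(round(duration_s * fs))
  t <- (seq_len(n) - 1L) / fs

  # gravity direction with slow (< 0.3 Hz) orientation drift
  g0 <- stats::rnorm(3)
  g0 <- g0 / sqrt(sum(g0^2))
  data <- matrix(0, n, 3L)
  for (a in 1:3) {
    drift <- 0.05 * sin(2 * pi * stats::runif(1, 0.01, 0.05) * t +
                          stats::runif(1, 0, 2 * pi)) +
             0.03 * sin(2 * pi * stats::runif(1, 0.05, 0.1) * t +
                          stats::runif(1, 0, 2 * pi))
    data[, a] <- g0[a] + drift + adl_component(n, fs, profile$adl_level)
  }

  # broadband ADL transients: exponentially damped noise jolts (wrist impacts
  # and abrupt manipulations reach a sizable fraction of 1 g and are broadband)
  n_trans <- stats::rpois(1, transient_rate * duration_s)
  if (n_trans > 0 && profile$adl_level > 0) {
    for (tr in seq_len(n_trans)) {
      tl <- as.integer(round(stats::runif(1, 0.2, 0.6) * fs))
      env <- exp(-(seq_len(tl) - 1L) / (0.08 * fs))
      i0 <- sample.int(n - tl, 1L)
      amp <- stats::runif(1, 0.3, 1)
      for (a in 1:3) {
        data[i0:(i0 + tl - 1L), a] <- data[i0:(i0 + tl - 1L), a] +
          amp * stats::runif(1, 0.3, 1) * env * stats::rnorm(tl)
      }
    }
  }

  # tremor bursts: Poisson-distributed starts, gamma-distributed durations
  p <- profile$tremor_prevalence
  starts <- ends <- numeric(0)
  if (p > 0) {
    mean_gap <- profile$tremor_burst_duration * (1 - p) / max(p, 1e-3)
    cur <- stats::rexp(1, 1 / max(mean_gap, 1e-3))
    while (cur < duration_s - 1) {
      dur <- max(1, stats::rgamma(1, shape = 2,
                                  scale = profile$tremor_burst_duration / 2))
      e <- min(cur + dur, duration_s)
      starts <- c(starts, cur); ends <- c(ends, e)
      cur <- e + stats::rexp(1, 1 / max(mean_gap, 1e-3))
    }
  }
  axis_w <- stats::runif(3, 0.5, 1)
  for (b in seq_along(starts)) {
    i0 <- floor(starts[b] * fs) + 1L
    i1 <- min(ceiling(ends[b] * fs), n)
    idx <- i0:i1
    env <- burst_envelope(length(idx), fs)
    fb <- profile$f0 + stats::runif(1, -0.05, 0.05)
    for (a in 1:3) {
      wave <- numeric(length(idx))
      for (k in 1:3) {
        if (k * fb >= 50) next
        wave <- wave + profile$harmonic_amps[k] *
          sin(2 * pi * k * fb * t[idx] + stats::runif(1, 0, 2 * pi))
      }
      data[, a][idx] <- data[, a][idx] + axis_w[a] * env * wave
    }
  }
  data <- data + matrix(stats::rnorm(n * 3L, sd = noise_sd), n, 3L)

  rec <- accel_recording(data, fs, subject_id = profile$subject_id,
                         hand = hand, units = "g")
  tiv <- if (length(starts)) tremor_intervals(starts, ends, hand = hand)
         else tremor_intervals(hand = hand)
  list(recording = rec, intervals = tiv)
}

#' Derive 5-minute weak diary labels from ground-truth intervals
#'
#' One entry per `entry_period_s` seconds (end-anchored: the entry covers the
#' five minutes before each period boundary, mirroring a prompt-driven diary
#' app). The true tremor fraction in the entry maps through the <33 / 33-66 /
#' >66 percent rule; with probability `label_noise` the label shifts one
#' level (clamped at the ends).
#'
#' @param intervals a `tremor_intervals` with the true burst extents.
#' @param duration_s recording length in seconds (must cover >= 1 entry).
#' @param entry_period_s spacing of diary prompts (default 3600 s; must be
#'   >= 300).
#' @param profile the [subject_profile()] (supplies `subject_id` and
#'   `label_noise`).
#' @param seed integer seed for the label noise.
#' @return data frame with columns `subject`, `hand`, `start`, `end`,
#'   `label`, `true_fraction`.
#' @export
gen_weak_labels <- function(intervals, duration_s, entry_period_s = 3600,
                            profile, seed = 1L) {
  if (entry_period_s < 300) stop("entry_period_s must be >= 300 s")
  n_entries <- floor(duration_s / entry_period_s)
  if (n_entries < 1L) stop("duration covers no diary entry")
  set.seed(seed)
  ends <- seq_len(n_entries) * entry_period_s
  rows <- lapply(ends, function(e) {
    s <- e - 300
    frac <- interval_total_time(intervals, s, e) / 300
    lab <- percent_to_weak_label(100 * frac)
    if (stats::runif(1) < profile$label_noise) {
      o <- match(lab, weak_label_levels) - 1L
      o <- min(max(o + sample(c(-1L, 1L), 1L), 0L), 2L)
      lab <- weak_label_levels[o + 1L]
    }
    data.frame(subject = profile$subject_id, hand = attr(intervals, "hand"),
               start = s, end = e, label = lab, true_fraction = frac)
  })
  do.call(rbind, rows)
}

#' Default cohort configuration
#'
#' Study conditions for the synthetic cohort: 20-minute recordings per hand
#' at 100 Hz, diary entries every 5 minutes (a dense diary so the weak
#' supervision path is exercised), per-subject tremor prevalence spread
#' evenly from 3% to 70% (so the cohort always contains a low- and a
#' high-prevalence subject), base frequencies in 4-8 Hz, tremor amplitudes
#' 0.08-0.3 g with decaying harmonics, ADL levels 0.05-0.12 g RMS, and 5%
#' diary label noise.
#'
#' @param duration_s recording length per hand (default 1200 s).
#' @param entry_period_s diary prompt spacing (default 300 s).
#' @param prevalence_range range of per-subject tremor prevalences.
#' @param label_noise diary mislabel probability.
#' @return named list of generator settings.
#' @export
cohort_config <- function(duration_s = 1200, entry_period_s = 300,
                          prevalence_range = c(0.03, 0.70),
                          label_noise = 0.05) {
  list(duration_s = duration_s, entry_period_s = entry_period_s,
       prevalence_range = prevalence_range, label_noise = label_noise)
}

#' Generate a synthetic cohort (both hands, intervals, weak labels)
#'
#' Draws one [subject_profile()] per subject (prevalences spread evenly over
#' `prevalence_range`, other parameters sampled from the configured ranges)
#' and generates a 100 Hz recording, ground-truth tremor intervals and weak
#' diary labels for each hand. A manifest records every profile and seed.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param seed integer master seed; all randomness derives from it.
#' @param config a [cohort_config()].
#' @return an object of class `synthetic_cohort`: list with `subjects` (each
#'   holding `profile` and per-hand `recording`, `intervals`, `weak_labels`),
#'   `weak_labels` (all entries combined), `config`, `manifest`.
#' @export
gen_cohort <- function(n_subjects = 6L, seed = 1L, config = cohort_config()) {
  if (n_subjects < 2L) stop("need at least 2 subjects")
  set.seed(seed_mix(seed, 0L))
  prev <- seq(config$prevalence_range[1L], config$prevalence_range[2L],
              length.out = n_subjects)
  subjects <- vector("list", n_subjects)
  all_weak <- list()
  for (i in seq_len(n_subjects)) {
    base_amp <- stats::runif(1, 0.08, 0.3)
    prof <- subject_profile(
      subject_id = sprintf("s%02d", i),
      f0 = stats::runif(1, 4, 8),
      harmonic_amps = base_amp * c(1, stats::runif(1, 0.3, 0.6),
                                   stats::runif(1, 0.1, 0.3)),
      tremor_prevalence = prev[i],
      tremor_burst_duration = stats::runif(1, 5, 15),
      adl_level = stats::runif(1, 0.05, 0.12),
      label_noise = config$label_noise)
    hands <- list()
    for (h in c("left", "right")) {
      k <- i * 10L + match(h, c("left", "right"))
      g <- gen_recording(prof, config$duration_s, seed = seed_mix(seed, k),
                         hand = h)
      wl <- gen_weak_labels(g$intervals, config$duration_s,
                            config$entry_period_s, prof,
                            seed = seed_mix(seed, k + 100L))
      hands[[h]] <- list(recording = g$recording, intervals = g$intervals,
                         weak_labels = wl)
      all_weak[[length(all_weak) + 1L]] <- wl
    }
    subjects[[i]] <- list(profile = prof, left = hands$left,
                          right = hands$right)
  }
  structure(list(subjects = subjects,
                 weak_labels = do.call(rbind, all_weak),
                 config = config,
                 manifest = list(seed = seed, n_subjects = n_subjects,
                                 profiles = lapply(subjects, function(s)
                                   unclass(s$profile)))),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects x 2 hands, %.0f s per recording, %d diary entries\n",
              length(x$subjects), x$config$duration_s, nrow(x$weak_labels)))
  invisible(x)
}

#' Preprocess and featurize a whole cohort
#'
#' Runs every recording through the standard pipeline (downsample to 50 Hz,
#' gravity high-pass, 3-s windows, >50%-overlap labels), factorizes each
#' subject-hand's windows (personalized dictionaries), and computes the
#' requested feature sets. Heavy inputs for the CNNs (raw windows, stacked
#' tremor/non-tremor spectra) are kept only on request.
#'
#' @param cohort a `synthetic_cohort`.
#' @param sets feature sets to compute (see [compute_features()]).
#' @param keep_windows keep the raw `n x 3 x 150` window array?
#' @param keep_tnt keep the stacked `n x 9 x 128` CNN-T/NT input?
#' @param personalize_dict,n_iter passed to [factorize_windows()].
#' @return list with `meta` (data frame: `subject`, `hand`, `start_s`,
#'   `label`), `energy` (per-window factorized tremor energy), `features`
#'   (named list of matrices), and optionally `windows`, `tnt`.
#' @export
cohort_pipeline <- function(cohort, sets = c("energy", "mfcc_tnt"),
                            keep_windows = FALSE, keep_tnt = FALSE,
                            personalize_dict = TRUE, n_iter = 100L) {
  meta <- list(); energy <- list(); feats <- list(); wins <- list(); tnt <- list()
  for (s in cohort$subjects) for (h in c("left", "right")) {
    rec <- s[[h]]$recording
    ws <- make_windows(highpass_gravity(resample_to_50hz(rec)))
    ws <- label_windows(ws, s[[h]]$intervals)
    ntf <- factorize_windows(ws, personalize_dict = personalize_dict,
                             n_iter = n_iter)
    meta[[length(meta) + 1L]] <- data.frame(
      subject = ws$subject_id, hand = ws$hand, start_s = ws$start_s,
      label = ws$label)
    energy[[length(energy) + 1L]] <- ntf$energy
    fl <- lapply(sets, function(set)
      compute_features(ws, set, ntf = if (set == "mfcc_tnt") ntf else NULL))
    names(fl) <- sets
    feats[[length(feats) + 1L]] <- fl
    if (keep_windows)
      wins[[length(wins) + 1L]] <- aperm(ws$windows, c(1L, 3L, 2L))
    if (keep_tnt) tnt[[length(tnt) + 1L]] <- stack_tnt_input(ntf)
  }
  bind_arrays <- function(lst) {
    d <- dim(lst[[1L]])
    out <- array(0, dim = c(sum(vapply(lst, function(a) dim(a)[1L], 0)), d[2L], d[3L]))
    at <- 0L
    for (a in lst) {
      out[at + seq_len(dim(a)[1L]), , ] <- a
      at <- at + dim(a)[1L]
    }
    out
  }
  out <- list(meta = do.call(rbind, meta), energy = unlist(energy),
              features = lapply(sets, function(set)
                do.call(rbind, lapply(feats, `[[`, set))))
  names(out$features) <- sets
  if (keep_windows) out$windows <- bind_arrays(wins)
  if (keep_tnt) out$tnt <- bind_arrays(tnt)
  out
}

# ---- plain-text cohort serialization (CLI interface) ------------------------

#' Write / read tremor intervals and weak labels as JSON
#'
#' Interval JSON: an array of `{"start": s, "end": s, "hand": "left"}`
#' objects. Weak-label JSON: an array of
#' `{"subject", "hand", "start", "end", "label"}` objects.
#'
#' @param tiv a `tremor_intervals`.
#' @param path output / input file path.
#' @return the read object, or `path` invisibly for writers.
#' @export
write_intervals <- function(tiv, path) {
  df <- data.frame(start = tiv$start, end = tiv$end,
                   hand = attr(tiv, "hand"))
  jsonlite::write_json(df, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(df) == 0L || nrow(df) == 0L) return(tremor_intervals())
  tremor_intervals(df$start, df$end, hand = df$hand[1L])
}

#' @rdname write_intervals
#' @param weak a weak-label data frame (see [gen_weak_labels()]).
#' @export
write_weak_labels <- function(weak, path) {
  jsonlite::write_json(weak[c("subject", "hand", "start", "end", "label")],
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_weak_labels <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(df$label %in% weak_label_levels)) stop("unknown weak label in ", path)
  df
}

#' Write a whole synthetic cohort to a directory
#'
#' One recording CSV (+ JSON sidecar) per subject-hand, interval and
#' weak-label JSONs, and a manifest.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects) for (h in c("left", "right")) {
    stem <- file.path(dir, paste0(s$profile$subject_id, "_", h))
    write_recording(s[[h]]$recording, paste0(stem, ".csv"))
    write_intervals(s[[h]]$intervals, paste0(stem, "_intervals.json"))
    write_weak_labels(s[[h]]$weak_labels, paste0(stem, "_weak.json"))
  }
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir the cohort directory.
#' @return a `synthetic_cohort`-shaped list usable with [cohort_pipeline()].
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE, simplifyDataFrame = FALSE)
  ids <- vapply(man$profiles, function(p) p$subject_id, "")
  subjects <- lapply(seq_along(ids), function(i) {
    out <- list(profile = do.call(subject_profile, man$profiles[[i]]))
    for (h in c("left", "right")) {
      stem <- file.path(dir, paste0(ids[i], "_", h))
      out[[h]] <- list(
        recording = load_recording(paste0(stem, ".csv")),
        intervals = read_intervals(paste0(stem, "_intervals.json")),
        weak_labels = read_weak_labels(paste0(stem, "_weak.json")))
    }
    out
  })
  weak <- do.call(rbind, unlist(lapply(subjects, function(s)
    list(s$left$weak_labels, s$right$weak_labels)), recursive = FALSE))
  structure(list(subjects = subjects, weak_labels = weak,
                 config = NULL, manifest = man),
            class = "synthetic_cohort")
}
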