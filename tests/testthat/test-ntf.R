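test_that("dictionary has 60 tremor atoms, a ones row, and 63 Hann bases", {
  d <- build_dictionary()
  expect_equal(nrow(d$T), 61L)
  expect_equal(length(d$base_freqs), 60L)
  expect_equal(nrow(d$H), 63L)
  expect_identical(d$A, d$H)
  expect_true(all(d$T >= 0) && all(d$H >= 0))
  expect_true(all(rowSums(d$H) > 0))
  expect_equal(diff(d$base_freqs), rep(0.1, 59), tolerance = 1e-9)
  expect_true(all(d$base_freqs >= 3 & d$base_freqs < 9))
  expect_equal(d$T[61L, ], rep(1, 128))

  # the f0 = 5.0 row peaks at the grid bin nearest 5 Hz (direct construction)
  i5 <- which.min(abs(d$base_freqs - 5))
  expect_equal(which.max(d$T[i5, ]), which.min(abs(freq_grid() - 5)))

  expect_error(build_dictionary(1:64), "128")
})

test_that("multiplicative updates keep weights non-negative and descend", {
  d <- build_dictionary()
  expect_error(factorize(-freq_grid(), d), "non-negative")

  w0 <- factorize(rep(0, 128), d)
  expect_true(all(w0$wt[1, 1:60] == 0))
  tr0 <- split_spectra(w0, d, rep(0, 128))
  expect_equal(sum(tr0$tremor) + sum(tr0$nontremor), 0, tolerance = 1e-20)

  set.seed(11)
  S <- matrix(runif(30 * 128), 30, 128)
  w <- factorize(S, d)
  expect_true(all(w$wt >= 0) && all(w$wh >= 0) && all(w$wa >= 0))
  expect_true(all(is.finite(w$objective_trace)))
  rel_inc <- (w$objective_trace[, -1] - w$objective_trace[, -100]) /
    pmax(w$objective_trace[, -100], 1e-300)
  expect_lt(max(rel_inc), 1e-9)
})

test_that("split spectra satisfy the additive reconstruction identity", {
  d <- build_dictionary()
  set.seed(12)
  S <- matrix(runif(5 * 128), 5, 128)
  w <- factorize(S, d)
  tr <- split_spectra(w, d, S)
  recon <- (w$wt %*% d$T) * (w$wh %*% d$H) + w$wa %*% d$A
  expect_equal(tr$tremor + tr$nontremor, recon, tolerance = 1e-12)

  # spectrum with energy only below 3 Hz: almost nothing lands in tremor part
  adl <- exp(-freq_grid())
  adl[freq_grid() >= 3] <- 0
  wa <- factorize(adl, d)
  ta <- split_spectra(wa, d, adl)
  expect_lt(sum(ta$tremor^2) / sum((ta$tremor + ta$nontremor)^2), 0.10)
})

test_that("personalization finds f0 in 4-8 Hz and refuses degenerate input", {
  d <- build_dictionary()
  grid <- freq_grid()
  bump <- function(f) exp(-0.5 * ((grid - f) / 0.3)^2)

  p6 <- personalize(d, bump(6))
  expect_true(p6$personalized)
  expect_lt(abs(p6$f0 - 6), 50 / 256 + 1e-9)
  expect_equal(p6$T[61L, ], rep(1, 128))         # ones row untouched
  expect_true(all(abs(apply(p6$T[1:60, ], 1, max) - 1) < 1e-12))

  # peak search is confined to 4-8 Hz: a taller bump at 3.2 Hz is ignored
  p36 <- personalize(d, 3 * bump(3.2) + bump(6))
  expect_lt(abs(p36$f0 - 6), 50 / 256 + 1e-9)

  expect_warning(pf <- personalize(d, rep(1, 128)), "refused")
  expect_false(pf$personalized)
  expect_warning(pz <- personalize(d, rep(0, 128)), "refused")
  expect_false(pz$personalized)
})

test_that("the f0 constraint keeps the three largest in-band weights", {
  d <- build_dictionary()
  pd <- personalize(d, exp(-0.5 * ((freq_grid() - 5) / 0.3)^2))
  w <- factorize(rep(0, 128), pd)
  # plant weights at 4.2 / 4.9 / 5.0 / 5.1 / 6.5 Hz with values 1/2/5/3/9
  at <- function(f) which.min(abs(d$base_freqs - f))
  w$wt[1, ] <- 0
  w$wt[1, at(4.2)] <- 1; w$wt[1, at(4.9)] <- 2; w$wt[1, at(5.0)] <- 5
  w$wt[1, at(5.1)] <- 3; w$wt[1, at(6.5)] <- 9
  out <- constrain_to_f0(w, pd)
  kept <- which(out$wt[1, 1:60] > 0)
  expect_setequal(kept, c(at(4.9), at(5.0), at(5.1)))

  # all-zero weights unchanged; applying twice = applying once
  wz <- factorize(rep(0, 128), pd)
  expect_equal(constrain_to_f0(wz, pd)$wt, wz$wt)
  expect_equal(constrain_to_f0(out, pd)$wt, out$wt)
  expect_error(constrain_to_f0(w, d), "personalized")
})

test_that("thresholding is idempotent", {
  d <- build_dictionary()
  set.seed(13)
  S <- matrix(runif(3 * 128), 3, 128)
  w <- factorize(S, d)
  thr <- w$wt[, 61L]
  again <- w$wt
  again[, 1:60][again[, 1:60] < thr] <- 0
  expect_identical(again, w$wt)
})

test_that("tremor energy is a quadratic, rank-preserving statistic", {
  d <- build_dictionary()
  set.seed(14)
  S <- matrix(runif(2 * 128), 2, 128)
  w <- factorize(S, d)
  tr <- split_spectra(w, d, S)
  e <- tremor_energy(tr)
  expect_gte(e, 0)
  tr2 <- tr; tr2$tremor <- 2 * tr2$tremor
  expect_equal(tremor_energy(tr2), 4 * e, tolerance = 1e-12)
  trz <- tr; trz$tremor <- 0 * trz$tremor
  expect_equal(tremor_energy(trz), 0)
})

test_that("factorized energy ranks tremor windows above ADL windows", {
  set.seed(15)
  prof_t <- subject_profile("t", f0 = 6, tremor_prevalence = 1, adl_level = 0)
  prof_a <- subject_profile("a", f0 = 6, tremor_prevalence = 0, adl_level = 0.1)
  prep <- function(p, seed) {
    g <- gen_recording(p, 90, seed = seed)
    make_windows(highpass_gravity(resample_to_50hz(g$recording)))
  }
  rt <- factorize_windows(prep(prof_t, 21), personalize_dict = FALSE)
  ra <- factorize_windows(prep(prof_a, 22), personalize_dict = FALSE)
  expect_gte(mean(outer(rt$energy, ra$energy, ">")), 0.95)
  expect_equal(tremor_energy(rt), rt$energy)
})
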