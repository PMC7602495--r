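#' Build the fixed tremor / shape / non-tremor dictionaries
#'
#' The tremor dictionary `T` holds N = 60 "ideal" tremor spectra with base
#' frequencies every 0.1 Hz on \[3, 9) Hz, each the sum of three rectified
#' sinc lobes at f0, 2*f0 and 3*f0 (tremor and its first two harmonics), plus
#' a final all-ones row that models motionless windows and doubles as the
#' weight threshold. The shape dictionary `H` (and the identical non-tremor
#' dictionary `A`) holds M = 63 Hann bumps of width 5 grid points spread over
#' the frequency axis with 50% overlap.
#'
#' Each harmonic contributes only the main lobe of a rectified sinc
#' (truncated at its first zeros), with half-width one grid step
#' (50/256 Hz); lobes above 25 Hz are dropped. Compact, near-impulsive
#' tremor atoms keep the tremor / non-tremor split identifiable: with wide
#' overlapping sinc tails the Hann basis can absorb most tremor energy
#' within the fixed iteration budget. Harmonic amplitudes decay as
#' 1, 1/2, 1/4, mimicking typical harmonic roll-off. Every tremor row and
#' the ones row peak at 1, so the weights `wt` are mutually comparable —
#' the thresholding and f0-constraint steps depend on that.
#'
#' @param grid frequency grid; must be the shared 128-point [freq_grid()].
#' @return an object of class `tremor_dictionary`: list with matrices `T`
#'   (61 x 128), `H`, `A` (63 x 128), `base_freqs` (60 values),
#'   `grid`, `personalized` flag and optional `f0`.
#' @export
build_dictionary <- function(grid = freq_grid()) {
  if (length(grid) != 128L) stop("dictionary grid must have 128 points")
  base_freqs <- seq(3, 8.9, by = 0.1)
  delta <- 50 / 256                       # one grid step
  amps <- c(1, 0.5, 0.25)
  sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))
  Tm <- matrix(0, 61L, 128L)
  for (i in seq_along(base_freqs)) {
    f0 <- base_freqs[i]
    row <- numeric(128L)
    for (k in 1:3) {
      fk <- k * f0
      if (fk > 25) next
      lobe <- abs(sinc((grid - fk) / delta))
      lobe[abs(grid - fk) > delta] <- 0    # main lobe only
      row <- row + amps[k] * lobe
    }
    Tm[i, ] <- row
  }
  Tm[61L, ] <- 1
  hann5 <- 0.5 - 0.5 * cos(2 * pi * (0:4) / 4)  # 0, .5, 1, .5, 0
  centers <- seq(3L, 127L, by = 2L)             # 63 centers, 50% overlap
  H <- matrix(0, 63L, 128L)
  for (j in seq_along(centers)) {
    idx <- centers[j] + (-2:2)
    ok <- idx >= 1L & idx <= 128L
    H[j, idx[ok]] <- hann5[ok]
  }
  structure(list(T = Tm, H = H, A = H, base_freqs = base_freqs, grid = grid,
                 personalized = FALSE, f0 = NULL),
            class = "tremor_dictionary")
}

#' @export
print.tremor_dictionary <- function(x, ...) {
  cat(sprintf("<tremor_dictionary> %d tremor spectra (%.1f-%.1f Hz) + ones row; %d Hann shape bases%s\n",
              length(x$base_freqs), min(x$base_freqs), max(x$base_freqs),
              nrow(x$H),
              if (x$personalized) sprintf("; personalized (f0 = %.2f Hz)", x$f0) else ""))
  invisible(x)
}

#' Factorize amplitude spectra into tremor and non-tremor parts
#'
#' Minimizes `||S_total - S_hat||^2` with
#' `S_hat = (wt T) * (wh H) + wa A` (elementwise product) by multiplicative
#' updates, cycling wt, wh, wa and recomputing the reconstruction after every
#' update. Weights start at 1 (deterministic) and stay non-negative.
#' After the final iteration the weight of the all-ones row acts as a
#' threshold: every tremor weight below it is set to zero.
#'
#' Several spectra can be factorized at once (rows of a matrix); the updates
#' are vectorized across rows, which is how whole recordings are processed.
#'
#' @param S_total non-negative spectrum (length-128 vector) or `n x 128`
#'   matrix of spectra.
#' @param dict a `tremor_dictionary`.
#' @param n_iter number of multiplicative update sweeps (default 100).
#' @param eps denominator floor guarding 0/0 (default 1e-12).
#' @return an object of class `ntf_weights`: list with matrices `wt`
#'   (`n x 61`), `wh`, `wa` (`n x 63`), `n_iter`, and `objective_trace`
#'   (`n x n_iter`, the squared reconstruction error after each sweep).
#' @export
factorize <- function(S_total, dict, n_iter = 100L, eps = 1e-12) {
  S <- if (is.matrix(S_total)) S_total else matrix(S_total, nrow = 1L)
  if (ncol(S) != 128L) stop("spectra must live on the shared 128-point grid")
  if (any(S < 0)) stop("input spectrum must be non-negative")
  n <- nrow(S)
  Tm <- dict$T; H <- dict$H; A <- dict$A
  wt <- matrix(1, n, 61L); wh <- matrix(1, n, 63L); wa <- matrix(1, n, 63L)
  trace <- matrix(NA_real_, n, n_iter)
  tT <- t(Tm); tH <- t(H); tA <- t(A)
  for (it in seq_len(n_iter)) {
    source <- wt %*% Tm; shape <- wh %*% H
    shat <- source * shape + wa %*% A
    wt <- wt * ((shape * S) %*% tT) / pmax((shape * shat) %*% tT, eps)
    source <- wt %*% Tm
    shat <- source * shape + wa %*% A
    wh <- wh * ((source * S) %*% tH) / pmax((source * shat) %*% tH, eps)
    shape <- wh %*% H
    shat <- source * shape + wa %*% A
    wa <- wa * (S %*% tA) / pmax(shat %*% tA, eps)
    shat <- source * shape + wa %*% A
    trace[, it] <- rowSums((S - shat)^2)
  }
  # all-ones-row weight thresholds the tremor weights
  thr <- wt[, 61L]
  wt[, 1:60][wt[, 1:60] < thr] <- 0
  structure(list(wt = wt, wh = wh, wa = wa, n_iter = n_iter,
                 objective_trace = trace),
            class = "ntf_weights")
}

#' Personalize the tremor dictionary to one subject
#'
#' Shapes the 60 ideal tremor spectra by the subject's average power spectrum
#' (max-normalized; the all-ones row is untouched) and estimates the subject's
#' base tremor frequency f0 as the highest strict local maximum of the average
#' spectrum within 4-8 Hz. After the multiplication each tremor row is
#' renormalized to unit maximum: the shaping must change each atom's profile,
#' not its scale, or the weight threshold and the "three maximum weights"
#' constraint would compare weights of incommensurate rows. If the average
#' spectrum is all zero or has no strict local maximum in that band,
#' personalization is refused and an unpersonalized copy is returned with a
#' warning.
#'
#' @param dict a `tremor_dictionary`.
#' @param avg_spectrum length-128 non-negative mean power spectrum over the
#'   subject's windows (see [subject_avg_spectrum()]).
#' @return the personalized dictionary (flag set, `f0` recorded).
#' @export
personalize <- function(dict, avg_spectrum) {
  if (length(avg_spectrum) != 128L) stop("avg_spectrum must have 128 points")
  if (any(avg_spectrum < 0)) stop("avg_spectrum must be non-negative")
  refuse <- function(msg) {
    warning("personalization refused: ", msg)
    dict$personalized <- FALSE
    dict
  }
  if (all(avg_spectrum == 0)) return(refuse("average spectrum is all zero"))
  grid <- dict$grid
  band <- which(grid >= 4 & grid <= 8)
  s <- avg_spectrum
  is_peak <- vapply(band, function(i) {
    i > 1L && i < 128L && s[i] > s[i - 1L] && s[i] > s[i + 1L]
  }, logical(1))
  if (!any(is_peak)) return(refuse("no strict local maximum in 4-8 Hz"))
  peaks <- band[is_peak]
  f0 <- grid[peaks[which.max(s[peaks])]]
  shape <- avg_spectrum / max(avg_spectrum)
  Tp <- sweep(dict$T[1:60, , drop = FALSE], 2L, shape, `*`)
  mx <- apply(Tp, 1L, max)
  Tp[mx > 0, ] <- Tp[mx > 0, , drop = FALSE] / mx[mx > 0]
  dict$T[1:60, ] <- Tp
  dict$personalized <- TRUE
  dict$f0 <- f0
  dict
}

#' Average power spectrum of a subject's windows
#'
#' Mean over windows of the squared amplitude spectra, averaged over the three
#' axes — the input [personalize()] expects.
#'
#' @param spectra `n x 3 x 128` amplitude spectra (from [window_spectra()]).
#' @return length-128 mean power spectrum.
#' @export
subject_avg_spectrum <- function(spectra) {
  apply(spectra^2, 3L, mean)
}

#' Constrain tremor weights to a personalized base frequency
#'
#' Among the tremor weights whose base frequency lies within +/- 1 Hz of the
#' personalized f0, only the three largest survive; all other tremor weights
#' (including those outside the interval) are zeroed. Ties break toward the
#' lower base frequency. The threshold (ones-row) weight is untouched.
#' Applied once, after the final update sweep and after thresholding.
#'
#' @param w an `ntf_weights` object.
#' @param dict the personalized `tremor_dictionary` used to produce `w`.
#' @return `w` with constrained tremor weights.
#' @export
constrain_to_f0 <- function(w, dict) {
  if (!isTRUE(dict$personalized)) stop("constrain_to_f0 needs a personalized dictionary")
  f0 <- dict$f0
  in_band <- which(dict$base_freqs >= f0 - 1 & dict$base_freqs <= f0 + 1)
  wt <- w$wt
  for (r in seq_len(nrow(wt))) {
    v <- wt[r, 1:60]
    keep <- in_band[order(-v[in_band], in_band)][seq_len(min(3L, length(in_band)))]
    keep <- keep[v[keep] > 0]
    nv <- numeric(60L)
    nv[keep] <- v[keep]
    wt[r, 1:60] <- nv
  }
  w$wt <- wt
  w
}

#' Split a total spectrum into tremor and non-tremor parts
#'
#' Reconstructs `tremor = (wt T) * (wh H)` and `nontremor = wa A`; by
#' construction `tremor + nontremor` equals the factorization's
#' reconstruction of the total spectrum.
#'
#' @param w an `ntf_weights` object (n rows).
#' @param dict the `tremor_dictionary` used to produce `w`.
#' @param S_total the spectra that were factorized (vector or `n x 128`).
#' @return an object of class `spectrum_triple`: list of `n x 128` matrices
#'   `total`, `tremor`, `nontremor` (single-row inputs are returned as
#'   vectors inside 1 x 128 matrices).
#' @export
split_spectra <- function(w, dict, S_total) {
  S <- if (is.matrix(S_total)) S_total else matrix(S_total, nrow = 1L)
  if (nrow(S) != nrow(w$wt)) stop("spectrum / weight row mismatch")
  tremor <- (w$wt %*% dict$T) * (w$wh %*% dict$H)
  nontremor <- w$wa %*% dict$A
  structure(list(total = S, tremor = tremor, nontremor = nontremor),
            class = "spectrum_triple")
}

#' Tremor energy of factorized windows
#'
#' Sum of squared tremor-spectrum amplitudes over axes — the unsupervised
#' ranking statistic used to initialize multiple-instance learning.
#'
#' @param x a `spectrum_triple` (rows summed together as axes of one window)
#'   or an `ntf_result` from [factorize_windows()] (returns one energy per
#'   window).
#' @return non-negative scalar, or a vector for `ntf_result`.
#' @export
tremor_energy <- function(x) {
  if (inherits(x, "ntf_result")) return(x$energy)
  if (!inherits(x, "spectrum_triple")) stop("need a spectrum_triple or ntf_result")
  sum(x$tremor^2)
}

#' Run the tremor factorization over a whole window set
#'
#' Computes Hamming-tapered amplitude spectra, optionally personalizes the
#' dictionary from the subject's average power spectrum (and then constrains
#' each window's tremor weights around the personalized f0), factorizes every
#' axis of every window, and assembles per-window spectrum triples and tremor
#' energies.
#'
#' @param ws a `window_set` (typically one subject-hand recording).
#' @param dict a `tremor_dictionary`; default builds the standard one.
#' @param personalize_dict personalize to this window set's average spectrum?
#' @param n_iter update sweeps per factorization (default 100).
#' @return an object of class `ntf_result`: list with `spectra`
#'   (`n x 3 axes x 3 kinds x 128`, kinds = total/tremor/nontremor),
#'   `energy` (length n), and the (possibly personalized) `dict`.
#' @export
factorize_windows <- function(ws, dict = build_dictionary(),
                              personalize_dict = TRUE, n_iter = 100L) {
  sp <- window_spectra(ws, taper = "hamming")
  n <- dim(sp)[1L]
  if (personalize_dict && n > 0L)
    dict <- suppressWarnings(personalize(dict, subject_avg_spectrum(sp)))
  out <- array(0, dim = c(n, 3L, 3L, 128L))
  if (n > 0L) {
    for (a in 1:3) {
      S <- matrix(sp[, a, ], n, 128L)
      w <- factorize(S, dict, n_iter = n_iter)
      if (isTRUE(dict$personalized)) w <- constrain_to_f0(w, dict)
      tr <- split_spectra(w, dict, S)
      out[, a, 1L, ] <- tr$total
      out[, a, 2L, ] <- tr$tremor
      out[, a, 3L, ] <- tr$nontremor
    }
  }
  energy <- if (n > 0L) apply(out[, , 2L, , drop = FALSE]^2, 1L, sum) else numeric()
  structure(list(spectra = out, energy = energy, dict = dict,
                 subject_id = ws$subject_id, hand = ws$hand,
                 start_s = ws$start_s),
            class = "ntf_result")
}

#' @export
print.ntf_result <- function(x, ...) {
  cat(sprintf("<ntf_result> %d windows, subject %s (%s hand)%s\n",
              dim(x$spectra)[1L], x$subject_id, x$hand,
              if (isTRUE(x$dict$personalized))
                sprintf(", personalized f0 = %.2f Hz", x$dict$f0) else ""))
  invisible(x)
}
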