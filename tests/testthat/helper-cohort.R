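# Shared synthetic-cohort fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# the package's default study cohort: 6 subjects x 2 hands x 20 min
default_pipeline <- function() {
  if (is.null(.fixtures$pl6)) {
    coh <- gen_cohort(6, seed = 1)
    .fixtures$coh6 <- coh
    .fixtures$pl6 <- cohort_pipeline(coh, sets = c("energy", "mfcc_tnt"))
  }
  list(cohort = .fixtures$coh6, pl = .fixtures$pl6)
}

# a small 3-subject cohort with raw windows and stacked spectra for CNN tests
small_cnn_pipeline <- function() {
  if (is.null(.fixtures$pl_cnn)) {
    coh <- gen_cohort(3, seed = 9, config = cohort_config(duration_s = 300))
    .fixtures$pl_cnn <- cohort_pipeline(coh, sets = "energy",
                                        keep_windows = TRUE, keep_tnt = TRUE)
  }
  .fixtures$pl_cnn
}
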