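test_that("LOSO folds partition subjects regardless of input order", {
  subjects <- rep(paste0("s", 1:6), times = 10)
  f <- loso_folds(subjects)
  expect_length(f, 6L)
  tests <- vapply(f, `[[`, "", "test")
  expect_setequal(tests, paste0("s", 1:6))
  expect_equal(anyDuplicated(tests), 0L)
  for (k in f) expect_false(k$test %in% k$train)

  # permutation oracle: shuffled subject vector gives identical folds
  set.seed(50)
  f2 <- loso_folds(sample(subjects))
  expect_identical(f, f2)
  expect_error(loso_folds(rep("a", 5)), "2 subjects")
})

test_that("ROC metrics match the Mann-Whitney statistic and pROC", {
  skip_if_not_installed("pROC")
  perfect <- roc_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1.0)
  expect_equal(perfect$fpr_at_090_tpr, 0.0)

  set.seed(51)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    s <- round(runif(n), 2)          # induce ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    got <- roc_metrics(s, y)
    expect_equal(got$auc, mw_auc(s, y), tolerance = 1e-12)
    expect_equal(got$auc,
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }

  # permutation null: scores carry no information
  set.seed(52)
  y <- rbinom(1e4, 1, 0.5)
  expect_equal(roc_metrics(runif(1e4), y)$auc, 0.5, tolerance = 0.02)

  # invariance under strictly monotone transforms
  set.seed(53)
  s <- rnorm(200); y <- rbinom(200, 1, 0.4)
  a <- roc_metrics(s, y)
  b <- roc_metrics(exp(2 * s) + 5, y)
  expect_equal(a, b, tolerance = 1e-12)

  expect_error(roc_metrics(runif(5), rep(1, 5)), "single class")
})

test_that("Hanley-McNeil test matches the closed form and sharpens with n", {
  expect_equal(hanley_auc_significance(0.8, 0.8, 50, 50), 1.0)

  # SE at A = 0.5 with equal class sizes has an algebraic closed form
  se_direct <- function(a, np, nn) {
    q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
    sqrt((a * (1 - a) + (np - 1) * (q1 - a^2) + (nn - 1) * (q2 - a^2)) / (np * nn))
  }
  for (n in c(10, 50, 200)) {
    closed <- sqrt((0.25 + 2 * (n - 1) * (1 / 3 - 0.25)) / n^2)
    expect_equal(se_direct(0.5, n, n), closed, tolerance = 1e-12)
  }

  p <- sapply(c(20, 80, 320), function(n)
    hanley_auc_significance(0.75, 0.7, n, n))
  expect_true(all(diff(p) < 0))
  expect_error(hanley_auc_significance(1.0, 0.5, 10, 10), "inside")
  expect_error(hanley_auc_significance(0.7, 0.6, 1, 10), "2 cases")
})

test_that("percent tremor aggregates windows per period", {
  expect_equal(percent_tremor(rep(1, 40))$percent, 100)
  expect_equal(percent_tremor(rep(c(1, 0), 20))$percent, 50)
  per <- percent_tremor(c(rep(1, 60), rep(0, 60)), period_s = 60)
  expect_equal(per$percent, c(100, 0))
  expect_equal(per$period_start, c(0, 60))
})

test_that("an oracle classifier recovers the generated tremor fraction", {
  prof <- subject_profile("o", tremor_prevalence = 0.4)
  g <- gen_recording(prof, 600, seed = 55)
  ws <- label_windows(make_windows(highpass_gravity(resample_to_50hz(g$recording))),
                      g$intervals)
  est <- percent_tremor(ws$label, start_s = ws$start_s)$percent
  truth <- 100 * interval_total_time(g$intervals, 0, 600) / 600
  expect_lt(abs(est - truth), 2)
})

test_that("percent-tremor error shrinks with longer aggregation periods", {
  prof <- subject_profile("p", tremor_prevalence = 0.35)
  g <- gen_recording(prof, 1800, seed = 56)
  ws <- label_windows(make_windows(highpass_gravity(resample_to_50hz(g$recording))),
                      g$intervals)
  # noisy classifier: flip 15% of window predictions asymmetrically
  set.seed(57)
  pred <- ws$label
  flip <- runif(length(pred)) < 0.15
  pred[flip] <- 1L - pred[flip]
  err_at <- function(period) {
    est <- percent_tremor(pred, period_s = period, start_s = ws$start_s)
    tru <- vapply(est$period_start, function(s)
      100 * interval_total_time(g$intervals, s, s + period) / period, 0)
    mean(abs(est$percent - tru))
  }
  errs <- vapply(c(60, 300, 900), err_at, 0)
  expect_lt(errs[3], errs[1] + 1)   # non-increasing in expectation
})

test_that("the percent/label maps use the printed thresholds and midpoints", {
  expect_equal(percent_to_weak_label(c(10, 50, 90)),
               c("almost_none", "half_the_time", "almost_always"))
  expect_equal(percent_to_weak_label(33), "half_the_time")
  expect_equal(percent_to_weak_label(66), "half_the_time")
  expect_equal(percent_to_weak_label(32.99), "almost_none")
  expect_equal(percent_to_weak_label(66.01), "almost_always")
  expect_equal(unname(weak_label_to_percent("half_the_time")), 50)
  expect_equal(unname(weak_label_to_percent(c("almost_none", "almost_always"))),
               c(16.6, 83.3))
  expect_error(percent_to_weak_label(101), "0, 100")
})

test_that("weak-label agreement matches the rank-formula oracle", {
  expect_equal(weak_agreement(c(0, 1, 2, 1), c(0, 1, 2, 1))$rho, 1)
  expect_equal(weak_agreement(c(0, 1, 2), c(2, 1, 0))$rho, -1)

  set.seed(58)
  for (i in 1:15) {
    a <- sample(0:2, 20, replace = TRUE)
    b <- sample(0:2, 20, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(weak_agreement(a, b)$rho, rank_spearman(a, b),
                 tolerance = 1e-12)
  }

  flat <- weak_agreement(rep("almost_none", 5), rep("half_the_time", 5))
  expect_false(flat$defined)
  expect_true(is.na(flat$rho))
})
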