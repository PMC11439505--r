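make_log <- function(durations, id = "p1", study = "study1") {
  tibble::tibble(
    participant_id = id, study_id = study,
    day_index = seq_along(durations), duration = durations,
    sessions = as.integer(durations > 0), max_level = 1L,
    tasks = as.integer(durations > 0)
  )
}

test_that("adherence labeling applies the 10-minute criterion inclusively", {
  log <- make_log(c(10, 0, 9.99, 45, 10.01))
  lab <- label_adherence(log)$adherent
  expect_equal(lab, c(1L, 0L, 0L, 1L, 1L))
  # threshold is configurable
  expect_equal(label_adherence(log, threshold_minutes = 30)$adherent[4], 1L)
  expect_error(label_adherence(log, threshold_minutes = 0), "> 0")
})

test_that("chronological split takes days 1-30 and 31-60 and drops the rest", {
  parts <- split_train_test(make_log(rep(20, 60)))
  expect_equal(range(parts$train$day_index), c(1, 30))
  expect_equal(range(parts$test$day_index), c(31, 60))
  long <- split_train_test(make_log(rep(20, 70)))
  expect_equal(max(long$test$day_index), 60)  # days 61-70 unused
  expect_error(
    split_train_test(make_log(rep(20, 59))),
    "p1.*fewer than 60"
  )
})

test_that("window size recovers a pure sinusoid's period from exact sampling", {
  x <- sin(2 * pi * (1:28) / 7)
  expect_equal(select_window_size(x), 7L)
  # and an off-phase, scaled sinusoid
  expect_equal(select_window_size(100 + 31 * cos(2 * pi * (1:35) / 7 + 1)), 7L)
})

test_that("window size recovers the weekly schedule from 30 days", {
  x <- rep(c(45, 45, 45, 45, 45, 0, 0), length.out = 30)
  expect_equal(select_window_size(x), 7L)
})

test_that("flat spectra fall back to the default window with a warning", {
  expect_warning(n <- select_window_size(rep(45, 30)), "fallback")
  expect_equal(n, 7L)
  expect_error(select_window_size(c(1, 2, 3)), "too short")
})

test_that("window size equals the naive quadratic Fourier oracle", {
  withr::with_seed(42, {
    for (t_len in c(20, 30, 41, 64)) {
      for (rep in 1:5) {
        x <- rnorm(t_len) + sin(2 * pi * (1:t_len) / sample(3:10, 1)) * runif(1, 0, 3)
        expect_equal(select_window_size(x), naive_period_argmax(x))
      }
    }
  })
})

test_that("integer-period argmax agrees with the DFT-bin argmax on commensurate lengths", {
  withr::with_seed(7, {
    for (p_true in c(4, 7)) {
      t_len <- p_true * 6
      x <- sin(2 * pi * (1:t_len) / p_true) + rnorm(t_len, sd = 0.2)
      amp <- Mod(stats::fft(x - mean(x)))
      bins <- 2:(floor(t_len / 2) + 1)
      periods <- t_len / (bins - 1)
      keep <- periods >= 2 & periods <= t_len / 2
      bin_period <- periods[keep][which.max(amp[bins][keep])]
      expect_equal(select_window_size(x), as.integer(round(bin_period)))
    }
  })
})

test_that("feature normalization is fit on training data only", {
  train <- data.frame(duration = c(15, 25), sessions = c(1, 1),
                      max_level = c(2, 4), tasks = c(3, 5))
  test <- data.frame(duration = 25, sessions = 0, max_level = 3, tasks = 4)
  norm <- normalize_features(train, test)
  # constant training column maps to zero everywhere
  expect_equal(norm$train$sessions, c(0, 0))
  expect_equal(norm$test$sessions, 0)
  # closed form: (25 - 20) / sd(c(15,25))
  expect_equal(norm$test$duration, (25 - 20) / stats::sd(c(15, 25)))
  # round trip via the stored transform
  back <- norm$train$duration * norm$scale["duration"] + norm$center["duration"]
  expect_equal(unname(back), train$duration, tolerance = 1e-12)
  # leakage check: test values cannot alter the transform
  norm2 <- normalize_features(train, transform(test, duration = 9000))
  expect_identical(norm$center, norm2$center)
  expect_identical(norm$scale, norm2$scale)
})

test_that("windows pair N consecutive days with the following day's label", {
  feats <- matrix(seq_len(30 * 4), 30, 4)
  labels <- rep(c(1L, 0L), 15)
  wd <- make_windows(feats, labels, 7)
  expect_equal(dim(wd$x), c(23, 7, 4))
  expect_length(wd$y, 23)
  # window k covers days k..k+6, labeled with day k+7
  expect_equal(wd$x[1, , 1], as.numeric(1:7))
  expect_equal(wd$y, labels[8:30])
  expect_equal(wd$day, 8:30)
  # boundary cases
  one <- make_windows(matrix(1:32, 8, 4), rep(0L, 8), 7)
  expect_equal(dim(one$x)[1], 1)
  expect_equal(one$day, 8)
  expect_error(make_windows(matrix(1:28, 7, 4), rep(0L, 7), 7), "at least")
})

test_that("shifting the label series by one day changes every window label", {
  withr::with_seed(5, {
    feats <- matrix(rnorm(80), 20, 4)
    labels <- rep(c(0L, 1L), 10)  # alternating: any shift flips all labels
    a <- make_windows(feats, labels, 7)
    b <- make_windows(feats, c(labels[-1], 0L), 7)
    expect_true(all(a$y != b$y))
  })
})

test_that("prepare_participant assembles leakage-free train/test windows", {
  log <- generate_participant(archetype_preset("consistent"), 60, seed = 13)
  prep <- prepare_participant(log, n = 7)
  expect_equal(dim(prep$train$x), c(23, 7, 4))
  expect_equal(dim(prep$test$x), c(23, 7, 4))
  expect_equal(prep$train$domain[1], "target")
  # test-period perturbation cannot change the fitted normalization
  log2 <- log
  log2$duration[log2$day_index > 30] <- log2$duration[log2$day_index > 30] + 500
  prep2 <- prepare_participant(log2, n = 7)
  expect_identical(prep$center, prep2$center)
  expect_identical(prep$train$x, prep2$train$x)
})
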