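#' Label daily adherence
#'
#' A participant meets the minimal adherence criterion on a day if they
#' played for at least `threshold_minutes` that day (default 10 minutes —
#' long enough to exclude accidentally opening the app).
#'
#' @param log A play-log tibble (see [generate_participant()]).
#' @param threshold_minutes Positive adherence threshold in minutes.
#' @return `log` with an added integer column `adherent` (1 = met the
#'   criterion).
#' @export
label_adherence <- function(log, threshold_minutes = 10) {
  assert_play_log(log)
  assert_number(threshold_minutes, "threshold_minutes")
  if (threshold_minutes <= 0) abort("`threshold_minutes` must be > 0.")
  if (nrow(log) == 0L) abort("`log` is empty.")
  mutate(log, adherent = as.integer(.data$duration >= threshold_minutes))
}

#' Chronological train/test split
#'
#' Splits each participant's log into the first `train_days` days for
#' training and the next `test_days` for testing; any later days are
#' dropped. The split is strictly chronological, so no future information
#' reaches the training side.
#'
#' @param log A play-log tibble, possibly containing several participants.
#' @param train_days,test_days Days in each portion (defaults 30/30).
#' @return A list with tibbles `train` and `test`.
#' @export
split_train_test <- function(log, train_days = 30, test_days = 30) {
  assert_play_log(log)
  assert_number(train_days, "train_days", 1)
  assert_number(test_days, "test_days", 1)
  need <- train_days + test_days
  lens <- summarise(group_by(log, .data$participant_id), n = max(.data$day_index))
  short <- filter(lens, .data$n < need)
  if (nrow(short) > 0L) {
    abort(sprintf(
      "Participant(s) %s have fewer than %d days of data (need train + test).",
      paste(short$participant_id, collapse = ", "), need
    ))
  }
  list(
    train = filter(log, .data$day_index <= train_days),
    test = filter(
      log, .data$day_index > train_days, .data$day_index <= need
    )
  )
}

#' Select the sliding-window size from the dominant cyclic period
#'
#' Estimates the dominant periodicity of a daily play-time series by
#' Fourier analysis and uses it as the window size N. The series is
#' mean-centered (the zero-frequency component is not a periodicity) and
#' the discrete-time Fourier amplitude `|sum_t x_t exp(-2 pi i t / p)|` is
#' evaluated at every whole-day candidate period `p` between 2 days and
#' half the series length — daily sampling makes only integer-day periods
#' meaningful as window sizes, and periods longer than half the series are
#' unresolvable. The period with maximum amplitude is returned (ties break
#' to the shortest period). When the series length is a multiple of the
#' dominant period this coincides with the maximum-amplitude bin of the
#' discrete Fourier transform; on other lengths the integer-period grid
#' avoids the bin-quantization that would otherwise misreport the cycle
#' (e.g. a 7-day cycle observed for 30 days falls between the 7.5- and
#' 6-day DFT bins). If no candidate rises above numerical noise (a flat
#' spectrum, e.g. a constant series), `fallback_n` is returned with a
#' warning.
#'
#' Under a 5-days-per-week prescribed schedule the dominant period — and
#' hence the window size — is 7 days.
#'
#' @param x Numeric series of daily play durations.
#' @param fallback_n Window size used when the spectrum is flat (default 7).
#' @return Integer window size N.
#' @examples
#' select_window_size(rep(c(45, 45, 45, 45, 45, 0, 0), length.out = 30))
#' @export
select_window_size <- function(x, fallback_n = 7) {
  assert_number(fallback_n, "fallback_n", 1)
  if (!is.numeric(x)) abort("`x` must be a numeric series.")
  t_len <- length(x)
  if (t_len < 2 * fallback_n) {
    abort(sprintf(
      "Series too short for period detection: %d days (need at least %d).",
      t_len, 2 * fallback_n
    ))
  }
  centered <- x - mean(x)
  periods <- seq2(2L, floor(t_len / 2))
  amp <- period_amplitudes(centered, periods)
  tol <- 1e-8 * t_len * max(1, max(abs(centered)))
  if (length(periods) == 0L || max(amp) <= tol) {
    warn(sprintf(
      "Flat amplitude spectrum: no dominant period found; using fallback N = %d.",
      as.integer(fallback_n)
    ))
    return(as.integer(fallback_n))
  }
  as.integer(periods[which.max(amp)])
}

# Fourier amplitude of `x` at frequency 1/p for each candidate period p.
period_amplitudes <- function(x, periods) {
  t <- seq_along(x)
  vapply(
    periods,
    function(p) Mod(sum(x * exp(-2i * pi * t / p))),
    numeric(1)
  )
}

seq2 <- function(from, to) if (to < from) integer(0) else seq.int(from, to)

#' Fit and apply per-feature standardization without test leakage
#'
#' Standardizes each feature column using the mean and standard deviation
#' computed on the training portion only, then applies the identical affine
#' transform to the test portion. Zero-variance training features map to 0
#' everywhere.
#'
#' @param train,test Data frames holding the feature columns; `test` may be
#'   `NULL`.
#' @param cols Character vector of feature columns (defaults to the four
#'   play-log predictors).
#' @return A list with `train`, `test` (transformed copies) and the fitted
#'   `center`/`scale` vectors (named by column).
#' @export
normalize_features <- function(train, test = NULL,
                               cols = c("duration", "sessions", "max_level", "tasks")) {
  if (nrow(train) == 0L) abort("`train` must be nonempty.")
  missing <- setdiff(cols, names(train))
  if (length(missing) > 0L) {
    abort(sprintf("Missing feature column(s): %s.", paste(missing, collapse = ", ")))
  }
  center <- vapply(train[cols], mean, numeric(1))
  scale <- vapply(train[cols], stats::sd, numeric(1))
  scale[!is.finite(scale) | scale == 0] <- Inf  # zero-variance -> 0 after transform
  apply_tf <- function(df) {
    for (j in cols) df[[j]] <- (df[[j]] - center[j]) / scale[j]
    df
  }
  list(
    train = apply_tf(train),
    test = if (!is.null(test)) apply_tf(test),
    center = center,
    scale = scale
  )
}

#' Build sliding windows labeled by next-day adherence
#'
#' Converts per-day feature vectors into the supervised task: window `k`
#' covers days `k .. k+N-1` and is labeled with day `k+N`'s adherence, so a
#' series of `D` days yields `D - N` windows.
#'
#' @param features Numeric matrix or data frame, one row per consecutive
#'   day, one column per feature.
#' @param labels Binary (0/1) adherence labels, one per day.
#' @param n Window size N (days).
#' @param domain Optional domain tag (e.g. `"target"`/`"source"`) stored
#'   per window for the adversarial trainer.
#' @return A `windowed_dataset`: list with `x` (array, windows x N x
#'   features), `y` (integer labels), `day` (day index of the labeled day),
#'   `feature_names` and `domain`.
#' @export
make_windows <- function(features, labels, n, domain = NA_character_) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  d <- nrow(features)
  if (length(labels) != d) abort("`labels` must have one entry per day.")
  assert_number(n, "n", 1)
  if (d < n + 1) {
    abort(sprintf(
      "Need at least N + 1 = %d days to form one window; got %d.", n + 1, d
    ))
  }
  n_win <- d - n
  x <- array(NA_real_, dim = c(n_win, n, ncol(features)))
  for (k in seq_len(n_win)) x[k, , ] <- features[k:(k + n - 1), , drop = FALSE]
  structure(
    list(
      x = x,
      y = as.integer(labels[(n + 1):d]),
      day = (n + 1):d,
      feature_names = colnames(features) %||% paste0("f", seq_len(ncol(features))),
      domain = rep(domain, n_win)
    ),
    class = "windowed_dataset"
  )
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf(
    "<windowed_dataset> %d windows of %d days x %d features (%d adherent labels)\n",
    dim(x$x)[1], dim(x$x)[2], dim(x$x)[3], sum(x$y)
  ))
  invisible(x)
}

# Concatenate windowed datasets (same window geometry).
bind_windows <- function(datasets) {
  datasets <- datasets[!vapply(datasets, is.null, logical(1))]
  if (length(datasets) == 1L) return(datasets[[1L]])
  dims <- vapply(datasets, function(d) dim(d$x)[2:3], numeric(2))
  if (any(dims != dims[, 1])) abort("Window geometries differ; cannot pool.")
  structure(
    list(
      x = do.call(abind_rows, map(datasets, "x")),
      y = unlist(map(datasets, "y"), use.names = FALSE),
      day = unlist(map(datasets, "day"), use.names = FALSE),
      feature_names = datasets[[1L]]$feature_names,
      domain = unlist(map(datasets, "domain"), use.names = FALSE)
    ),
    class = "windowed_dataset"
  )
}

abind_rows <- function(...) {
  arrays <- list(...)
  n <- sum(vapply(arrays, function(a) dim(a)[1], numeric(1)))
  out <- array(NA_real_, dim = c(n, dim(arrays[[1]])[2], dim(arrays[[1]])[3]))
  at <- 1L
  for (a in arrays) {
    k <- dim(a)[1]
    if (k > 0) out[at:(at + k - 1L), , ] <- a
    at <- at + k
  }
  out
}

#' Windowed train/test sets for one participant
#'
#' End-to-end preprocessing for a single participant: adherence labeling,
#' chronological split, leakage-free feature standardization fitted on the
#' training days, and sliding-window construction on both portions.
#'
#' @param log One participant's play-log tibble.
#' @param n Window size N (days); see [select_window_size()].
#' @param threshold_minutes Adherence threshold (default 10 minutes).
#' @param train_days,test_days Split sizes (defaults 30/30).
#' @param domain Domain tag stored on the windows.
#' @return List with `train` and `test` `windowed_dataset`s and the fitted
#'   normalization (`center`, `scale`).
#' @export
prepare_participant <- function(log, n = 7, threshold_minutes = 10,
                                train_days = 30, test_days = 30,
                                domain = "target") {
  pid <- unique(log$participant_id)
  if (length(pid) != 1L) abort("`log` must contain exactly one participant.")
  labeled <- label_adherence(log, threshold_minutes)
  labeled <- arrange(labeled, .data$day_index)
  parts <- split_train_test(labeled, train_days, test_days)
  cols <- c("duration", "sessions", "max_level", "tasks")
  norm <- normalize_features(parts$train, parts$test, cols)
  list(
    train = make_windows(norm$train[cols], norm$train$adherent, n, domain),
    test = make_windows(norm$test[cols], norm$test$adherent, n, domain),
    center = norm$center,
    scale = norm$scale,
    participant_id = pid
  )
}
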