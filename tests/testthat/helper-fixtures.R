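# Shared fixtures built in code at test time.

# windowed dataset from raw per-day features/labels
wd_from <- function(features, labels, n = 7, domain = "target") {
  make_windows(as.matrix(features), labels, n, domain = domain)
}

# windows whose label is separable from the window's overall feature level
separable_windows <- function(n_win, mu = 1, seed = 1, domain = "target") {
  withr::with_seed(seed, {
    y <- rbinom(n_win, 1, 0.5)
    x <- array(
      rnorm(n_win * 7 * 4, mean = rep(ifelse(y == 1, mu, -mu), 7 * 4)),
      dim = c(n_win, 7, 4)
    )
    structure(
      list(
        x = x, y = as.integer(y), day = seq_len(n_win) + 7L,
        feature_names = paste0("f", 1:4), domain = rep(domain, n_win)
      ),
      class = "windowed_dataset"
    )
  })
}

# windows from an autocorrelated daily process; label = yesterday's sign,
# so the predictive signal sits at the end of each window
persistent_windows <- function(n_days, seed = 1, domain = "target",
                               mean_shift = 0) {
  withr::with_seed(seed, {
    f1 <- as.numeric(stats::arima.sim(list(ar = 0.8), n_days)) + mean_shift
    feats <- cbind(f1, matrix(rnorm(n_days * 3, sd = 0.3), n_days, 3))
    labels <- as.integer(c(0, f1[-n_days] > mean_shift))
    make_windows(feats, labels, 7, domain = domain)
  })
}

# adjusted Rand index between two partitions (hypergeometric expectation)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

# naive O(T^2) Fourier amplitude at integer candidate periods (oracle for
# select_window_size): double loop, no vectorized tricks
naive_period_argmax <- function(x) {
  x <- x - mean(x)
  t_len <- length(x)
  periods <- 2:(t_len %/% 2)
  best_p <- NA_integer_
  best_a <- -Inf
  for (p in periods) {
    re <- 0
    im <- 0
    for (t in seq_len(t_len)) {
      re <- re + x[t] * cos(2 * pi * t / p)
      im <- im - x[t] * sin(2 * pi * t / p)
    }
    a <- sqrt(re^2 + im^2)
    if (a > best_a + 1e-12) {
      best_a <- a
      best_p <- p
    }
  }
  best_p
}

# exhaustive sign-test oracle: enumerate all 2^n equally likely sign
# patterns and sum the probability of outcomes at least as extreme
enumerate_sign_test <- function(n_pos, n) {
  if (n == 0) return(1)
  m <- min(n_pos, n - n_pos)
  extreme <- 0
  for (bits in 0:(2^n - 1)) {
    k <- sum(bitwAnd(bits, 2^(0:(n - 1))) > 0)
    if (k <= m || k >= n - m) extreme <- extreme + 1
  }
  extreme / 2^n
}
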