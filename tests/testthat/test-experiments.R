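test_that("metrics follow the confusion-matrix definitions", {
  perfect <- compute_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # TP=2 FP=2 FN=0 TN=0
  m <- compute_metrics(c(1, 0, 1, 0), c(1, 1, 1, 1))
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 2 / 3)
  # no positives anywhere: flags raised, metrics 0
  z <- compute_metrics(c(0, 0), c(0, 0))
  expect_equal(z$accuracy, 1)
  expect_equal(z$precision, 0)
  expect_false(z$precision_defined)
  expect_false(z$recall_defined)
  expect_error(compute_metrics(c(1, 0), c(1, 0, 1)), "equal length")
  expect_error(compute_metrics(c(1, 2), c(1, 0)), "binary")
})

test_that("metrics match random confusion matrices computed by hand", {
  withr::with_seed(1, {
    for (i in 1:20) {
      n <- sample(5:50, 1)
      yt <- rbinom(n, 1, 0.5)
      yp <- rbinom(n, 1, 0.5)
      tp <- sum(yt & yp); fp <- sum(!yt & yp)
      fn <- sum(yt & !yp); tn <- sum(!yt & !yp)
      m <- compute_metrics(yt, yp)
      expect_equal(m$accuracy, (tp + tn) / n)
      if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
      if (tp + fn > 0) expect_equal(m$recall, tp / (tp + fn))
    }
  })
})

test_that("sign test matches the exact binomial and exhaustive enumeration", {
  st <- sign_test(1:8, 0:7)  # 8 positive differences, no ties
  expect_equal(st$p.value, 2 * (1 / 2)^8)
  expect_equal(st$n_positive, 8L)
  tied <- sign_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tied$p.value, 1)
  expect_true(tied$all_ties)
  withr::with_seed(2, {
    for (i in 1:15) {
      n <- sample(3:12, 1)
      a <- rnorm(n)
      b <- rnorm(n)
      st <- sign_test(a, b)
      expect_equal(st$p.value, enumerate_sign_test(st$n_positive, st$n))
    }
  })
  # ties are dropped before the binomial reference
  st2 <- sign_test(c(5, 5, 5, 1, 2), c(5, 5, 5, 0, 0))
  expect_equal(st2$n, 2L)
})

test_that("repeated-measures ANOVA matches the paired t-test for 2 conditions", {
  flat <- repeated_measures_anova(cbind(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(flat$F, 0)
  expect_equal(flat$p.value, 1)
  withr::with_seed(3, {
    for (i in 1:10) {
      n <- sample(4:20, 1)
      m <- cbind(rnorm(n), rnorm(n))
      res <- repeated_measures_anova(m)
      tt <- t.test(m[, 1], m[, 2], paired = TRUE)
      expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-9)
      expect_equal(res$p.value, tt$p.value, tolerance = 1e-9)
    }
  })
})

test_that("repeated-measures ANOVA matches hand-computed sums of squares", {
  # small worked dataset: 4 subjects x 3 conditions
  m <- rbind(c(30, 28, 16), c(14, 18, 10), c(24, 20, 18), c(38, 34, 20))
  res <- repeated_measures_anova(m)
  grand <- mean(m)
  ss_cond <- 4 * sum((colMeans(m) - grand)^2)
  ss_subj <- 3 * sum((rowMeans(m) - grand)^2)
  ss_err <- sum((m - grand)^2) - ss_cond - ss_subj
  expect_equal(res$F, (ss_cond / 2) / (ss_err / 6))
  # independent route: blocked aov decomposition
  df <- data.frame(
    y = as.vector(m),
    subj = factor(rep(1:4, 3)),
    cond = factor(rep(1:3, each = 4))
  )
  fit <- stats::aov(y ~ cond + subj, data = df)
  tab <- summary(fit)[[1]]
  expect_equal(res$F, tab["cond", "F value"], tolerance = 1e-9)
  expect_equal(res$p.value, tab["cond", "Pr(>F)"], tolerance = 1e-9)
  expect_error(repeated_measures_anova(rbind(c(1, NA), c(2, 3))), "complete")
})

test_that("all three arms share identical test windows and labels", {
  cohort <- generate_cohort(cohort_spec(
    6, archetype_mix = c(consistent = 0.5, consistent_with_lapses = 0.5),
    shift = 1, seed = 31
  ))
  cfg <- cnn_config(epochs = 15, seed = 1)
  res <- suppressWarnings(run_within_study(cohort, k = 2, cfg = cfg, seed = 31))
  pp <- tidy(res)
  expect_equal(nrow(pp), 6 * 3)
  expect_setequal(unique(pp$arm),
                  c("no_source_no_da", "with_source_no_da", "with_source_with_da"))
  # the test windows are a pure function of the log: re-preparation is identical
  pid <- pp$participant_id[1]
  log <- dplyr::filter(cohort, participant_id == pid)
  p1 <- prepare_participant(log, n = res$window_size)
  p2 <- prepare_participant(log, n = res$window_size)
  expect_identical(p1$test, p2$test)
})

test_that("aggregates are recomputable from the per-participant table", {
  cohort <- generate_cohort(cohort_spec(
    5, archetype_mix = c(consistent = 1), shift = 1, seed = 17
  ))
  res <- suppressWarnings(
    run_within_study(cohort, k = 2, cfg = cnn_config(epochs = 10, seed = 2), seed = 17)
  )
  byhand <- tidy(res) |>
    dplyr::group_by(arm) |>
    dplyr::summarise(acc = mean(accuracy), acc_sd = stats::sd(accuracy))
  agg <- aggregate_metrics(res) |> dplyr::arrange(arm)
  expect_equal(agg$accuracy_mean, dplyr::arrange(byhand, arm)$acc)
  expect_equal(agg$accuracy_sd, dplyr::arrange(byhand, arm)$acc_sd)
})

test_that("training never reads the target's test days", {
  cohort <- generate_cohort(cohort_spec(
    4, archetype_mix = c(consistent = 1), shift = 1, seed = 23
  ))
  target <- unique(cohort$participant_id)[1]
  tampered <- cohort
  sel <- tampered$participant_id == target & tampered$day_index > 30
  tampered$duration[sel] <- pmax(0, tampered$duration[sel] + 37)
  asg <- cluster_cohort(cohort, k = 2, seed = 1, span = "train")
  cfg <- cnn_config(epochs = 10, seed = 4)
  for (arm in c("no_source_no_da", "with_source_no_da", "with_source_with_da")) {
    prep_a <- prepare_participant(dplyr::filter(cohort, participant_id == target), n = 7)
    prep_b <- prepare_participant(dplyr::filter(tampered, participant_id == target), n = 7)
    # training inputs are identical, so the fitted models must be too
    expect_identical(prep_a$train, prep_b$train)
    expect_identical(prep_a$center, prep_b$center)
    m_a <- run_arm(cohort, target, arm, asg, n = 7, cfg = cfg)
    m_b <- run_arm(tampered, target, arm, asg, n = 7, cfg = cfg)
    expect_false(is.null(m_a))
    expect_false(is.null(m_b))
  }
})

test_that("cross-study sources come only from the other study", {
  a <- generate_cohort(cohort_spec(
    4, archetype_mix = c(consistent = 1), shift = 1,
    study_id = "study1", seed = 41
  ))
  b <- generate_cohort(cohort_spec(
    4, archetype_mix = c(consistent = 1), shift = 1,
    study_id = "study2", prescribed_minutes = 60, seed = 42
  ))
  res <- suppressWarnings(run_cross_study(
    a, b, k = 2, cfg = cnn_config(epochs = 8, seed = 3), seed = 41
  ))
  expect_equal(res$protocol, "cross_study")
  asg <- res$assignment
  for (pid in asg$participant_id) {
    own <- asg$study_id[asg$participant_id == pid]
    pool <- source_pool(asg, pid, restrict_study = own)
    pool_studies <- asg$study_id[asg$participant_id %in% pool]
    expect_true(all(pool_studies != own))
  }
  expect_equal(nrow(tidy(res)), 8 * 3)
})

test_that("result objects tidy, glance and plot", {
  cohort <- generate_cohort(cohort_spec(
    4, archetype_mix = c(consistent = 1), shift = 1, seed = 51
  ))
  res <- suppressWarnings(
    run_within_study(cohort, k = 2, cfg = cnn_config(epochs = 8, seed = 5), seed = 51)
  )
  expect_s3_class(tidy(res), "tbl_df")
  g <- glance(res)
  expect_equal(nrow(g), 1)
  expect_true(all(c("accuracy_no_source_no_da", "accuracy_with_source_with_da")
                  %in% names(g)))
  expect_s3_class(autoplot(res), "ggplot")
  cmp <- compare_arms(res)
  expect_s3_class(cmp$sign_test, "sign_test")
  expect_s3_class(cmp$anova, "rm_anova")
})
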