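#' Confusion-matrix evaluation metrics
#'
#' Accuracy, precision, recall and F1 for binary adherence predictions,
#' with the adherent class (1) as positive. When a denominator is zero
#' (no predicted positives for precision, no true positives+false negatives
#' for recall) the metric is reported as 0 and flagged.
#'
#' @param y_true,y_pred Equal-length binary (0/1) vectors.
#' @return A one-row tibble with `accuracy`, `precision`, `recall`, `f1`
#'   and logical flags `precision_defined`, `recall_defined`.
#' @examples
#' compute_metrics(c(1, 0, 1, 0), c(1, 1, 1, 1))
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must be nonempty vectors of equal length.")
  }
  if (!all(y_true %in% 0:1) || !all(y_pred %in% 0:1)) {
    abort("Labels must be binary (0/1).")
  }
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  prec_def <- (tp + fp) > 0
  rec_def <- (tp + fn) > 0
  precision <- if (prec_def) tp / (tp + fp) else 0
  recall <- if (rec_def) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble(
    accuracy = (tp + tn) / length(y_true),
    precision = precision,
    recall = recall,
    f1 = f1,
    precision_defined = prec_def,
    recall_defined = rec_def
  )
}

arm_names <- c("no_source_no_da", "with_source_no_da", "with_source_with_da")

arm_short <- function(arm) {
  switch(arm,
    no_source_no_da = "baseline",
    with_source_no_da = "pooled",
    with_source_with_da = "dann",
    abort(sprintf(
      "Unknown arm %s; must be one of %s.",
      deparse(arm), paste0('"', arm_names, '"', collapse = ", ")
    ))
  )
}

# Train one arm from already-prepared (windowed, per-participant normalized)
# data and evaluate on the target's test windows.
run_arm_prepared <- function(arm, prep_target, source_windows, cfg, dann) {
  short <- arm_short(arm)
  model <- switch(short,
    baseline = train_baseline(prep_target$train, cfg),
    pooled = train_pooled(prep_target$train, source_windows, cfg),
    dann = train_dann(prep_target$train, source_windows, dann)
  )
  preds <- predict_adherence(model, prep_target$test)
  metrics <- compute_metrics(prep_target$test$y, preds$.pred)
  list(metrics = metrics, model = model, predictions = preds)
}

#' Run one experimental arm for one target participant
#'
#' Trains the arm-appropriate model for the target — `no_source_no_da`
#' (target-only), `with_source_no_da` (pooled same-cluster sources) or
#' `with_source_with_da` (adversarial adaptation) — and evaluates it on the
#' target's test-day windows. All arms of a target see byte-identical test
#' windows. Source participants are the target's cluster mates (optionally
#' restricted to the other study); each participant's windows are
#' standardized with their own training-day statistics before pooling.
#'
#' @param cohort Play-log tibble holding all participants.
#' @param target Target participant id.
#' @param arm Arm name (see above).
#' @param assignment A `cluster_assignment` from [cluster_participants()].
#' @param n Window size in days.
#' @param cfg A [cnn_config()].
#' @param dann A [dann_config()] (used by the DA arm).
#' @param threshold_minutes,train_days,test_days Preprocessing settings.
#' @param restrict_study Optional study id whose participants are excluded
#'   from the source pool (cross-study protocol).
#' @return A one-row metrics tibble (see [compute_metrics()]).
#' @export
run_arm <- function(cohort, target, arm, assignment, n = 7,
                    cfg = cnn_config(), dann = dann_config(base = cfg),
                    threshold_minutes = 10, train_days = 30, test_days = 30,
                    restrict_study = NULL) {
  assert_play_log(cohort)
  prep <- prepare_participant(
    filter(cohort, .data$participant_id == target),
    n = n, threshold_minutes = threshold_minutes,
    train_days = train_days, test_days = test_days
  )
  pool <- source_pool(assignment, target, restrict_study)
  src <- prepare_sources(cohort, pool, n, threshold_minutes, train_days, test_days)
  run_arm_prepared(arm, prep, src, cfg, dann)$metrics
}

prepare_sources <- function(cohort, pool, n, threshold_minutes,
                            train_days, test_days) {
  if (length(pool) == 0L) return(NULL)
  preps <- map(pool, function(pid) {
    prepare_participant(
      filter(cohort, .data$participant_id == pid),
      n = n, threshold_minutes = threshold_minutes,
      train_days = train_days, test_days = test_days, domain = "source"
    )$train
  })
  bind_windows(preps)
}

# Shared orchestration for the within- and cross-study protocols.
run_protocol <- function(cohort, k, cfg, dann, n, threshold_minutes,
                         train_days, test_days, seed, extractor_name,
                         feature_dim, span, protocol) {
  assert_play_log(cohort)
  if (is.null(n)) {
    train_part <- filter(cohort, .data$day_index <= train_days)
    mean_series <- train_part |>
      group_by(.data$day_index) |>
      summarise(duration = mean(.data$duration), .groups = "drop") |>
      arrange(.data$day_index)
    n <- select_window_size(mean_series$duration)
  }
  assignment <- cluster_cohort(
    cohort, k = k, seed = derive_seed(seed, "cluster"),
    extractor_name = extractor_name, dim = feature_dim,
    span = span, train_days = train_days
  )
  ids <- sort(unique(cohort$participant_id))
  preps <- map(ids, function(pid) {
    prepare_participant(
      filter(cohort, .data$participant_id == pid),
      n = n, threshold_minutes = threshold_minutes,
      train_days = train_days, test_days = test_days
    )
  })
  names(preps) <- ids
  source_preps <- map(preps, function(p) {
    tr <- p$train
    tr$domain <- rep("source", n_windows(tr))
    tr
  })

  rows <- list()
  for (pid in ids) {
    restrict <- if (protocol == "cross_study") {
      assignment$study_id[assignment$participant_id == pid]
    } else {
      NULL
    }
    pool <- source_pool(assignment, pid, restrict)
    src <- if (length(pool) > 0) bind_windows(source_preps[pool]) else NULL
    if (is.null(src)) {
      warn(sprintf(
        "Participant %s has an empty source pool; source arms fall back to target-only training.",
        pid
      ))
    }
    t_seed <- derive_seed(seed, paste0("target-", pid))
    cfg_t <- cfg
    cfg_t$seed <- t_seed
    dann_t <- dann
    dann_t$base <- cfg_t
    for (arm in arm_names) {
      res <- run_arm_prepared(arm, preps[[pid]], src, cfg_t, dann_t)
      rows[[length(rows) + 1L]] <- bind_cols(
        tibble(
          participant_id = pid,
          study_id = assignment$study_id[assignment$participant_id == pid],
          cluster = assignment$cluster[assignment$participant_id == pid],
          arm = arm
        ),
        res$metrics
      )
    }
  }
  per_participant <- list_rbind(rows)
  aggregate <- per_participant |>
    group_by(.data$arm) |>
    summarise(across(
      c("accuracy", "precision", "recall", "f1"),
      list(mean = mean, sd = stats::sd)
    ), .groups = "drop") |>
    arrange(match(.data$arm, arm_names))
  structure(
    list(
      per_participant = per_participant,
      aggregate = aggregate,
      assignment = assignment,
      protocol = protocol,
      window_size = n,
      k = k,
      seed = seed,
      config = cfg,
      dann_config = dann
    ),
    class = "experiment_result"
  )
}

#' Run the three-arm within-study experiment
#'
#' The full experimental protocol on a single-study cohort: participants
#' are clustered on their GAF features (play-time series -> GAF image ->
#' features -> K-means), then every participant in turn serves as the
#' target — their same-cluster peers are the sources — and all three arms
#' (target-only, pooled sources, adversarial adaptation) are trained and
#' evaluated on the target's test windows. Metrics are averaged (mean and
#' SD) across participants per arm.
#'
#' @param cohort Play-log tibble of one study.
#' @param k Number of clusters (default 4).
#' @param cfg A [cnn_config()]; per-target seeds are derived from `seed`.
#' @param dann A [dann_config()] for the DA arm.
#' @param n Window size in days; `NULL` (default) selects it globally from
#'   the dominant cyclic period of the cohort's mean training-day play-time
#'   series (see [select_window_size()]).
#' @param threshold_minutes,train_days,test_days Preprocessing settings.
#' @param seed Master seed for clustering and per-target training.
#' @param extractor_name,feature_dim GAF feature extractor settings.
#' @param span Series span used for GAF clustering (`"full"` or `"train"`).
#' @return An `experiment_result`: per-participant and aggregate metric
#'   tables plus the cluster assignment and all settings.
#' @export
run_within_study <- function(cohort, k = 4, cfg = cnn_config(),
                             dann = dann_config(base = cfg), n = NULL,
                             threshold_minutes = 10, train_days = 30,
                             test_days = 30, seed = 1L,
                             extractor_name = "flatten_pca", feature_dim = 8,
                             span = "full") {
  if (length(unique(cohort$study_id)) != 1L) {
    abort("`cohort` must contain a single study; use `run_cross_study()` for two.")
  }
  run_protocol(
    cohort, k, cfg, dann, n, threshold_minutes, train_days, test_days,
    seed, extractor_name, feature_dim, span, "within_study"
  )
}

#' Run the three-arm cross-study experiment
#'
#' Joint protocol over two independent study cohorts: all participants are
#' clustered together, but for each target only same-cluster participants
#' from the *other* study are eligible sources — emulating the deployment
#' scenario where the new program has no peer data and history from a
#' similar previous trial must be transferred. No model is ever trained on
#' the union of the two studies without a designated target.
#'
#' @param cohort_a,cohort_b Play-log tibbles with distinct `study_id`s.
#' @inheritParams run_within_study
#' @return An `experiment_result` with `protocol = "cross_study"`.
#' @export
run_cross_study <- function(cohort_a, cohort_b, k = 4, cfg = cnn_config(),
                            dann = dann_config(base = cfg), n = NULL,
                            threshold_minutes = 10, train_days = 30,
                            test_days = 30, seed = 1L,
                            extractor_name = "flatten_pca", feature_dim = 8,
                            span = "full") {
  assert_play_log(cohort_a, "cohort_a")
  assert_play_log(cohort_b, "cohort_b")
  sa <- unique(cohort_a$study_id)
  sb <- unique(cohort_b$study_id)
  if (length(sa) != 1L || length(sb) != 1L || sa == sb) {
    abort("`cohort_a` and `cohort_b` must each hold one study, with distinct ids.")
  }
  cohort <- bind_rows(cohort_a, cohort_b)
  run_protocol(
    cohort, k, cfg, dann, n, threshold_minutes, train_days, test_days,
    seed, extractor_name, feature_dim, span, "cross_study"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "<experiment_result> %s protocol, %d participants, K = %d, N = %d\n",
    x$protocol, length(unique(x$per_participant$participant_id)),
    x$k, x$window_size
  ))
  print(x$aggregate)
  invisible(x)
}

#' Aggregate metric table of an experiment
#'
#' Mean and SD of each evaluation metric over participants, per arm —
#' recomputable from the per-participant table.
#'
#' @param x An `experiment_result`.
#' @return A tibble, one row per arm.
#' @export
aggregate_metrics <- function(x) {
  if (!inherits(x, "experiment_result")) abort("`x` must be an `experiment_result`.")
  x$aggregate
}

#' Exact sign test on paired per-participant scores
#'
#' Two-sided exact binomial sign test of whether scores under condition `a`
#' systematically exceed those under condition `b` across participants.
#' Ties are discarded; the number of positive differences among the `n`
#' remaining pairs is referred to a Binomial(n, 1/2) distribution and the
#' two-sided p-value is twice the smaller tail (capped at 1). With all
#' pairs tied the test is vacuous: p = 1 with `all_ties = TRUE`.
#'
#' @param a,b Equal-length numeric score vectors (e.g. per-participant F1
#'   under two arms).
#' @return A list of class `sign_test`: `n_positive`, `n_negative`, `n`
#'   (non-ties), `p.value`, `all_ties`.
#' @export
sign_test <- function(a, b) {
  if (length(a) == 0L || length(a) != length(b)) {
    abort("`a` and `b` must be nonempty vectors of equal length.")
  }
  d <- a - b
  n_pos <- sum(d > 0)
  n_neg <- sum(d < 0)
  n <- n_pos + n_neg
  if (n == 0L) {
    out <- list(n_positive = 0L, n_negative = 0L, n = 0L,
                p.value = 1, all_ties = TRUE)
  } else {
    p <- min(1, 2 * stats::pbinom(min(n_pos, n_neg), n, 0.5))
    out <- list(n_positive = n_pos, n_negative = n_neg, n = n,
                p.value = p, all_ties = FALSE)
  }
  structure(out, class = "sign_test")
}

#' @export
print.sign_test <- function(x, ...) {
  cat(sprintf(
    "Exact sign test: %d positive / %d negative of %d non-tied pairs, p = %.4g%s\n",
    x$n_positive, x$n_negative, x$n, x$p.value,
    if (x$all_ties) " (all ties)" else ""
  ))
  invisible(x)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject comparison of k conditions measured on the same
#' participants (e.g. per-participant F1 under the experimental arms),
#' computed directly from the sums-of-squares decomposition with the
#' participant as blocking factor: the condition effect is tested against
#' the participant-by-condition residual with `(k - 1)` and
#' `(n - 1)(k - 1)` degrees of freedom. No sphericity correction is
#' applied. For two conditions, F equals the squared paired t statistic.
#'
#' @param scores Numeric matrix or data frame, one row per participant and
#'   one column per condition; must be complete.
#' @return A list of class `rm_anova`: `F`, `df1`, `df2`, `p.value` and the
#'   sums of squares (`ss_condition`, `ss_subject`, `ss_error`).
#' @export
repeated_measures_anova <- function(scores) {
  m <- as.matrix(scores)
  if (any(!is.finite(m))) abort("`scores` must be a complete numeric matrix (no missing values).")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) abort("Need at least 2 participants and 2 conditions.")
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1L
  df2 <- (n - 1L) * (k - 1L)
  tol <- 1e-12 * max(1, ss_tot)
  if (ss_cond <= tol) {
    f_stat <- 0
    p <- 1
  } else if (ss_err <= tol) {
    f_stat <- Inf
    p <- 0
  } else {
    f_stat <- (ss_cond / df1) / (ss_err / df2)
    p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  }
  structure(
    list(F = f_stat, df1 = df1, df2 = df2, p.value = p,
         ss_condition = ss_cond, ss_subject = ss_subj, ss_error = ss_err),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
    x$df1, x$df2, x$F, x$p.value
  ))
  invisible(x)
}

#' Compare two arms of an experiment
#'
#' Runs the paired significance tests on the per-participant F1 scores of
#' two arms: the exact sign test and the repeated-measures ANOVA.
#'
#' @param x An `experiment_result`.
#' @param arm_a,arm_b Arm names (defaults compare DA against pooled).
#' @param metric Metric column to compare (default `"f1"`).
#' @return A list with elements `sign_test` and `anova`.
#' @export
compare_arms <- function(x, arm_a = "with_source_with_da",
                         arm_b = "with_source_no_da", metric = "f1") {
  if (!inherits(x, "experiment_result")) abort("`x` must be an `experiment_result`.")
  wide <- x$per_participant |>
    select("participant_id", "arm", all_of(metric)) |>
    tidyr::pivot_wider(names_from = "arm", values_from = all_of(metric)) |>
    arrange(.data$participant_id)
  a <- wide[[arm_a]]
  b <- wide[[arm_b]]
  list(
    sign_test = sign_test(a, b),
    anova = repeated_measures_anova(cbind(a = a, b = b))
  )
}
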