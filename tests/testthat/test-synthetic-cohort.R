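test_that("zero play probability yields an all-zero log", {
  arch <- archetype_spec("non_player", play_probability = 0, mean_duration = 10)
  log <- generate_participant(arch, n_days = 60, seed = 7)
  expect_equal(nrow(log), 60)
  expect_true(all(log$duration == 0))
  expect_true(all(log$sessions == 0))
  expect_true(all(log$tasks == 0))
})

test_that("a fully consistent participant follows the 5-of-7 schedule exactly", {
  arch <- archetype_spec("consistent", play_probability = 1,
                         mean_duration = 45, duration_sd = 0)
  log <- generate_participant(arch, n_days = 14, schedule_days = 5, seed = 1)
  expect_equal(sum(log$duration == 45), 10)
  expect_equal(sum(log$duration == 0), 4)
  expect_equal(log$duration[6:7], c(0, 0))
  expect_equal(log$day_index, 1:14)
})

test_that("played fraction of scheduled days matches the configured probability", {
  arch <- archetype_spec("consistent", play_probability = 0.8,
                         mean_duration = 45, duration_sd = 8)
  log <- generate_participant(arch, n_days = 10000, seed = 11)
  scheduled <- ((log$day_index - 1) %% 7) < 5
  frac <- mean(log$duration[scheduled] > 0)
  se <- sqrt(0.8 * 0.2 / sum(scheduled))
  expect_lt(abs(frac - 0.8), 3 * se)
})

test_that("invariants hold on generated logs", {
  for (name in c("non_player", "consistent", "consistent_with_lapses", "erratic")) {
    log <- generate_participant(archetype_preset(name), n_days = 60, seed = 3)
    expect_equal(log$day_index, 1:60)
    zero <- log$duration == 0
    expect_true(all(log$sessions[zero] == 0))
    expect_true(all(log$tasks[zero] == 0))
    expect_true(all(log$duration >= 0))
    expect_true(all(log$max_level >= 0))
  }
})

test_that("archetype validation rejects bad configurations", {
  expect_error(archetype_spec("keen_player", 0.5, 45), "Unknown archetype")
  expect_error(archetype_spec("erratic", 1.5, 45), "play_probability")
  expect_error(
    cohort_spec(5, archetype_mix = c(consistent = 0.6, erratic = 0.6)),
    "sum to 1"
  )
})

test_that("a shift-free single-archetype cohort has identical parameters", {
  spec <- cohort_spec(8, archetype_mix = c(consistent = 1), shift = 0, seed = 2)
  cohort <- generate_cohort(spec)
  meta <- cohort_archetypes(cohort)
  expect_equal(nrow(meta), 8)
  expect_equal(length(unique(meta$play_probability)), 1L)
  expect_equal(length(unique(meta$mean_duration)), 1L)
})

test_that("archetype assignment counts follow the mixture multinomially", {
  spec <- cohort_spec(100, seed = 9)  # default equal mix over 4 archetypes
  counts <- table(cohort_archetypes(generate_cohort(spec))$archetype)
  se <- sqrt(100 * 0.25 * 0.75)
  expect_true(all(abs(counts - 25) < 3 * se))
  expect_equal(length(counts), 4L)
})

test_that("prescribed session length moves played durations in the consistent stratum", {
  mk <- function(minutes) {
    spec <- cohort_spec(12, archetype_mix = c(consistent = 1), shift = 0,
                        prescribed_minutes = minutes, seed = 5)
    cohort <- generate_cohort(spec)
    mean(cohort$duration[cohort$duration > 0])
  }
  m45 <- mk(45)
  m60 <- mk(60)
  expect_gt(m60, m45 + 10)
})

test_that("cohort generation is deterministic in the specification seed", {
  spec <- cohort_spec(6, seed = 123)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  c <- generate_cohort(cohort_spec(6, seed = 124))
  expect_false(identical(a$duration, c$duration))
})

test_that("weekly schedule shows as a lag-7 autocorrelation peak", {
  log <- generate_participant(archetype_preset("consistent"), n_days = 70, seed = 4)
  ac <- stats::acf(log$duration, lag.max = 10, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac), 7L)
})

test_that("empirical adherence rate matches the configured play process", {
  arch <- archetype_spec("consistent", play_probability = 0.85,
                         mean_duration = 30, duration_sd = 12)
  log <- generate_participant(arch, n_days = 20000, seed = 21)
  scheduled <- ((log$day_index - 1) %% 7) < 5
  rate <- mean(label_adherence(log)$adherent[scheduled])
  # played-day durations are a zero-truncated Gaussian
  p_over <- (1 - pnorm(10, 30, 12)) / (1 - pnorm(0, 30, 12))
  expected <- 0.85 * p_over
  se <- sqrt(expected * (1 - expected) / sum(scheduled))
  expect_lt(abs(rate - expected), 4 * se)
})

test_that("lapse archetype produces multi-day missed runs", {
  arch <- archetype_spec("consistent_with_lapses", play_probability = 0.7,
                         mean_duration = 45, duration_sd = 5,
                         lapse_run_length = 3)
  log <- generate_participant(arch, n_days = 5000, seed = 8)
  scheduled <- ((log$day_index - 1) %% 7) < 5
  miss <- rle(log$duration[scheduled] == 0)
  runs <- miss$lengths[miss$values]
  # geometric with mean 3: average missed-run length well above 1
  expect_gt(mean(runs), 2)
  expect_lt(abs(mean(log$duration[scheduled] > 0) - 0.7), 0.05)
})
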