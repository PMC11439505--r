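#' Archetypal playing patterns
#'
#' An archetype describes one qualitative pattern of engagement with a
#' prescribed tablet-based training schedule. Four archetypes cover the
#' patterns seen in daily play-time records of older adults in cognitive
#' training trials: participants who essentially never play
#' (`non_player`), who play nearly every scheduled day (`consistent`), who
#' play consistently but with multi-day lapses (`consistent_with_lapses`),
#' and whose engagement is unpredictable (`erratic`).
#'
#' @param name Archetype name, one of `"non_player"`, `"consistent"`,
#'   `"consistent_with_lapses"`, `"erratic"`.
#' @param play_probability Probability of playing on a scheduled day, in
#'   \[0, 1\]. For `consistent_with_lapses` this is the long-run fraction of
#'   scheduled days played under the lapse-run process.
#' @param mean_duration Mean play time (minutes) on a day the participant
#'   plays; durations are drawn from a zero-truncated Gaussian.
#' @param duration_sd Standard deviation (minutes) of the duration draw.
#' @param lapse_run_length Mean length (days) of a run of consecutive missed
#'   scheduled days; only used by `consistent_with_lapses`.
#' @param level_growth_rate Expected increase of the maximum task level per
#'   played day.
#'
#' @return A list of class `archetype_spec`.
#' @seealso [archetype_preset()] for the calibrated defaults,
#'   [generate_participant()].
#' @export
archetype_spec <- function(name,
                           play_probability,
                           mean_duration,
                           duration_sd = 0,
                           lapse_run_length = 1,
                           level_growth_rate = 0.5) {
  valid <- c("non_player", "consistent", "consistent_with_lapses", "erratic")
  if (!is.character(name) || length(name) != 1L || !name %in% valid) {
    abort(sprintf(
      "Unknown archetype name %s; must be one of %s.",
      deparse(name), paste0('"', valid, '"', collapse = ", ")
    ))
  }
  assert_number(play_probability, "play_probability", 0, 1)
  assert_number(mean_duration, "mean_duration", 0)
  assert_number(duration_sd, "duration_sd", 0)
  assert_number(lapse_run_length, "lapse_run_length", 1)
  assert_number(level_growth_rate, "level_growth_rate", 0)
  structure(
    list(
      name = name,
      play_probability = play_probability,
      mean_duration = mean_duration,
      duration_sd = duration_sd,
      lapse_run_length = lapse_run_length,
      level_growth_rate = level_growth_rate
    ),
    class = "archetype_spec"
  )
}

#' Calibrated archetype presets
#'
#' Default parameterizations of the four playing archetypes, scaled to a
#' prescribed session length. The values are calibrated qualitatively: a
#' `non_player` almost never opens the app and rarely for long; a
#' `consistent` participant plays close to every scheduled day for about the
#' prescribed time; `consistent_with_lapses` interleaves adherent stretches
#' with multi-day missed runs; `erratic` participants play on and off
#' schedule with highly variable session lengths.
#'
#' @param name Archetype name (see [archetype_spec()]).
#' @param prescribed_minutes Target session length of the study protocol
#'   (typically 45 or 60 minutes).
#' @return An `archetype_spec`.
#' @export
archetype_preset <- function(name, prescribed_minutes = 45) {
  assert_number(prescribed_minutes, "prescribed_minutes", 1)
  switch(name,
    non_player = archetype_spec(
      "non_player",
      play_probability = 0.05, mean_duration = 8, duration_sd = 5,
      level_growth_rate = 0.1
    ),
    consistent = archetype_spec(
      "consistent",
      play_probability = 0.95, mean_duration = prescribed_minutes,
      duration_sd = 8, level_growth_rate = 0.6
    ),
    consistent_with_lapses = archetype_spec(
      "consistent_with_lapses",
      play_probability = 0.7, mean_duration = prescribed_minutes,
      duration_sd = 8, lapse_run_length = 3, level_growth_rate = 0.5
    ),
    erratic = archetype_spec(
      "erratic",
      play_probability = 0.5, mean_duration = 0.6 * prescribed_minutes,
      duration_sd = 20, level_growth_rate = 0.3
    ),
    abort(sprintf("Unknown archetype name %s.", deparse(name)))
  )
}

# Zero-truncated Gaussian durations via inverse-CDF so that sd = 0 is exact
# and played days always have duration > 0.
rtrunc_duration <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  if (sd <= 0) return(rep(max(mean, 0), n))
  lo <- stats::pnorm(0, mean, sd)
  u <- stats::runif(n, lo, 1)
  stats::qnorm(u, mean, sd)
}

# Play/lapse decisions on scheduled days. Bernoulli for most archetypes; a
# two-state Markov chain for consistent_with_lapses whose missed runs have
# geometric mean length lapse_run_length and whose stationary play
# probability equals play_probability.
draw_played <- function(archetype, scheduled) {
  n <- length(scheduled)
  played <- logical(n)
  p <- archetype$play_probability
  if (archetype$name == "consistent_with_lapses" && p > 0 && p < 1) {
    q_lp <- 1 / archetype$lapse_run_length            # lapse -> play
    q_pl <- min(1, q_lp * (1 - p) / p)                # play -> lapse
    state <- stats::runif(1) < p
    for (i in seq_len(n)) {
      if (scheduled[i]) {
        played[i] <- state
        state <- if (state) stats::runif(1) >= q_pl else stats::runif(1) < q_lp
      }
    }
  } else {
    p_off <- if (archetype$name == "erratic") p / 2 else 0
    prob <- ifelse(scheduled, p, p_off)
    played <- stats::runif(n) < prob
  }
  played
}

#' Simulate one participant's daily play log
#'
#' Generates `n_days` of daily records (duration played, sessions, maximum
#' task level, tasks completed) under a weekly prescribed schedule: the
#' first `schedule_days` days of every 7-day week are scheduled play days.
#' On scheduled days the participant plays according to the archetype; on
#' unscheduled days duration is 0 (the `erratic` archetype occasionally
#' plays off schedule). Durations on played days follow a zero-truncated
#' Gaussian; sessions are 1 on played days; tasks are Poisson with mean
#' proportional to duration; the maximum level is a noisy monotone ramp over
#' played days.
#'
#' @param archetype An [archetype_spec()].
#' @param n_days Number of study days to simulate.
#' @param schedule_days Prescribed play days per 7-day week (default 5).
#' @param seed Integer seed; identical inputs give identical logs.
#' @param participant_id,study_id Identifiers stamped on every row.
#' @return A tibble with columns `participant_id`, `study_id`, `day_index`,
#'   `duration` (minutes), `sessions`, `max_level`, `tasks`.
#' @examples
#' generate_participant(archetype_preset("consistent"), n_days = 14, seed = 1)
#' @export
generate_participant <- function(archetype, n_days, schedule_days = 5,
                                 seed = 1L, participant_id = "p01",
                                 study_id = "study1") {
  if (!inherits(archetype, "archetype_spec")) {
    abort("`archetype` must be an `archetype_spec` (see `archetype_preset()`).")
  }
  assert_number(n_days, "n_days", 1)
  assert_number(schedule_days, "schedule_days", 0, 7)
  local_seed(seed, {
    day <- seq_len(n_days)
    scheduled <- ((day - 1L) %% 7L) < schedule_days
    played <- draw_played(archetype, scheduled)
    duration <- numeric(n_days)
    duration[played] <- rtrunc_duration(
      sum(played), archetype$mean_duration, archetype$duration_sd
    )
    played <- duration > 0
    sessions <- as.integer(played)
    tasks <- integer(n_days)
    tasks[played] <- stats::rpois(sum(played), 0.25 * duration[played])
    level <- integer(n_days)
    if (any(played)) {
      inc <- stats::rpois(sum(played), archetype$level_growth_rate)
      level[played] <- 1L + cumsum(inc)
    }
    tibble(
      participant_id = participant_id,
      study_id = study_id,
      day_index = day,
      duration = duration,
      sessions = sessions,
      max_level = level,
      tasks = tasks
    )
  })
}

#' Cohort simulation settings
#'
#' Bundles everything needed to simulate a study cohort: size, length,
#' archetype mixture, the prescribed weekly schedule and session length, and
#' a domain-disparity knob. `shift` scales per-participant random offsets
#' applied to the archetype parameters (additive jitter with standard
#' deviation `0.08 * shift` on the play probability and `8 * shift` minutes
#' on the mean duration), so `shift = 0` gives exchangeable participants
#' within an archetype and larger values give increasingly participant-
#' specific distributions.
#'
#' @param n_participants Number of participants.
#' @param n_days Days of structured-phase data per participant (default 60,
#'   supporting the default 30-day train / 30-day test split).
#' @param archetype_mix Named proportions over archetype names, summing to 1.
#' @param schedule_days Prescribed play days per week (default 5).
#' @param prescribed_minutes Target session length in minutes (default 45).
#' @param shift Nonnegative domain-disparity level (default 1).
#' @param study_id Cohort label stamped on every row.
#' @param archetypes Optional named list of [archetype_spec()]s overriding
#'   the presets for the names in `archetype_mix` (e.g. to sharpen the
#'   separation between patterns).
#' @param seed Integer master seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants,
                        n_days = 60,
                        archetype_mix = c(
                          non_player = 0.25, consistent = 0.25,
                          consistent_with_lapses = 0.25, erratic = 0.25
                        ),
                        schedule_days = 5,
                        prescribed_minutes = 45,
                        shift = 1,
                        study_id = "study1",
                        archetypes = NULL,
                        seed = 1L) {
  assert_number(n_participants, "n_participants", 1)
  assert_number(n_days, "n_days", 1)
  assert_number(shift, "shift", 0)
  assert_number(prescribed_minutes, "prescribed_minutes", 1)
  if (is.null(names(archetype_mix)) || any(!nzchar(names(archetype_mix)))) {
    abort("`archetype_mix` must be a named vector of proportions.")
  }
  if (abs(sum(archetype_mix) - 1) > 1e-8) {
    abort(sprintf(
      "`archetype_mix` must sum to 1 (got %.6f).", sum(archetype_mix)
    ))
  }
  if (!is.null(archetypes)) {
    if (!all(vapply(archetypes, inherits, logical(1), "archetype_spec"))) {
      abort("`archetypes` must be a named list of `archetype_spec` objects.")
    }
    missing <- setdiff(names(archetype_mix), names(archetypes))
    if (length(missing) > 0L) {
      abort(sprintf(
        "`archetypes` lacks definitions for: %s.", paste(missing, collapse = ", ")
      ))
    }
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_days = as.integer(n_days),
      archetype_mix = archetype_mix,
      schedule_days = schedule_days,
      prescribed_minutes = prescribed_minutes,
      shift = shift,
      study_id = study_id,
      archetypes = archetypes,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# Apply per-participant jitter to an archetype; clamped to valid ranges.
jitter_archetype <- function(base, shift) {
  if (shift <= 0) return(base)
  p <- min(0.98, max(0.02, base$play_probability + stats::rnorm(1, 0, 0.08 * shift)))
  m <- max(2, base$mean_duration + stats::rnorm(1, 0, 8 * shift))
  archetype_spec(
    base$name, p, m, base$duration_sd,
    base$lapse_run_length, base$level_growth_rate
  )
}

#' Simulate a cohort of play logs
#'
#' Draws an archetype per participant from the mixture, applies the
#' per-participant parameter jitter controlled by `shift`, and simulates
#' each participant with [generate_participant()] under seeds derived from
#' the master seed. The same `cohort_spec` always yields an identical
#' cohort.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble (one row per participant-day, play-log schema) with
#'   attribute `"archetypes"`: a tibble of each participant's assigned
#'   archetype and realized parameters.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_participants = 4, seed = 7))
#' dplyr::count(cohort, participant_id)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    abort("`spec` must be a `cohort_spec`.")
  }
  n <- spec$n_participants
  ids <- sprintf("%s_p%03d", spec$study_id, seq_len(n))
  local_seed(spec$seed, {
    assigned <- sample(
      names(spec$archetype_mix), n,
      replace = TRUE, prob = spec$archetype_mix
    )
    archetypes <- map(assigned, function(a) {
      base <- if (!is.null(spec$archetypes)) {
        spec$archetypes[[a]]
      } else {
        archetype_preset(a, spec$prescribed_minutes)
      }
      jitter_archetype(base, spec$shift)
    })
    seeds <- sample.int(2147483646L, n)
    logs <- purrr::pmap(
      list(archetypes, seeds, ids),
      function(arch, s, id) {
        generate_participant(
          arch, spec$n_days, spec$schedule_days,
          seed = s, participant_id = id, study_id = spec$study_id
        )
      }
    )
    meta <- tibble(
      participant_id = ids,
      study_id = spec$study_id,
      archetype = assigned,
      play_probability = map_dbl(archetypes, "play_probability"),
      mean_duration = map_dbl(archetypes, "mean_duration")
    )
    out <- list_rbind(logs)
    attr(out, "archetypes") <- meta
    out
  })
}

#' True archetype assignment of a simulated cohort
#'
#' @param cohort A tibble from [generate_cohort()].
#' @return The per-participant archetype tibble recorded at simulation time.
#' @export
cohort_archetypes <- function(cohort) {
  meta <- attr(cohort, "archetypes")
  if (is.null(meta)) {
    abort("`cohort` carries no archetype metadata; was it generated by `generate_cohort()`?")
  }
  meta
}
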