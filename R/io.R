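#' Write a play-log CSV
#'
#' Persists a cohort in the interchange schema (schema version 1): one row
#' per participant-day with columns `participant_id`, `study_id`,
#' `day_index`, `duration_min`, `sessions`, `max_level`, `tasks`.
#'
#' @param log Play-log tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_play_log <- function(log, path) {
  assert_play_log(log)
  out <- log |>
    select(all_of(play_log_columns)) |>
    rename(duration_min = "duration")
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a play-log CSV
#'
#' Reads the interchange schema written by [write_play_log()] (the
#' `duration_min` column may also be named `duration`). Rows are grouped by
#' participant and sorted by day index; calendar gaps in `day_index` are
#' filled with all-zero days — absence of play is informative non-play, not
#' missing data — and flagged in the logical `gap_filled` column. Malformed
#' or negative values are rejected with their row numbers.
#'
#' @param path CSV path.
#' @return A play-log tibble with an extra `gap_filled` column.
#' @export
read_play_log <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if ("duration_min" %in% names(raw)) raw <- rename(raw, duration = "duration_min")
  missing <- setdiff(play_log_columns, names(raw))
  if (length(missing) > 0L) {
    abort(sprintf(
      "Play-log schema error in %s: missing column(s) %s.",
      path, paste0("`", missing, "`", collapse = ", ")
    ))
  }
  num_cols <- c("day_index", "duration", "sessions", "max_level", "tasks")
  parsed <- raw
  for (j in num_cols) parsed[[j]] <- suppressWarnings(as.numeric(raw[[j]]))
  bad <- which(rowSums(is.na(parsed[num_cols])) > 0)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Malformed play-log row(s) at line(s) %s of %s (non-numeric values).",
      paste(utils::head(bad + 1L, 5), collapse = ", "), path
    ))
  }
  neg <- which(rowSums(parsed[num_cols] < 0) > 0)
  if (length(neg) > 0L) {
    abort(sprintf(
      "Negative values in play-log row(s) at line(s) %s of %s.",
      paste(utils::head(neg + 1L, 5), collapse = ", "), path
    ))
  }
  parsed <- parsed |>
    mutate(across(c("day_index", "sessions", "max_level", "tasks"), as.integer)) |>
    arrange(.data$participant_id, .data$day_index)
  filled <- parsed |>
    group_by(.data$participant_id, .data$study_id) |>
    tidyr::complete(day_index = seq_len(max(.data$day_index))) |>
    ungroup() |>
    mutate(
      gap_filled = is.na(.data$duration),
      duration = tidyr::replace_na(.data$duration, 0),
      sessions = tidyr::replace_na(.data$sessions, 0L),
      max_level = tidyr::replace_na(.data$max_level, 0L),
      tasks = tidyr::replace_na(.data$tasks, 0L)
    ) |>
    select(all_of(play_log_columns), "gap_filled") |>
    arrange(.data$participant_id, .data$day_index)
  n_gaps <- sum(filled$gap_filled)
  if (n_gaps > 0) {
    inform(sprintf("Zero-filled %d missing day(s) across participants.", n_gaps))
  }
  as_tibble(filled)
}

run_config_defaults <- function() {
  list(
    threshold_minutes = 10,
    train_days = 30,
    test_days = 30,
    fallback_n = 7,
    window_size = NULL,
    k = 4,
    extractor = "flatten_pca",
    feature_dim = 8,
    span = "full",
    protocol = "within",
    lambda = 1,
    lambda_schedule = "fixed",
    domain_head_units = 8,
    source_weight = 1,
    kernel_size = 2,
    pool_size = 2,
    filters = c(8, 16),
    dense_units = 16,
    epochs = 200,
    batch_size = 8,
    learning_rate = 1e-3,
    early_stop_patience = 20,
    validation_fraction = 0.2,
    class_weights = FALSE,
    seed = 1
  )
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON-as-YAML) configuration file and fills every
#' omitted field with the study defaults (10-minute adherence criterion,
#' 30/30 chronological split, fallback window size 7, K = 4 clusters, and
#' the documented model hyperparameters). Unknown keys are rejected, listing
#' them, so typos cannot silently fall back to defaults. The fully resolved
#' configuration can be echoed to a run directory for provenance.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @param echo_dir Optional directory; when given, the resolved
#'   configuration plus package version is written there as
#'   `run_config.yaml`.
#' @return A list of class `run_config`.
#' @export
load_config <- function(path = NULL, echo_dir = NULL) {
  defaults <- run_config_defaults()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.list(user)) abort(sprintf("Config file %s must contain a mapping.", path))
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    abort(sprintf(
      "Unknown config key(s): %s. Valid keys: %s.",
      paste0("`", unknown, "`", collapse = ", "),
      paste(names(defaults), collapse = ", ")
    ))
  }
  cfg <- utils::modifyList(defaults, user, keep.null = TRUE)
  cfg <- structure(cfg, class = "run_config")
  if (!is.null(echo_dir)) {
    dir.create(echo_dir, showWarnings = FALSE, recursive = TRUE)
    echo <- unclass(cfg)
    echo$package_version <- as.character(utils::packageVersion("adhereda"))
    yaml::write_yaml(echo, file.path(echo_dir, "run_config.yaml"))
  }
  cfg
}

#' Model configurations from a run configuration
#'
#' @param cfg A `run_config` from [load_config()].
#' @return A list with `cnn` ([cnn_config()]) and `dann` ([dann_config()]).
#' @export
model_configs <- function(cfg) {
  if (!inherits(cfg, "run_config")) abort("`cfg` must be a `run_config`.")
  cnn <- cnn_config(
    kernel_size = cfg$kernel_size, pool_size = cfg$pool_size,
    filters = cfg$filters, dense_units = cfg$dense_units,
    epochs = cfg$epochs, batch_size = cfg$batch_size,
    learning_rate = cfg$learning_rate,
    early_stop_patience = cfg$early_stop_patience,
    validation_fraction = cfg$validation_fraction,
    class_weights = cfg$class_weights, seed = cfg$seed
  )
  list(
    cnn = cnn,
    dann = dann_config(
      base = cnn, lambda = cfg$lambda, lambda_schedule = cfg$lambda_schedule,
      domain_head_units = cfg$domain_head_units,
      source_weight = cfg$source_weight
    )
  )
}
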