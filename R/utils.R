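#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map2 imap list_rbind
NULL

# Run code under a fixed RNG seed without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Derive a child seed from a master seed and a stream label, keeping the
# result a valid 32-bit integer. Distinct labels give distinct streams.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483399) + 1L
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, lower, upper))
  }
  invisible(x)
}

play_log_columns <- c(
  "participant_id", "study_id", "day_index",
  "duration", "sessions", "max_level", "tasks"
)

assert_play_log <- function(log, arg = "log") {
  missing <- setdiff(play_log_columns, names(log))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is not a play log: missing column(s) %s.",
      arg, paste0("`", missing, "`", collapse = ", ")
    ))
  }
  invisible(log)
}
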