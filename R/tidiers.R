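#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-participant results of an experiment
#'
#' @param x An `experiment_result`.
#' @param ... Unused.
#' @return The per-participant long tibble: one row per participant and
#'   arm with the four evaluation metrics.
#' @export
tidy.experiment_result <- function(x, ...) {
  x$per_participant
}

#' One-row summary of an experiment
#'
#' @param x An `experiment_result`.
#' @param ... Unused.
#' @return A one-row tibble with the protocol, sizes, and the mean accuracy
#'   of each arm.
#' @export
glance.experiment_result <- function(x, ...) {
  acc <- stats::setNames(x$aggregate$accuracy_mean, x$aggregate$arm)
  tibble(
    protocol = x$protocol,
    n_participants = length(unique(x$per_participant$participant_id)),
    k = x$k,
    window_size = x$window_size,
    accuracy_no_source_no_da = acc[["no_source_no_da"]],
    accuracy_with_source_no_da = acc[["with_source_no_da"]],
    accuracy_with_source_with_da = acc[["with_source_with_da"]]
  )
}

#' Plot the aggregate metrics of an experiment
#'
#' Dot-and-error-bar panel of the cohort-mean evaluation metrics per arm
#' (error bars: across-participant SD).
#'
#' @param object An `experiment_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.experiment_result <- function(object, ...) {
  long <- object$aggregate |>
    tidyr::pivot_longer(
      -"arm",
      names_to = c("metric", "stat"), names_pattern = "(.*)_(mean|sd)"
    ) |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value") |>
    mutate(arm = factor(.data$arm, levels = arm_names))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$arm, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(0, .data$mean - .data$sd),
      ymax = pmin(1, .data$mean + .data$sd)
    )) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = "score (mean ± SD over participants)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' Tidy a trained adherence model's training history
#'
#' @param x An `adherence_cnn`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: training label loss, training
#'   domain loss (DA models), and validation loss.
#' @export
tidy.adherence_cnn <- function(x, ...) {
  if (!isTRUE(x$trained)) abort("Model is untrained; no history to tidy.")
  x$history
}

#' One-row summary of a trained adherence model
#'
#' @param x An `adherence_cnn`.
#' @param ... Unused.
#' @return A one-row tibble: arm, parameter count, epochs run, best epoch
#'   and best validation loss.
#' @export
glance.adherence_cnn <- function(x, ...) {
  tibble(
    arm = x$arm %||% NA_character_,
    n_parameters = sum(vapply(x$weights, length, numeric(1))),
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    n_source_windows = x$n_source_windows %||% 0L
  )
}

#' Plot a training history
#'
#' @param object A trained `adherence_cnn`.
#' @param ... Unused.
#' @return A ggplot of the loss curves per epoch.
#' @export
autoplot.adherence_cnn <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(-"epoch", names_to = "series", values_to = "loss") |>
    filter(is.finite(.data$loss))
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$loss, color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the daily play pattern of a cohort
#'
#' Heatmap of daily play duration (participants x days), the raw pattern
#' the GAF encoding and clustering operate on.
#'
#' @param log A play-log tibble.
#' @return A ggplot object.
#' @export
plot_play_pattern <- function(log) {
  assert_play_log(log)
  ggplot2::ggplot(log, ggplot2::aes(
    x = .data$day_index, y = .data$participant_id, fill = .data$duration
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(
      colors = gaf_palette("ylgnbu", 64), name = "minutes"
    ) +
    ggplot2::labs(x = "study day", y = NULL) +
    ggplot2::theme_minimal()
}
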