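#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with one row per class: `class`, `accuracy`, plus the
#'   cascade and variant tags.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  dplyr::mutate(x$per_class, cascade = x$cascade,
                variant = x$variant %||% NA_character_)
}

#' @rdname tidy.cv_result
#' @return For `glance()`: a one-row tibble with `average`, `n_instances`,
#'   `k_folds`, `cascade`, `variant`.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(average = x$average, n_instances = sum(x$confusion),
                 k_folds = length(unique(x$folds)), cascade = x$cascade,
                 variant = x$variant %||% NA_character_)
}

#' Tidy a protocol report
#'
#' @param x A `protocol_report`.
#' @param ... Unused.
#' @return Long tibble over all evaluated cells: `round`, `variant`,
#'   `cascade`, per-class and average accuracies.
#' @method tidy protocol_report
#' @export
tidy.protocol_report <- function(x, ...) {
  pieces <- list()
  if (!is.null(x$round1)) pieces$`1` <- x$round1
  if (!is.null(x$round2)) pieces$`2` <- x$round2
  if (!is.null(x$round3)) pieces$`3` <- x$round3
  dplyr::bind_rows(pieces, .id = "round") |>
    dplyr::mutate(round = as.integer(.data$round)) |>
    dplyr::select(-"selected")
}

#' @rdname tidy.protocol_report
#' @return For `glance()`: one row with the final model's variant, cascade,
#'   accuracy, number of selected attributes and holdout majority.
#' @method glance protocol_report
#' @export
glance.protocol_report <- function(x, ...) {
  tibble::tibble(
    final_variant = x$final$variant,
    final_cascade = x$final$cascade,
    final_average = x$final$average,
    n_selected = length(x$final$selected %||% character()),
    holdout_majority = if (is.null(x$holdout)) NA_character_ else
      x$holdout$majority
  )
}

#' Plot group curves (memorization / pleasantness indexes)
#'
#' @param object A `group_curves` tibble.
#' @param ... Unused.
#' @return A ggplot: smoothed envelope over stimulus time per group.
#' @method autoplot group_curves
#' @export
autoplot.group_curves <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data$value,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (s)",
      y = unique(object$index),
      title = sprintf("%s, %s band", unique(object$index),
                      unique(object$band))) +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation confusion matrix
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot heat map of the confusion matrix.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("%s: %.2f%% macro accuracy",
                                  object$cascade, object$average)) +
    ggplot2::theme_minimal()
}

#' Plot protocol accuracies across rounds
#'
#' @param object A `protocol_report`.
#' @param ... Unused.
#' @return A ggplot of macro accuracy per variant and cascade, faceted by
#'   round.
#' @method autoplot protocol_report
#' @export
autoplot.protocol_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variant, y = .data$average,
                                   fill = .data$cascade)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(. ~ round, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "macro accuracy (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Per-instance cross-validation predictions
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with one row per instance: `subject`, `ad`, `true`,
#'   `predicted`, `fold`.
#' @method augment cv_result
#' @export
augment.cv_result <- function(x, ...) {
  x$predictions
}
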