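#' @export
tidy.dhm_confusion <- function(x, ...) {
  tibble::as_tibble(as.table(unclass(x))) |>
    dplyr::rename(count = "n")
}

#' @export
tidy.dhm_metrics <- function(x, ...) x$per_class

#' @export
glance.dhm_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 macro_sensitivity = x$macro_sensitivity,
                 macro_specificity = x$macro_specificity,
                 n = x$total)
}

#' @export
tidy.dhm_model <- function(x, ...) {
  if (is.null(x$cv)) {
    tibble::tibble(term = names(x$hyper),
                   value = as.character(unlist(x$hyper)))
  } else x$cv
}

#' @export
glance.dhm_model <- function(x, ...) {
  tibble::tibble(family = x$family,
                 n_classes = length(x$classes),
                 hyperparameters = paste(names(x$hyper), unlist(x$hyper),
                                         sep = "=", collapse = ", "))
}

#' @export
tidy.dhm_gridsearch <- function(x, ...) x$summary

#' @export
glance.dhm_gridsearch <- function(x, ...) {
  best <- x$summary[x$summary$point == x$best_point, ]
  dplyr::bind_cols(tibble::tibble(family = x$family), best)
}

#' @export
tidy.dhm_loso <- function(x, ...) x$per_subject

#' @export
glance.dhm_loso <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "metric",
                       values_from = c("mean", "sd"))
}

#' @export
tidy.dhm_comparison <- function(x, ...) x$per_class

#' @export
glance.dhm_comparison <- function(x, ...) x$overall

#' Heatmap of a confusion matrix
#'
#' @param object A [confusion_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dhm_confusion <- function(object, ...) {
  d <- tidy.dhm_confusion(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                  fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), color = "white") +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::labs(x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}

#' Composition time series plot
#'
#' Overlays one or more composition series (e.g. DHM-derived vs the
#' reference method) as proportion-versus-day lines, faceted by class and
#' subject.
#'
#' @param ... Composition tibbles (subject_id, matrix, day, class,
#'   proportion, source).
#' @return A ggplot object.
#' @export
plot_composition_series <- function(...) {
  d <- dplyr::bind_rows(...)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$proportion,
                                  color = .data$source)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(dplyr::vars(.data$class),
                        dplyr::vars(.data$subject_id)) +
    ggplot2::labs(x = "sampling day", y = "class proportion") +
    ggplot2::theme_minimal()
}

#' KDE overlays for a before/after feature-shift report
#'
#' @param object A [feature_shift_report()].
#' @param features Feature names to display (default: the six with the
#'   largest absolute effect size).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dhm_feature_shift <- function(object, features = NULL, ...) {
  data <- attr(object, "data")
  split_day <- attr(object, "split_day")
  features <- features %||%
    object$feature[order(-abs(object$cohens_d))][1:min(6, nrow(object))]
  long <- data |>
    dplyr::mutate(period = ifelse(.data$day <= split_day,
                                  "before", "after")) |>
    tidyr::pivot_longer(dplyr::all_of(features),
                        names_to = "feature", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value,
                                     color = .data$period)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(dplyr::vars(.data$feature), scales = "free") +
    ggplot2::labs(x = NULL, y = "density") +
    ggplot2::theme_minimal()
}
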