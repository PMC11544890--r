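#' Confusion matrix
#'
#' @param truth,predicted Equal-length label vectors; all labels must be
#'   among `classes`.
#' @param classes Ordered class labels; default: sorted union of the labels.
#' @return A `dhm_confusion`: integer C x C matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  classes <- classes %||% sort(unique(c(truth, predicted)))
  unknown <- setdiff(unique(c(truth, predicted)), classes)
  if (length(unknown))
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  tf <- factor(truth, levels = classes)
  pf <- factor(predicted, levels = classes)
  m <- table(tf, pf)
  cm <- matrix(as.integer(m), length(classes), length(classes),
               dimnames = list(truth = classes, predicted = classes))
  structure(cm, class = c("dhm_confusion", class(cm)))
}

#' @export
print.dhm_confusion <- function(x, ...) {
  print(matrix(as.integer(x), nrow(x), ncol(x), dimnames = dimnames(x)))
  invisible(x)
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' One-vs-rest per class: sensitivity is TP/(TP+FN), specificity is
#' TN/(TN+FP). Macro values are unweighted means over classes; classes with
#' zero support have undefined sensitivity and are excluded from the macro
#' mean with a warning.
#'
#' @param cm A [confusion_matrix()].
#' @return A `dhm_metrics` list: `accuracy`, `per_class` tibble (class,
#'   sensitivity, specificity, support), `macro_sensitivity`,
#'   `macro_specificity`, `total`.
#' @export
classification_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0L) stop("confusion matrix has zero total")
  classes <- rownames(cm)
  tp <- diag(cm)
  support <- rowSums(cm)
  fp <- colSums(cm) - tp
  fn <- support - tp
  tn <- total - tp - fp - fn
  sens <- ifelse(support > 0, tp / (tp + fn), NA_real_)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  if (anyNA(sens))
    warning("class(es) with zero support excluded from macro sensitivity: ",
            paste(classes[is.na(sens)], collapse = ", "))
  structure(
    list(accuracy = sum(tp) / total,
         per_class = tibble::tibble(class = classes,
                                    sensitivity = unname(sens),
                                    specificity = unname(spec),
                                    support = unname(as.integer(support))),
         macro_sensitivity = mean(sens, na.rm = TRUE),
         macro_specificity = mean(spec, na.rm = TRUE),
         total = total),
    class = "dhm_metrics")
}

#' Leave-one-subject-out validation
#'
#' One fold per subject: all rows of the held-out subject form the test
#' set, the remaining subjects' rows (SMOTE-balanced by default) the
#' training set, so train and test never share a subject. Reports per-fold
#' metrics and their mean/SD across folds.
#'
#' @param table Labeled feature table with a `subject_id` column (>= 2
#'   distinct subjects, no synthetic rows).
#' @param family,hyper,balance,smote_k,seed As in [fit_classifier()] /
#'   [grid_search_cv()].
#' @return A `dhm_loso`: `per_subject` tibble (subject, accuracy, macro
#'   sensitivity/specificity, n_test) and `summary` tibble (metric, mean,
#'   sd).
#' @export
leave_one_subject_out <- function(table, family = "rf", hyper = list(),
                                  balance = TRUE, smote_k = 5L, seed = 1L) {
  if (!all(c("class", "subject_id") %in% names(table)))
    stop("table needs `class` and `subject_id` columns")
  if (".synthetic" %in% names(table) && any(table$.synthetic))
    stop("table contains synthetic rows; LOSO must start from real cells")
  subjects <- unique(table$subject_id)
  if (length(subjects) < 2L) stop("need >= 2 distinct subjects")
  schema <- attr(table, "dhm_schema")
  res <- purrr::map_dfr(subjects, function(s) {
    tr <- table[table$subject_id != s, ]
    te <- table[table$subject_id == s, ]
    attr(tr, "dhm_schema") <- schema
    attr(te, "dhm_schema") <- schema
    if (balance)
      tr <- smote_balance(tr, k_neighbors = smote_k,
                          seed = derive_seed(seed, "loso-smote", s))
    model <- fit_classifier(tr, family, hyper,
                            seed = derive_seed(seed, "loso-fit", s))
    met <- classification_metrics(
      confusion_matrix(te$class, predict(model, te), model$classes))
    tibble::tibble(subject_id = s, accuracy = met$accuracy,
                   macro_sensitivity = met$macro_sensitivity,
                   macro_specificity = met$macro_specificity,
                   n_test = nrow(te))
  })
  summary <- res |>
    tidyr::pivot_longer(c("accuracy", "macro_sensitivity",
                          "macro_specificity"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")
  structure(list(per_subject = res, summary = summary, family = family),
            class = "dhm_loso")
}

#' Per-sample class composition from predicted labels
#'
#' @param labels Non-empty label vector for one sample.
#' @param classes Ordered class labels; default: sorted unique labels.
#' @return A tibble (class, proportion); proportions sum to 1.
#' @export
sample_composition <- function(labels, classes = NULL) {
  if (length(labels) == 0L) stop("empty sample")
  classes <- classes %||% sort(unique(labels))
  counts <- table(factor(labels, levels = classes))
  tibble::tibble(class = classes,
                 proportion = as.numeric(counts) / length(labels))
}

#' Composition series from per-cell predictions
#'
#' Aggregates a tibble of per-cell predicted labels into a tidy composition
#' series (one proportion per subject, day and class).
#'
#' @param predictions Tibble with `subject_id`, `matrix`, `day`, `class`.
#' @param classes Ordered class labels.
#' @param source Label stored in the `source` column.
#' @return A composition tibble (subject_id, matrix, day, class,
#'   proportion, source).
#' @export
composition_series <- function(predictions, classes = NULL,
                               source = "DHM") {
  classes <- classes %||% sort(unique(predictions$class))
  predictions |>
    dplyr::group_by(.data$subject_id, .data$matrix, .data$day) |>
    dplyr::group_modify(function(d, key) sample_composition(d$class, classes)) |>
    dplyr::ungroup() |>
    dplyr::mutate(source = source)
}

#' Compare two composition series
#'
#' Aligns a test series with a reference series on (subject, matrix, day,
#' class) and reports MAE, RMSE and MRE, overall, per class and per
#' subject (with a mean/SD summary across subjects). MRE averages
#' `|t - r| / r` over the pairs whose reference value is positive;
#' reference-zero pairs are
#' skipped and counted.
#'
#' @param test,reference Composition tibbles (as from
#'   [composition_series()] or a study's reference series).
#' @return A `dhm_comparison`: `overall`, `per_class`, `per_subject`,
#'   `subject_summary` tibbles, plus `n_pairs` and `mre_skipped`.
#' @export
compare_series <- function(test, reference) {
  key <- c("subject_id", "matrix", "day", "class")
  t2 <- dplyr::select(test, dplyr::all_of(key), t = "proportion")
  r2 <- dplyr::select(reference, dplyr::all_of(key), r = "proportion")
  joined <- dplyr::inner_join(t2, r2, by = key)
  if (nrow(joined) != nrow(t2) || nrow(joined) != nrow(r2))
    stop("test and reference series are misaligned (days/classes differ)")
  err_stats <- function(d) {
    e <- d$t - d$r
    pos <- d$r > 0
    tibble::tibble(mae = mean(abs(e)),
                   rmse = sqrt(mean(e^2)),
                   mre = if (any(pos)) mean(abs(e[pos]) / d$r[pos]) else NA_real_,
                   n_pairs = nrow(d), n_ref_zero = sum(!pos))
  }
  overall <- err_stats(joined)
  per_class <- joined |>
    dplyr::group_by(.data$class) |>
    dplyr::group_modify(function(d, key) err_stats(d)) |>
    dplyr::ungroup()
  per_subject <- joined |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(d, key) err_stats(d)) |>
    dplyr::ungroup()
  subject_summary <- per_subject |>
    tidyr::pivot_longer(c("mae", "rmse", "mre"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value), .groups = "drop")
  structure(list(overall = overall, per_class = per_class,
                 per_subject = per_subject,
                 subject_summary = subject_summary,
                 n_pairs = overall$n_pairs,
                 mre_skipped = overall$n_ref_zero),
            class = "dhm_comparison")
}

#' Before/after feature-distribution report
#'
#' A descriptive (non-inferential) check of whether cell morphology shifted
#' after an intervention such as vaccination: per feature, the standardized
#' mean difference (Cohen's d) between cells sampled up to `split_day` and
#' after it. Pairs with [autoplot.dhm_feature_shift()] KDE overlays.
#'
#' @param table Feature table with a `day` column.
#' @param split_day Last day counted as "before".
#' @return A `dhm_feature_shift` tibble (feature, mean_before, mean_after,
#'   pooled_sd, cohens_d, n_before, n_after).
#' @export
feature_shift_report <- function(table, split_day) {
  if (!"day" %in% names(table)) stop("table needs a `day` column")
  grp <- ifelse(table$day <= split_day, "before", "after")
  nms <- feature_columns(table)
  res <- purrr::map_dfr(nms, function(f) {
    a <- table[[f]][grp == "before"]; b <- table[[f]][grp == "after"]
    sp <- sqrt(((length(a) - 1) * sd(a)^2 + (length(b) - 1) * sd(b)^2) /
                 max(length(a) + length(b) - 2, 1))
    tibble::tibble(feature = f, mean_before = mean(a), mean_after = mean(b),
                   pooled_sd = sp,
                   cohens_d = if (sp > 0) (mean(b) - mean(a)) / sp else 0,
                   n_before = length(a), n_after = length(b))
  })
  attr(res, "split_day") <- split_day
  attr(res, "data") <- table[c("day", nms)]
  class(res) <- c("dhm_feature_shift", class(res))
  res
}
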