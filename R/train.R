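#' Stratified train/test split
#'
#' Reserves `test_fraction` of each class (rounded per class) for testing.
#' By default refuses tables containing SMOTE rows: interpolated copies in a
#' test set leak training information, so the supported protocol is
#' split-then-balance. Set `allow_synthetic = TRUE` only to reproduce the
#' balance-then-split ordering some published pipelines use.
#'
#' @param table Labeled feature table.
#' @param test_fraction Fraction in (0, 1); default 0.30.
#' @param seed Integer seed.
#' @param allow_synthetic Permit `.synthetic` rows in the input.
#' @return `list(train, test)` — disjoint, exhaustive tibbles.
#' @export
stratified_split <- function(table, test_fraction = 0.3, seed = 1L,
                             allow_synthetic = FALSE) {
  if (!"class" %in% names(table)) stop("table must have a `class` column")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)")
  if (!allow_synthetic && ".synthetic" %in% names(table) &&
      any(table$.synthetic))
    stop("table contains synthetic (SMOTE) rows; split before balancing")
  counts <- table(table$class)
  if (any(counts < 2L))
    stop("every class needs >= 2 rows to split")
  test_idx <- with_seed_if(seed, {
    unlist(lapply(names(counts), function(cl) {
      rows <- which(table$class == cl)
      sample(rows, round(test_fraction * length(rows)))
    }), use.names = FALSE)
  })
  schema <- attr(table, "dhm_schema")
  train <- table[-test_idx, ]; test <- table[test_idx, ]
  attr(train, "dhm_schema") <- schema
  attr(test, "dhm_schema") <- schema
  list(train = train, test = test)
}

# stratified fold assignment: per class, shuffled round-robin
make_folds <- function(labels, folds, seed) {
  stopifnot(folds >= 2L)
  fold_id <- integer(length(labels))
  with_seed_if(seed, {
    for (cl in unique(labels)) {
      rows <- which(labels == cl)
      fold_id[rows] <- rep_len(seq_len(folds), length(rows))[sample.int(length(rows))]
    }
  })
  fold_id
}

#' Default hyperparameter grids
#'
#' @param family `"knn"`, `"rf"` or `"svm"`.
#' @return A named list of value vectors (the exhaustive grid is their
#'   cross product).
#' @export
default_grid <- function(family = c("knn", "rf", "svm")) {
  switch(match.arg(family),
         knn = list(k = c(1L, 3L, 5L, 11L, 21L)),
         rf = list(ntree = c(100L, 300L), mtry = c(4L, 8L, 12L)),
         svm = list(cost = c(0.1, 1, 10), gamma = c(NA, 0.01, 0.1)))
}

valid_hyper <- list(knn = "k", rf = c("ntree", "mtry"),
                    svm = c("cost", "gamma"))

check_hyper <- function(family, hyper) {
  bad <- setdiff(names(hyper), valid_hyper[[family]])
  if (length(bad))
    stop(sprintf("invalid %s hyperparameter(s): %s", family,
                 paste(bad, collapse = ", ")))
}

#' Grid search with stratified cross-validation
#'
#' Evaluates every grid point by k-fold stratified cross-validation on the
#' training table. Class balancing (SMOTE) is fitted inside each training
#' fold, never on the validation fold, so validation rows are always real
#' cells. The best point maximizes mean CV accuracy, with ties broken by
#' higher mean macro sensitivity and then deterministic grid order.
#'
#' @param table Labeled (unbalanced) training table.
#' @param family `"knn"`, `"rf"` or `"svm"`.
#' @param grid Named list of hyperparameter value vectors; default
#'   [default_grid()].
#' @param folds Number of CV folds (default 5).
#' @param balance Balance training folds with SMOTE.
#' @param smote_k SMOTE neighborhood size.
#' @param seed Integer seed.
#' @return A `dhm_gridsearch`: `best` (hyperparameter list), `summary`
#'   (per-point means), `report` (per point x fold accuracy, macro
#'   sensitivity/specificity).
#' @export
grid_search_cv <- function(table, family = c("knn", "rf", "svm"),
                           grid = NULL, folds = 5L, balance = TRUE,
                           smote_k = 5L, seed = 1L) {
  family <- match.arg(family)
  grid <- grid %||% default_grid(family)
  if (length(grid) == 0L) stop("grid must be non-empty")
  check_hyper(family, grid)
  if (!"class" %in% names(table)) stop("table must be labeled")
  points <- do.call(tidyr::expand_grid, grid)
  fold_id <- make_folds(table$class, folds, derive_seed(seed, "folds"))

  report <- vector("list", nrow(points) * folds)
  ri <- 0L
  for (g in seq_len(nrow(points))) {
    hyper <- as.list(points[g, ])
    for (f in seq_len(folds)) {
      tr <- table[fold_id != f, ]
      va <- table[fold_id == f, ]
      attr(tr, "dhm_schema") <- attr(table, "dhm_schema")
      if (balance)
        tr <- smote_balance(tr, k_neighbors = smote_k,
                            seed = derive_seed(seed, "smote", g, f))
      model <- fit_classifier(tr, family, hyper,
                              seed = derive_seed(seed, "fit", g, f))
      pred <- predict(model, va)
      cm <- confusion_matrix(va$class, pred, model$classes)
      met <- classification_metrics(cm)
      ri <- ri + 1L
      report[[ri]] <- tibble::tibble(
        point = g, fold = f, accuracy = met$accuracy,
        macro_sensitivity = met$macro_sensitivity,
        macro_specificity = met$macro_specificity)
    }
  }
  report <- dplyr::bind_rows(report)
  summary <- report |>
    dplyr::group_by(.data$point) |>
    dplyr::summarise(dplyr::across(c("accuracy", "macro_sensitivity",
                                     "macro_specificity"), mean),
                     .groups = "drop") |>
    dplyr::bind_cols(points[, , drop = FALSE])
  best_point <- summary$point[order(-summary$accuracy,
                                    -summary$macro_sensitivity,
                                    summary$point)][1]
  structure(list(best = as.list(points[best_point, ]),
                 best_point = best_point,
                 summary = summary, report = report,
                 family = family, folds = folds, seed = seed),
            class = "dhm_gridsearch")
}

#' Fit a classifier on a feature table
#'
#' Trains one of the three supported families on the (typically
#' SMOTE-balanced) labeled table. Features are z-standardized with the
#' training table's statistics for kNN and SVM; random forests use raw
#' features. The returned model stores the feature-schema fingerprint and
#' refuses prediction on tables with a different schema.
#'
#' @param table Labeled feature table.
#' @param family `"knn"`, `"rf"` or `"svm"`.
#' @param hyper Named list of hyperparameters (see [default_grid()]); kNN
#'   `k` defaults to 5, RF to `ntree = 300`, `mtry = floor(sqrt(24))`, SVM
#'   to `cost = 1` and the `1/p` gamma heuristic (`gamma = NA`).
#' @param seed Integer seed (controls RF bootstrap).
#' @param cv Optional CV summary attached to the model.
#' @return A `dhm_model`.
#' @export
fit_classifier <- function(table, family = c("knn", "rf", "svm"),
                           hyper = list(), seed = 1L, cv = NULL) {
  family <- match.arg(family)
  check_hyper(family, hyper)
  if (!"class" %in% names(table)) stop("table must be labeled")
  X <- feature_matrix(table)
  y <- factor(table$class)
  ctr <- colMeans(X)
  scl <- apply(X, 2, function(v) { s <- sd(v); if (is.na(s) || s == 0) 1 else s })
  fit <- switch(
    family,
    knn = {
      k <- as.integer(hyper$k %||% 5L)
      Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
      list(Z = Z, y = y, k = k)
    },
    rf = {
      ntree <- as.integer(hyper$ntree %||% 300L)
      mtry <- as.integer(hyper$mtry %||% floor(sqrt(ncol(X))))
      with_seed_if(seed, randomForest::randomForest(
        x = X, y = y, ntree = ntree, mtry = mtry))
    },
    svm = {
      cost <- hyper$cost %||% 1
      gamma <- hyper$gamma
      if (is.null(gamma) || is.na(gamma)) gamma <- 1 / ncol(X)
      Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
      with_seed_if(seed, e1071::svm(
        x = Z, y = y, kernel = "radial", cost = cost, gamma = gamma,
        scale = FALSE))
    })
  structure(list(family = family, hyper = hyper, fit = fit,
                 center = ctr, scale = scl,
                 fingerprint = feature_fingerprint(),
                 classes = levels(y), seed = seed, cv = cv),
            class = "dhm_model")
}

# deterministic kNN: majority vote; ties broken by smaller mean neighbor
# distance among tied classes, then class order
knn_predict <- function(fit, Znew) {
  ntr <- nrow(fit$Z)
  k <- min(fit$k, ntr)
  sq_tr <- rowSums(fit$Z^2)
  yi <- as.integer(fit$y)
  ncls <- nlevels(fit$y)
  n <- nrow(Znew)
  out <- integer(n)
  chunk <- max(1L, floor(4e6 / ntr))
  for (start in seq(1L, n, by = chunk)) {
    ii <- start:min(start + chunk - 1L, n)
    D <- outer(rowSums(Znew[ii, , drop = FALSE]^2), sq_tr, "+") -
      2 * Znew[ii, , drop = FALSE] %*% t(fit$Z)
    for (r in seq_along(ii)) {
      nb <- order(D[r, ])[seq_len(k)]
      cls <- yi[nb]
      votes <- tabulate(cls, ncls)
      top <- which(votes == max(votes))
      if (length(top) > 1L) {
        mean_d <- vapply(top, function(cc) mean(D[r, nb[cls == cc]]),
                         numeric(1))
        top <- top[order(mean_d, top)][1]
      }
      out[ii[r]] <- top[1]
    }
  }
  levels(fit$y)[out]
}

#' Predict class labels for a feature table
#'
#' @param object A `dhm_model`.
#' @param newdata Feature table (schema must match training).
#' @param ... Unused.
#' @return Character vector of labels, one per row.
#' @export
predict.dhm_model <- function(object, newdata, ...) {
  schema <- attr(newdata, "dhm_schema")
  fp <- if (!is.null(schema)) schema$fingerprint else feature_fingerprint()
  if (!identical(fp, object$fingerprint))
    stop("feature schema fingerprint mismatch between model and table")
  if (nrow(newdata) == 0L) return(character(0))
  X <- feature_matrix(newdata)
  switch(object$family,
         knn = {
           Z <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
           knn_predict(object$fit, Z)
         },
         rf = as.character(predict(object$fit, X)),
         svm = {
           Z <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
           as.character(predict(object$fit, Z))
         })
}

#' @export
print.dhm_model <- function(x, ...) {
  cat("<dhm_model> family:", x$family, "\n",
      "classes:", paste(x$classes, collapse = ", "), "\n",
      "hyperparameters:",
      paste(names(x$hyper), unlist(x$hyper), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
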