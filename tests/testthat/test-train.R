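test_that("SMOTE balances counts and preserves originals verbatim", {
  tbl <- gaussian_feature_table(n_per_class = c(100L), seed = 1)
  # make counts {A:100, B:40, C:70}
  tbl <- dplyr::bind_rows(
    tbl[tbl$class == "A", ],
    head(tbl[tbl$class == "B", ], 40),
    head(tbl[tbl$class == "C", ], 70))
  bal <- smote_balance(tbl, seed = 2)
  counts <- table(bal$class)
  expect_true(all(counts == 100L))
  expect_identical(sum(bal$.synthetic & bal$class == "B"), 60L)
  expect_identical(sum(bal$.synthetic & bal$class == "A"), 0L)
  # originals appear unmodified, in order, at the head of the table
  orig <- bal[!bal$.synthetic, ]
  expect_equal(as.data.frame(orig[names(tbl)]), as.data.frame(tbl),
               tolerance = 0, ignore_attr = TRUE)
})

test_that("lambda = 0 reproduces base rows; synthetic rows stay in the parent box", {
  tbl <- gaussian_feature_table(n_per_class = 60L, seed = 3)
  tbl <- dplyr::bind_rows(tbl[tbl$class == "A", ],
                          head(tbl[tbl$class == "B", ], 25))
  bal0 <- smote_balance(tbl, lambda = 0, seed = 4)
  parents <- attr(bal0, "smote_parents")
  syn <- bal0[bal0$.synthetic, ]
  nms <- feature_columns(tbl)
  expect_equal(as.matrix(syn[nms]),
               as.matrix(tbl[parents$base_row, nms]), ignore_attr = TRUE)
  # random lambda: componentwise between the two parents
  bal <- smote_balance(tbl, seed = 5)
  parents <- attr(bal, "smote_parents")
  syn <- as.matrix(bal[bal$.synthetic, nms])
  lo <- pmin(as.matrix(tbl[parents$base_row, nms]),
             as.matrix(tbl[parents$neighbor_row, nms]))
  hi <- pmax(as.matrix(tbl[parents$base_row, nms]),
             as.matrix(tbl[parents$neighbor_row, nms]))
  expect_true(all(syn >= lo - 1e-12 & syn <= hi + 1e-12))
  # neighbors are same-class
  expect_true(all(tbl$class[parents$base_row] ==
                    tbl$class[parents$neighbor_row]))
})

test_that("SMOTE refuses classes with too few rows, naming them", {
  tbl <- gaussian_feature_table(n_per_class = 30L, seed = 6)
  tbl <- dplyr::bind_rows(tbl[tbl$class == "A", ],
                          head(tbl[tbl$class == "B", ], 4))
  expect_error(smote_balance(tbl, k_neighbors = 5), "'B'")
})

test_that("stratified split is an exact, seeded partition", {
  tbl <- gaussian_feature_table(n_per_class = 100L, seed = 7)
  sp <- stratified_split(tbl, test_fraction = 0.30, seed = 8)
  expect_identical(nrow(sp$test), 90L)
  expect_true(all(table(sp$test$class) == 30L))
  expect_identical(nrow(sp$train) + nrow(sp$test), nrow(tbl))
  key <- function(d) do.call(paste, d[feature_columns(d)])
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  expect_setequal(c(key(sp$train), key(sp$test)), key(tbl))
  sp2 <- stratified_split(tbl, test_fraction = 0.30, seed = 8)
  expect_identical(sp, sp2)
  # synthetic rows are refused under the default protocol
  bal <- smote_balance(dplyr::bind_rows(tbl[tbl$class == "A", ],
                                        head(tbl[tbl$class == "B", ], 50)),
                       seed = 1)
  expect_error(stratified_split(bal), "synthetic")
  expect_silent({sp3 <- stratified_split(bal, allow_synthetic = TRUE)})
})

test_that("grid search evaluates a clean partition and returns the best point", {
  tbl <- gaussian_feature_table(n_per_class = 60L, seed = 9)
  # degenerate single-point grid: that point comes back
  gs <- grid_search_cv(tbl, "knn", grid = list(k = 5L), folds = 3L,
                       balance = FALSE, seed = 10)
  expect_identical(gs$best$k, 5L)
  expect_identical(nrow(gs$report), 3L)
  # every row lands in exactly one validation fold per grid point
  fold_id <- holodcc:::make_folds(tbl$class, 5L, 1L)
  expect_identical(length(fold_id), nrow(tbl))
  expect_true(all(fold_id %in% 1:5))
  expect_true(all(table(tbl$class, fold_id) >= floor(60 / 5)))
  # separable data: RF CV accuracy >= 0.95
  gs_rf <- grid_search_cv(tbl, "rf", grid = list(ntree = 100L, mtry = 4L),
                          folds = 3L, balance = FALSE, seed = 11)
  expect_gte(gs_rf$summary$accuracy, 0.95)
  expect_error(grid_search_cv(tbl, "rf", grid = list(bogus = 1)), "invalid")
})

test_that("refit on the full table is at least nearly as good as CV", {
  tbl <- gaussian_feature_table(n_per_class = 60L, seed = 12)
  gs <- grid_search_cv(tbl, "rf", grid = list(ntree = 100L, mtry = 4L),
                       folds = 3L, balance = FALSE, seed = 13)
  m <- fit_classifier(tbl, "rf", gs$best, seed = 14)
  acc_train <- mean(predict(m, tbl) == tbl$class)
  expect_gte(acc_train, gs$summary$accuracy - 0.05)
})

test_that("1-NN memorizes distinct training rows; prediction is pointwise", {
  tbl <- gaussian_feature_table(n_per_class = 40L, seed = 15)
  m <- fit_classifier(tbl, "knn", list(k = 1L), seed = 16)
  expect_identical(predict(m, tbl), tbl$class)
  # duplicated rows get identical labels; empty table gives empty output
  dup <- dplyr::bind_rows(tbl[5, ], tbl[5, ])
  expect_identical(predict(m, dup)[1], predict(m, dup)[2])
  expect_identical(predict(m, tbl[0, ]), character(0))
})

test_that("tie-free kNN prediction agrees with class::knn", {
  tbl <- gaussian_feature_table(n_per_class = 50L, seed = 17)
  sp <- stratified_split(tbl, 0.3, seed = 18)
  m <- fit_classifier(sp$train, "knn", list(k = 3L), seed = 19)
  Xtr <- scale(as.matrix(sp$train[feature_columns(tbl)]))
  Xte <- scale(as.matrix(sp$test[feature_columns(tbl)]),
               attr(Xtr, "scaled:center"), attr(Xtr, "scaled:scale"))
  ref <- as.character(class::knn(Xtr, Xte, factor(sp$train$class), k = 3))
  got <- predict(m, sp$test)
  # class::knn breaks vote ties at random; compare only tie-free rows
  ties <- vapply(seq_len(nrow(Xte)), function(i) {
    d <- colSums((t(Xtr) - Xte[i, ])^2)
    nb <- order(d)[1:3]
    max(table(sp$train$class[nb])) == 1
  }, logical(1))
  expect_identical(got[!ties], ref[!ties])
  expect_gte(sum(!ties), 20L)
})

test_that("all three families are deterministic and schema-guarded", {
  tbl <- gaussian_feature_table(n_per_class = 40L, seed = 20)
  probe <- gaussian_feature_table(n_per_class = 10L, seed = 21)
  for (fam in c("knn", "rf", "svm")) {
    m1 <- fit_classifier(tbl, fam, seed = 22)
    m2 <- fit_classifier(tbl, fam, seed = 22)
    expect_identical(predict(m1, probe), predict(m2, probe))
    expect_true(all(predict(m1, probe) %in% m1$classes))
  }
  m <- fit_classifier(tbl, "rf", seed = 23)
  bad <- probe
  attr(bad, "dhm_schema") <- list(features = "x", fingerprint = "nope")
  expect_error(predict(m, bad), "fingerprint")
})

test_that("held-out accuracy is high on separated classes, chance after permutation", {
  tbl <- gaussian_feature_table(n_per_class = 200L, sep = 3, seed = 24)
  sp <- stratified_split(tbl, 0.3, seed = 25)
  m <- fit_classifier(sp$train, "rf", list(ntree = 300L), seed = 26)
  expect_gte(mean(predict(m, sp$test) == sp$test$class), 0.95)
  perm <- tbl
  perm$class <- withr::with_seed(27, sample(perm$class))
  gs <- grid_search_cv(perm, "rf", grid = list(ntree = 100L, mtry = 4L),
                       folds = 5L, balance = FALSE, seed = 28)
  expect_lt(abs(gs$summary$accuracy - 1 / 3), 0.05)
})

test_that("no synthetic row ever enters a validation fold", {
  tbl <- gaussian_feature_table(n_per_class = 50L, seed = 29)
  tbl <- dplyr::bind_rows(tbl[tbl$class != "C", ],
                          head(tbl[tbl$class == "C", ], 20))
  # balancing happens inside grid_search_cv on training folds only; the
  # validation metrics are computed on rows of the input table, which by
  # construction contains no synthetic rows
  gs <- grid_search_cv(tbl, "knn", grid = list(k = 3L), folds = 3L,
                       balance = TRUE, seed = 30)
  expect_identical(sum(gs$report$fold != 0), 3L)
  total_val <- sum(vapply(1:3, function(f)
    sum(holodcc:::make_folds(tbl$class, 3L,
                             derive_seed(30, "folds")) == f), 1L))
  expect_identical(total_val, nrow(tbl))
})
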