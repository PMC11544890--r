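test_that("confusion matrix counts match enumeration", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_identical(unclass(cm)[, ],
                   matrix(c(1L, 0L, 1L, 1L), 2, 2,
                          dimnames = list(truth = c("A", "B"),
                                          predicted = c("A", "B"))))
  perfect <- confusion_matrix(rep(c("A", "B", "C"), c(5, 3, 2)),
                              rep(c("A", "B", "C"), c(5, 3, 2)))
  expect_identical(diag(perfect), c(A = 5L, B = 3L, C = 2L))
  expect_identical(sum(perfect) - sum(diag(perfect)), 0L)
  empty <- confusion_matrix(character(0), character(0), c("A", "B"))
  expect_true(all(empty == 0L))
  expect_error(confusion_matrix("A", c("A", "B")), "equal length")
  expect_error(confusion_matrix("A", "Z", classes = c("A", "B")), "unknown")
})

test_that("metrics match hand arithmetic on the binary example", {
  cm <- confusion_matrix(rep(c("pos", "neg"), c(60, 40)),
                         c(rep("pos", 50), rep("neg", 10),
                           rep("pos", 5), rep("neg", 35)),
                         classes = c("pos", "neg"))
  m <- classification_metrics(cm)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$per_class$sensitivity[m$per_class$class == "pos"], 50 / 60)
  expect_equal(m$per_class$specificity[m$per_class$class == "pos"], 35 / 40)
  # all-wrong binary: sensitivity and specificity both zero
  worst <- classification_metrics(
    confusion_matrix(c("a", "b"), c("b", "a"), c("a", "b")))
  expect_equal(worst$per_class$sensitivity, c(0, 0))
  expect_equal(worst$per_class$specificity, c(0, 0))
  # perfect 3-class: all ones
  p <- classification_metrics(
    confusion_matrix(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(p$accuracy, 1)
  expect_equal(p$macro_sensitivity, 1)
  expect_equal(p$macro_specificity, 1)
})

test_that("metrics equal brute-force recomputation on random confusion matrices", {
  withr::with_seed(41, {
    for (i in 1:1000) {
      C <- sample(2:5, 1)
      counts <- matrix(rpois(C * C, 4), C, C)
      if (sum(counts) == 0) counts[1, 1] <- 1L
      classes <- LETTERS[seq_len(C)]
      dimnames(counts) <- list(truth = classes, predicted = classes)
      cm <- structure(counts, class = c("dhm_confusion", "matrix", "array"))
      m <- suppressWarnings(classification_metrics(cm))
      total <- sum(counts)
      expect_identical(m$accuracy, sum(diag(counts)) / total)
      for (ci in seq_len(C)) {
        tp <- counts[ci, ci]
        fn <- sum(counts[ci, ]) - tp
        fp <- sum(counts[, ci]) - tp
        tn <- total - tp - fn - fp
        want_sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
        expect_identical(m$per_class$sensitivity[ci], want_sens)
        expect_identical(m$per_class$specificity[ci], tn / (tn + fp))
      }
    }
  })
})

test_that("zero-support classes are excluded from macro averages with a warning", {
  cm <- confusion_matrix(c("a", "a"), c("a", "b"), classes = c("a", "b"))
  expect_warning(m <- classification_metrics(cm), "zero support")
  expect_identical(m$macro_sensitivity, 0.5)  # only class a contributes
})

test_that("sample compositions count labels and sum to one", {
  comp <- sample_composition(c("G", "G", "L", "M"), c("G", "L", "M"))
  expect_equal(comp$proportion, c(0.5, 0.25, 0.25))
  expect_equal(sample_composition(rep("G", 7), c("G", "L"))$proportion,
               c(1, 0))
  expect_error(sample_composition(character(0)), "empty")
  withr::with_seed(42, {
    labels <- sample(c("g", "l", "m"), 50000, replace = TRUE,
                     prob = c(0.6, 0.3, 0.1))
  })
  comp <- sample_composition(labels, c("g", "l", "m"))
  expect_true(all(abs(comp$proportion - c(0.6, 0.3, 0.1)) <= 0.01))
  expect_equal(sum(comp$proportion), 1, tolerance = 1e-12)
})

test_that("series comparison reproduces the worked example", {
  mk <- function(p, src) tibble::tibble(
    subject_id = "S1", matrix = "blood", day = 1,
    class = c("g", "l", "m"), proportion = p, source = src)
  cmp <- compare_series(mk(c(0.5, 0.3, 0.2), "t"),
                        mk(c(0.6, 0.2, 0.2), "r"))
  expect_equal(cmp$overall$mae, 0.2 / 3, tolerance = 1e-9)
  expect_equal(cmp$overall$rmse, sqrt(0.02 / 3), tolerance = 1e-9)
  expect_equal(cmp$overall$mre, (0.1 / 0.6 + 0.1 / 0.2 + 0) / 3,
               tolerance = 1e-9)
  ident <- compare_series(mk(c(0.5, 0.3, 0.2), "t"),
                          mk(c(0.5, 0.3, 0.2), "r"))
  expect_equal(unlist(ident$overall[c("mae", "rmse", "mre")]),
               c(mae = 0, rmse = 0, mre = 0))
  # misaligned days error
  bad <- mk(c(0.6, 0.2, 0.2), "r"); bad$day <- 2
  expect_error(compare_series(mk(c(0.5, 0.3, 0.2), "t"), bad), "misaligned")
  # reference zeros are skipped and counted
  z <- compare_series(mk(c(0.5, 0.5, 0.0), "t"), mk(c(0.6, 0.4, 0.0), "r"))
  expect_identical(z$mre_skipped, 1L)
})

test_that("MAE never exceeds RMSE on random series pairs", {
  withr::with_seed(43, {
    for (i in 1:1000) {
      n <- sample(3:12, 1)
      t_ <- runif(n); r_ <- runif(n)
      e <- t_ - r_
      expect_lte(mean(abs(e)), sqrt(mean(e^2)) + 1e-15)
    }
    # and through the public interface on a handful of random series
    for (i in 1:20) {
      days <- 1:4
      mk <- function(src) tidyr::expand_grid(
        subject_id = c("S1", "S2"), matrix = "blood", day = days,
        class = c("g", "l", "m")) |>
        dplyr::group_by(subject_id, day) |>
        dplyr::mutate(proportion = {x <- runif(3); x / sum(x)},
                      source = src) |>
        dplyr::ungroup()
      cmp <- compare_series(mk("t"), mk("r"))
      expect_lte(cmp$overall$mae, cmp$overall$rmse + 1e-15)
      expect_true(all(cmp$per_subject$mae <= cmp$per_subject$rmse + 1e-15))
    }
  })
})

test_that("LOSO folds never share subjects and report mean (SD) pairs", {
  tbl <- gaussian_feature_table(n_per_class = 60L, sep = 3,
                                subjects = c("c1", "c2", "c3"), seed = 44)
  loso <- leave_one_subject_out(tbl, "rf", list(ntree = 100L),
                                balance = FALSE, seed = 45)
  expect_identical(nrow(loso$per_subject), 3L)
  expect_setequal(loso$per_subject$subject_id, c("c1", "c2", "c3"))
  expect_identical(sum(loso$per_subject$n_test), nrow(tbl))
  expect_setequal(loso$summary$metric,
                  c("accuracy", "macro_sensitivity", "macro_specificity"))
  expect_true(all(c("mean", "sd") %in% names(loso$summary)))
  expect_error(leave_one_subject_out(dplyr::mutate(tbl, subject_id = "one")),
               ">= 2")
})

test_that("LOSO generalizes worse than same-subject holdout under subject jitter", {
  # subjects differ systematically (strong phenotype jitter); training on
  # two subjects and testing on the third must be harder than a pooled
  # random split
  sc <- scene_config(frame_shape = c(128L, 192L), cells_per_frame_mean = 8)
  iso <- synthesize_isolation_dataset(
    blood_phenotypes(), subjects = c("C1", "C2", "C3"),
    frames_per_class = 12L, imbalance = c(1, 1, 1), scene = sc,
    subject_jitter_sd = 0.15, seed = 46)
  feats <- purrr::map_dfr(iso$recordings, function(rec) {
    patches <- preprocess_recording(rec, tiny_params())
    cls <- sub("^.*_", "", rec$sample_id)
    build_feature_table(patches, metadata = list(subject_id = rec$subject_id),
                        labels = rep(cls, length(patches)),
                        params = tiny_params())
  })
  sp <- stratified_split(feats, 0.3, seed = 47)
  m <- fit_classifier(sp$train, "rf", list(ntree = 100L), seed = 48)
  holdout_acc <- mean(predict(m, sp$test) == sp$test$class)
  loso <- leave_one_subject_out(feats, "rf", list(ntree = 100L),
                                balance = FALSE, seed = 49)
  expect_lt(mean(loso$per_subject$accuracy), holdout_acc)
})

test_that("feature shift report computes standardized differences", {
  tbl <- gaussian_feature_table(n_per_class = 50L, seed = 50)
  tbl$day <- rep(c(2, 10), length.out = nrow(tbl))
  rep_ <- feature_shift_report(tbl, split_day = 8)
  expect_identical(nrow(rep_), 24L)
  expect_true(all(is.finite(rep_$cohens_d)))
  # shifting one feature after the split moves its effect size
  tbl2 <- tbl
  tbl2$area_um2[tbl2$day > 8] <- tbl2$area_um2[tbl2$day > 8] + 5
  rep2 <- feature_shift_report(tbl2, split_day = 8)
  expect_gt(rep2$cohens_d[rep2$feature == "area_um2"], 3)
})
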