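params_def <- segmentation_params()

# the ten constructed oracle patches: uniform and graded discs, two-level
# discs, bars and blocks on 9x9 / 11x11 grids
oracle_patches <- function() {
  two_level <- make_disc_patch(11, 4, fill = function(dr, dc)
    ifelse(dr^2 + dc^2 <= 4, 2.5, 1.0))
  ramp <- make_disc_patch(11, 4, fill = function(dr, dc) 1.5 + 0.1 * dc)
  dome <- make_disc_patch(11, 4.5, fill = function(dr, dc)
    2 * cos(pi * sqrt(dr^2 + dc^2) / 11))
  twin <- make_disc_patch(11, 4, fill = function(dr, dc)
    1 + exp(-((dr - 2)^2 + dc^2) / 2) + exp(-((dr + 2)^2 + dc^2) / 2))
  skewed <- make_disc_patch(11, 4, fill = function(dr, dc)
    1 + 0.5 * (dr^2 + dc^2 <= 1))
  list(
    disc_uniform = make_disc_patch(9, 3, value = 2),
    disc_big = make_disc_patch(11, 5, value = 1.2),
    disc_two_level = two_level,
    disc_ramp = ramp,
    disc_dome = dome,
    disc_twin_peaks = twin,
    disc_skewed = skewed,
    bar_horizontal = make_rect_patch(9, 2, 7, value = 1.4),
    bar_vertical = {
      p <- make_rect_patch(9, 7, 2, value = 0.9); p
    },
    block_square = make_rect_patch(11, 5, 5, value = 1.1))
}

test_that("all 24 features match the per-definition oracle on constructed patches", {
  for (nm in names(oracle_patches())) {
    p <- oracle_patches()[[nm]]
    got <- compute_features(p, params_def)
    want <- oracle_features(p$values, p$mask, params_def$pixel_area_um2)
    expect_equal(got[names(want)], want, tolerance = 1e-9, label = nm)
  }
})

test_that("hand-frozen values for the uniform disc are exact", {
  # digital disc r=3 on 9x9 has 29 lattice points; phase 2.0 everywhere
  p <- make_disc_patch(9, 3, value = 2)
  f <- compute_features(p, params_def)
  expect_equal(unname(f["area_um2"]), 29 * 11.9)
  expect_equal(unname(f["mean_phase"]), 2.0)
  expect_equal(unname(f["median_phase"]), 2.0)
  expect_equal(unname(f["std_phase"]), 0.0)
  expect_equal(unname(f["phase_range"]), 0.0)
  expect_equal(unname(f["phase_skewness"]), 0.0)
  expect_equal(unname(f["phase_kurtosis"]), 0.0)
  expect_equal(unname(f["phase_entropy"]), 0.0)
  expect_equal(unname(f["optical_volume"]), 29 * 2.0 * 11.9)
  expect_equal(unname(f["mass_displacement_um"]), 0.0)
  expect_equal(unname(f["eccentricity"]), 0.0)
  expect_equal(unname(f["solidity"]), 1.0)
  expect_equal(unname(f["extent"]), 29 / 49)
  # 5x5 square block: digitization-exact shape values
  sq <- make_rect_patch(11, 5, 5, value = 1.1)
  fs <- compute_features(sq, params_def)
  pitch <- sqrt(11.9)
  expect_equal(unname(fs["perimeter_um"]), 20 * pitch)
  expect_equal(unname(fs["circularity"]), 4 * pi * 25 / 400)
  expect_equal(unname(fs["extent"]), 1.0)
  expect_equal(unname(fs["aspect_ratio"]), 1.0)
})

test_that("features are invariant to translating the patch content", {
  p <- oracle_patches()$disc_two_level
  shifted <- p
  shifted$values <- matrix(0, 15, 15)
  shifted$mask <- matrix(FALSE, 15, 15)
  shifted$values[4 + seq_len(11) - 1, 2 + seq_len(11) - 1] <- p$values
  shifted$mask[4 + seq_len(11) - 1, 2 + seq_len(11) - 1] <- p$mask
  expect_equal(compute_features(shifted, params_def),
               compute_features(p, params_def), tolerance = 1e-12)
})

test_that("intensity features scale linearly with phase; shape features do not", {
  p <- oracle_patches()$disc_dome
  f1 <- compute_features(p, params_def)
  p2 <- p; p2$values <- p$values * 2
  f2 <- compute_features(p2, params_def)
  lin <- c("mean_phase", "median_phase", "max_phase", "min_phase",
           "phase_range", "std_phase", "optical_volume")
  expect_equal(unname(f2[lin]), unname(2 * f1[lin]), tolerance = 1e-12)
  inv <- c("area_um2", "eccentricity", "solidity", "extent", "circularity",
           "perimeter_um", "phase_skewness", "phase_kurtosis")
  expect_equal(unname(f2[inv]), unname(f1[inv]), tolerance = 1e-12)
})

test_that("90-degree rotation leaves the catalog unchanged", {
  for (nm in c("disc_two_level", "disc_twin_peaks", "bar_horizontal")) {
    p <- oracle_patches()[[nm]]
    rot <- p
    rot$values <- t(p$values[nrow(p$values):1, ])
    rot$mask <- t(p$mask[nrow(p$mask):1, ])
    f1 <- compute_features(p, params_def)
    f2 <- compute_features(rot, params_def)
    expect_equal(f2, f1, tolerance = 1e-9, label = nm)
  }
})

test_that("local maxima count separates single- from twin-peak phantoms", {
  f1 <- compute_features(oracle_patches()$disc_dome, params_def)
  f2 <- compute_features(oracle_patches()$disc_twin_peaks, params_def)
  expect_identical(unname(f1["n_local_maxima"]), 1)
  expect_identical(unname(f2["n_local_maxima"]), 2)
})

test_that("degenerate masks are rejected", {
  p <- make_disc_patch(9, 3, value = 1)
  p$mask[] <- FALSE
  expect_error(compute_features(p, params_def), "empty mask")
  p$mask[1, 1:3] <- TRUE
  expect_error(compute_features(p, params_def), "fewer than 4")
})

test_that("class-conditional means of key features separate by >= 1 pooled SD", {
  ph <- blood_phenotypes()
  withr::with_seed(17, {
    tbl <- purrr::map_dfr(names(ph), function(cl) {
      patches <- lapply(1:60, function(i) {
        cell <- render_cell(ph[[cl]])
        structure(list(values = cell$values, mask = cell$mask,
                       provenance = list(sample_id = cl, frame_index = i,
                                         component_index = 1L,
                                         centroid_row = 0, centroid_col = 0,
                                         area_px = cell$truth$area_px)),
                  class = "dhm_patch")
      })
      build_feature_table(patches, labels = rep(cl, 60))
    })
  })
  for (feat in c("area_um2", "optical_volume", "std_phase")) {
    stats <- tbl |>
      dplyr::group_by(class) |>
      dplyr::summarise(m = mean(.data[[feat]]), s = sd(.data[[feat]]))
    pooled <- sqrt(mean(stats$s^2))
    gaps <- abs(outer(stats$m, stats$m, "-")) / pooled
    # at least one other class >= 1 pooled SD away from each class
    expect_true(all(apply(gaps + diag(Inf, 3), 1, max) >= 1),
                label = feat)
  }
})

test_that("feature tables carry schema, labels and deterministic order", {
  sc <- tiny_scene()
  rec <- synthesize_recording(10, blood_phenotypes(), c(.4, .4, .2), sc,
                              sample_id = "ft", seed = 19)
  patches <- preprocess_recording(rec, tiny_params())
  expect_error(build_feature_table(patches, labels = "just-one"), "align")
  tbl <- build_feature_table(patches, metadata = list(subject_id = "S1"),
                             labels = rep("granulocyte", length(patches)),
                             params = tiny_params())
  expect_identical(nrow(tbl), length(patches))
  expect_true(all(feature_catalog()$name %in% names(tbl)))
  expect_identical(attr(tbl, "dhm_schema")$fingerprint,
                   attr(build_feature_table(list()), "dhm_schema")$fingerprint)
  # empty input keeps the full schema
  empty <- build_feature_table(list(), labels = character(0))
  expect_identical(nrow(empty), 0L)
  expect_true(all(feature_catalog()$name %in% names(empty)))
  # byte-identical CSV across runs
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  readr::write_csv(tbl, f1)
  readr::write_csv(build_feature_table(
    patches, metadata = list(subject_id = "S1"),
    labels = rep("granulocyte", length(patches)), params = tiny_params()), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
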