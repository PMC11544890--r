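#' Render a single cell phantom
#'
#' Draws radius and peak phase from the phenotype's (truncated) normal
#' distributions and renders a raised-cosine phase bump on a small patch:
#' `phi(rho) = peak * cos(pi * rho / 2)` with `rho` the elliptical radial
#' coordinate (1 at the mask boundary). Optional angular lobes depress the
#' profile between `lobe_count` ridges, and multiplicative speckle adds
#' intra-cell texture. The mask is the digital ellipse `rho <= 1`; values
#' are exactly zero outside it.
#'
#' @param phenotype A [class_phenotype()].
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A list with `values` (phase patch, radians), `mask` (logical
#'   matrix) and `truth` (class, sampled radius/peak, area_px, centroid
#'   offset relative to the patch center).
#' @export
render_cell <- function(phenotype, seed = NULL) {
  stopifnot(inherits(phenotype, "dhm_phenotype"))
  with_seed_if(seed, {
    radius <- NA_real_
    for (try in 1:10) {
      r <- rnorm_trunc(1, phenotype$radius_mean, phenotype$radius_sd)
      if (r > 0.5) { radius <- r; break }
    }
    if (is.na(radius)) stop("non-positive sampled radius after 10 retries")
    peak <- NA_real_
    for (try in 1:10) {
      p <- rnorm_trunc(1, phenotype$peak_phase_mean, phenotype$peak_phase_sd)
      if (p > 0) { peak <- p; break }
    }
    if (is.na(peak)) stop("non-positive sampled peak phase after 10 retries")

    ecc <- phenotype$eccentricity_mean
    a <- radius / (1 - ecc^2)^0.25   # semi-major, area-preserving stretch
    b <- radius * (1 - ecc^2)^0.25   # semi-minor
    ang <- runif(1, 0, pi)
    lobe_phase <- runif(1, 0, 2 * pi)

    half <- ceiling(a) + 1L
    side <- 2L * half + 1L
    dr <- matrix(rep(-half:half, side), side, side)
    dc <- t(dr)
    u <- cos(ang) * dc + sin(ang) * dr
    v <- -sin(ang) * dc + cos(ang) * dr
    rho <- sqrt((u / a)^2 + (v / b)^2)
    mask <- rho <= 1
    values <- matrix(0, side, side)
    values[mask] <- peak * cos(pi * rho[mask] / 2)
    if (phenotype$lobe_count > 0L) {
      theta <- atan2(v, u)
      depress <- 0.25 * (1 - cos(phenotype$lobe_count * theta + lobe_phase)) /
        2 * sin(pi * pmin(rho, 1))
      values[mask] <- values[mask] * (1 - depress[mask])
    }
    if (phenotype$granularity_sd > 0) {
      n <- sum(mask)
      values[mask] <- values[mask] *
        (1 + rnorm_trunc(n, 0, phenotype$granularity_sd, trunc = 2))
    }
    n <- sum(mask)
    list(values = values, mask = mask,
         truth = list(class = phenotype$class_name,
                      radius = radius, peak = peak, area_px = n,
                      offset_row = sum(dr[mask]) / n,
                      offset_col = sum(dc[mask]) / n))
  })
}

#' Static channel artifact pattern
#'
#' The deterministic phase pattern contributed by the microfluidic channel,
#' identical across all frames of a recording. A smooth superposition of
#' incommensurate sinusoids scaled by the scene's artifact amplitude.
#'
#' @param frame_shape Integer `(rows, cols)`.
#' @param amplitude Pattern amplitude in radians.
#' @return A numeric matrix.
#' @export
artifact_pattern <- function(frame_shape, amplitude) {
  r <- matrix(rep(seq_len(frame_shape[1]), frame_shape[2]),
              frame_shape[1], frame_shape[2])
  c_ <- matrix(rep(seq_len(frame_shape[2]), each = frame_shape[1]),
               frame_shape[1], frame_shape[2])
  amplitude * (0.5 * sin(2 * pi * c_ / 173) + 0.3 * cos(2 * pi * r / 131) +
                 0.2 * sin(2 * pi * (r + c_) / 97))
}

# Place one rendered phantom into frame/occupancy; returns updated state or
# NULL when no non-overlapping position was found within `tries` attempts.
place_phantom <- function(frame, occ, cell, forbid, tries = 500L) {
  side <- nrow(cell$values)
  half <- (side - 1L) %/% 2L
  nr <- nrow(frame); nc <- ncol(frame)
  if (nr < side || nc < side) {
    stop("frame too small to place a phantom of side ", side)
  }
  mask_idx_local <- which(cell$mask)
  lr <- (mask_idx_local - 1L) %% side           # 0-based local row
  lc <- (mask_idx_local - 1L) %/% side          # 0-based local col
  for (t in seq_len(tries)) {
    cr <- sample.int(nr - side + 1L, 1L) + half  # center row
    cc <- sample.int(nc - side + 1L, 1L) + half
    idx <- (cc - half - 1L + lc) * nr + (cr - half + lr)
    if (forbid && any(occ[idx])) next
    rows <- (cr - half):(cr + half)
    cols <- (cc - half):(cc + half)
    frame[rows, cols] <- frame[rows, cols] + cell$values
    occ[idx] <- TRUE
    return(list(frame = frame, occ = occ, center = c(cr, cc)))
  }
  NULL
}

#' Synthesize one annotated phase frame
#'
#' Draws a Poisson number of cells, assigns classes from the mixture,
#' renders and places non-overlapping phantoms onto the static channel
#' artifact plus i.i.d. Gaussian phase noise, and returns the frame together
#' with exact truth records. Debris phantoms (if the scene defines them) are
#' added the same way and flagged with `role = "debris"`.
#'
#' @param phenotypes Non-empty named list of [class_phenotype()].
#' @param mixture Class proportions (same length as `phenotypes`, sums to 1).
#' @param scene A [scene_config()].
#' @param seed Optional integer seed.
#' @param artifact Optional precomputed [artifact_pattern()] for the scene
#'   (recomputed when `NULL`); recordings pass it once for speed.
#' @return A list with `values` (frame matrix, radians) and `truth`
#'   (tibble: class, role, centroid_row/col (1-based), area_px, radius, peak).
#' @export
synthesize_frame <- function(phenotypes, mixture, scene = scene_config(),
                             seed = NULL, artifact = NULL) {
  if (length(phenotypes) == 0L) stop("phenotypes must be non-empty")
  if (length(mixture) != length(phenotypes))
    stop("mixture length must match phenotypes")
  if (abs(sum(mixture) - 1) > 1e-9 || any(mixture < 0))
    stop("mixture must be non-negative and sum to 1")
  with_seed_if(seed, {
    shp <- scene$frame_shape
    frame <- artifact %||% artifact_pattern(shp, scene$artifact_amplitude)
    if (scene$noise_sd > 0)
      frame <- frame + rnorm(prod(shp), 0, scene$noise_sd)
    occ <- matrix(FALSE, shp[1], shp[2])
    forbid <- scene$overlap_policy == "forbid"

    n_cells <- rpois(1, scene$cells_per_frame_mean)
    cls_idx <- if (n_cells > 0)
      sample.int(length(phenotypes), n_cells, replace = TRUE, prob = mixture)
    else integer(0)
    n_debris <- if (!is.null(scene$debris) && scene$debris_per_frame_mean > 0)
      rpois(1, scene$debris_per_frame_mean) else 0L

    specs <- c(lapply(cls_idx, function(i) phenotypes[[i]]),
               rep(list(scene$debris), n_debris))
    np <- length(specs)
    t_class <- character(np); t_role <- character(np)
    t_crow <- double(np); t_ccol <- double(np)
    t_area <- integer(np); t_radius <- double(np); t_peak <- double(np)
    for (i in seq_along(specs)) {
      cell <- render_cell(specs[[i]])
      placed <- place_phantom(frame, occ, cell, forbid)
      if (is.null(placed))
        stop("could not place phantom without overlap after bounded retries")
      frame <- placed$frame; occ <- placed$occ
      tr <- cell$truth
      t_class[i] <- tr$class; t_role[i] <- specs[[i]]$role
      t_crow[i] <- placed$center[1] + tr$offset_row
      t_ccol[i] <- placed$center[2] + tr$offset_col
      t_area[i] <- tr$area_px; t_radius[i] <- tr$radius; t_peak[i] <- tr$peak
    }
    truth <- new_tbl(class = t_class, role = t_role,
                     centroid_row = t_crow, centroid_col = t_ccol,
                     area_px = t_area, radius = t_radius, peak = t_peak)
    list(values = frame, truth = truth)
  })
}

#' Synthesize a multi-frame recording
#'
#' @param n_frames Number of frames.
#' @param phenotypes,mixture,scene As in [synthesize_frame()].
#' @param sample_id,subject_id,matrix,day Provenance metadata.
#' @param seed Integer seed (each frame draws from one seeded stream).
#' @return A `dhm_recording`: list of `frames` (matrices), a `truth` tibble
#'   with `frame_index`, and provenance fields.
#' @export
synthesize_recording <- function(n_frames, phenotypes, mixture,
                                 scene = scene_config(),
                                 sample_id = "sample", subject_id = NA_character_,
                                 matrix = NA_character_, day = NA_real_,
                                 seed = NULL) {
  stopifnot(n_frames >= 1)
  with_seed_if(seed, {
    frames <- vector("list", n_frames)
    truths <- vector("list", n_frames)
    art <- artifact_pattern(scene$frame_shape, scene$artifact_amplitude)
    for (f in seq_len(n_frames)) {
      fr <- synthesize_frame(phenotypes, mixture, scene, artifact = art)
      frames[[f]] <- fr$values
      if (nrow(fr$truth))
        truths[[f]] <- dplyr::mutate(fr$truth, frame_index = f, .before = 1)
    }
    truth <- dplyr::bind_rows(truths)
    structure(list(frames = frames, truth = truth, sample_id = sample_id,
                   subject_id = subject_id, matrix = matrix, day = day,
                   scene = scene),
              class = "dhm_recording")
  })
}

# Apply a deterministic per-subject jitter to phenotype size/height so
# subjects differ systematically (what leave-one-subject-out probes).
jitter_phenotypes <- function(phenotypes, subject_id, sd, seed) {
  if (sd == 0) return(phenotypes)
  with_seed_if(derive_seed(seed, "subject-jitter", subject_id), {
    lapply(phenotypes, function(ph) {
      ph$radius_mean <- ph$radius_mean * rnorm_trunc(1, 1, sd, 2)
      ph$peak_phase_mean <- ph$peak_phase_mean * rnorm_trunc(1, 1, sd, 2)
      ph
    })
  })
}

#' Synthesize a sorted-cell (isolation) dataset
#'
#' Emulates FACS-sorted single-class recordings: one recording per
#' (subject, class), each containing only that class, with a deterministic
#' per-subject jitter of phenotype size and optical height (so subjects
#' differ systematically) and deliberately imbalanced class frame counts
#' (default 5:3:1) mirroring the uneven abundance of leukocyte types.
#'
#' @param phenotypes Named list of cell phenotypes (one per class).
#' @param subjects Character subject IDs (>= 1).
#' @param frames_per_class Frames for the largest class (>= 1); other classes
#'   get `round(frames_per_class * w / max(w))` frames.
#' @param imbalance Positive weights, recycled to the number of classes;
#'   `c(1, 1, 1)` gives equal expected counts.
#' @param scene A [scene_config()].
#' @param subject_jitter_sd Relative SD of the per-subject phenotype jitter.
#' @param seed Integer seed.
#' @return A `dhm_isolation`: named list `recordings` plus metadata.
#' @export
synthesize_isolation_dataset <- function(phenotypes,
                                         subjects = c("C1", "C2", "C3"),
                                         frames_per_class = 40L,
                                         imbalance = c(5, 3, 1),
                                         scene = scene_config(),
                                         subject_jitter_sd = 0.04,
                                         seed = 1L) {
  stopifnot(length(subjects) >= 1L, frames_per_class >= 1L)
  classes <- names(phenotypes)
  if (is.null(classes)) stop("phenotypes must be a named list")
  w <- rep_len(imbalance, length(classes))
  if (any(w <= 0)) stop("imbalance weights must be positive")
  n_frames <- pmax(1L, as.integer(round(frames_per_class * w / max(w))))

  recordings <- list()
  for (s in subjects) {
    ph_s <- jitter_phenotypes(phenotypes, s, subject_jitter_sd, seed)
    for (j in seq_along(classes)) {
      mixture <- as.numeric(seq_along(classes) == j)
      id <- paste(s, classes[j], sep = "_")
      recordings[[id]] <- synthesize_recording(
        n_frames[j], ph_s, mixture, scene,
        sample_id = id, subject_id = s,
        seed = derive_seed(seed, "isolation", s, classes[j]))
    }
  }
  structure(list(recordings = recordings, subjects = subjects,
                 classes = classes, frames_per_class = n_frames,
                 imbalance = w, seed = seed),
            class = "dhm_isolation")
}

#' Synthesize a longitudinal study
#'
#' Realizes a [study_design()] for one matrix: every (subject, day) sample
#' is a recording whose cells are drawn multinomially from the design's
#' ground-truth composition; subjects carry the same deterministic phenotype
#' jitter as the isolation generator. The realized truth series (proportions
#' of actually placed cells) and a reference-method series (truth plus
#' truncated Gaussian noise, clamped at zero and renormalized) are returned
#' as tidy composition tables.
#'
#' Recordings are large; by default only truth/reference series and the
#' per-sample manifest are kept, and individual recordings are reproduced on
#' demand with [realize_sample()]. Set `keep_frames = TRUE` (small scenes
#' only) to embed them.
#'
#' @param design A [study_design()].
#' @param phenotypes Named list of cell phenotypes matching the design's
#'   classes for `matrix`.
#' @param scene A [scene_config()].
#' @param matrix Which matrix of the design to realize (default: its first).
#' @param frames_per_sample Frames per (subject, day) recording.
#' @param subject_jitter_sd Relative SD of the per-subject phenotype jitter.
#' @param keep_frames Embed the recordings in the returned object.
#' @param seed Integer seed.
#' @return A `dhm_study` with `samples` (manifest tibble), `truth` and
#'   `reference` composition tibbles, and optionally `recordings`.
#' @export
synthesize_longitudinal_study <- function(design, phenotypes,
                                          scene = scene_config(),
                                          matrix = NULL,
                                          frames_per_sample = 400L,
                                          subject_jitter_sd = 0.04,
                                          keep_frames = FALSE,
                                          seed = 1L) {
  stopifnot(inherits(design, "dhm_design"))
  matrix <- matrix %||% design$matrix[1]
  matrix <- match.arg(matrix, design$matrix)
  classes <- names(phenotypes)
  comp <- dplyr::filter(design$compositions, .data$matrix == !!matrix)
  if (!setequal(unique(comp$class), classes))
    stop("phenotype classes must match the design's classes for ", matrix)

  study <- structure(
    list(design = design, phenotypes = phenotypes, scene = scene,
         matrix = matrix, frames_per_sample = as.integer(frames_per_sample),
         subject_jitter_sd = subject_jitter_sd, seed = seed),
    class = "dhm_study")

  samples <- tidyr::expand_grid(subject_id = design$subjects,
                                day = design$days)
  truths <- vector("list", nrow(samples))
  recs <- if (keep_frames) vector("list", nrow(samples)) else NULL
  for (i in seq_len(nrow(samples))) {
    rec <- realize_sample(study, samples$subject_id[i], samples$day[i])
    cells <- dplyr::filter(rec$truth, .data$role == "cell")
    p <- table(factor(cells$class, levels = classes))
    truths[[i]] <- tibble::tibble(
      subject_id = samples$subject_id[i], matrix = matrix,
      day = samples$day[i], class = classes,
      proportion = as.numeric(p) / sum(p), n_cells = sum(p))
    if (keep_frames) recs[[i]] <- rec
  }
  truth <- dplyr::bind_rows(truths)
  truth$source <- "truth"

  ref <- with_seed_if(derive_seed(seed, "reference"), {
    truth |>
      dplyr::group_by(.data$subject_id, .data$day) |>
      dplyr::mutate(proportion = {
        p <- .data$proportion
        if (design$reference_noise_sd > 0) {
          p <- pmax(0, p + rnorm_trunc(length(p), 0,
                                       design$reference_noise_sd, 2))
          p / sum(p)
        } else p
      }) |>
      dplyr::ungroup()
  })
  ref$source <- "reference"
  ref$n_cells <- NULL

  study$samples <- samples
  study$truth <- truth
  study$reference <- ref
  if (keep_frames) {
    names(recs) <- paste(samples$subject_id, samples$day, sep = "_d")
    study$recordings <- recs
  }
  study
}

#' Reproduce one recording of a longitudinal study
#'
#' Deterministic given the study's seed: the same (subject, day) always
#' yields the identical recording, so large studies need not keep frames in
#' memory.
#'
#' @param study A `dhm_study`.
#' @param subject_id,day Sample coordinates present in the design.
#' @return A `dhm_recording`.
#' @export
realize_sample <- function(study, subject_id, day) {
  stopifnot(inherits(study, "dhm_study"))
  comp <- study$design$compositions
  comp <- comp[comp$subject_id == subject_id & comp$day == day &
                 comp$matrix == study$matrix, ]
  if (nrow(comp) == 0L) stop("no such (subject, day) in the design")
  mixture <- comp$proportion[match(names(study$phenotypes), comp$class)]
  ph_s <- jitter_phenotypes(study$phenotypes, subject_id,
                            study$subject_jitter_sd, study$seed)
  synthesize_recording(
    study$frames_per_sample, ph_s, mixture, study$scene,
    sample_id = paste(subject_id, day, sep = "_d"),
    subject_id = subject_id, matrix = study$matrix, day = day,
    seed = derive_seed(study$seed, "sample", subject_id, day))
}
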