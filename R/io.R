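#' Write a recording as multi-page TIFF plus JSON sidecar
#'
#' One TIFF page per frame, 32-bit samples. TIFF stores samples normalized
#' to `[0, 1]`, so phase values are mapped through the affine transform
#' `(phase - phase_offset) / phase_scale` (default offset -4, scale 16,
#' exact to ~4e-9 rad over the plausible phase range); the transform and
#' all provenance (scene parameters, truth records) go into `<path>.json`.
#'
#' @param recording A `dhm_recording`.
#' @param path Output path; `.tif` appended if missing.
#' @param phase_offset,phase_scale Affine storage transform.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, phase_offset = -4,
                            phase_scale = 16) {
  stopifnot(inherits(recording, "dhm_recording"))
  if (!grepl("\\.tiff?$", path)) path <- paste0(path, ".tif")
  pages <- lapply(recording$frames, function(f) {
    g <- (f - phase_offset) / phase_scale
    if (any(g < 0 | g > 1))
      stop("phase values exceed the storable range; widen phase_scale")
    g
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  scene <- recording$scene
  sidecar <- list(
    sample_id = recording$sample_id, subject_id = recording$subject_id,
    matrix = recording$matrix, day = recording$day,
    n_frames = length(recording$frames),
    phase_offset = phase_offset, phase_scale = phase_scale,
    scene = list(frame_shape = scene$frame_shape,
                 cells_per_frame_mean = scene$cells_per_frame_mean,
                 noise_sd = scene$noise_sd,
                 artifact_amplitude = scene$artifact_amplitude,
                 overlap_policy = scene$overlap_policy,
                 debris_per_frame_mean = scene$debris_per_frame_mean),
    truth = recording$truth)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path Path to the TIFF file.
#' @return A `dhm_recording` (scene restored without any debris phenotype).
#' @export
read_recording <- function(path) {
  if (!grepl("\\.tiff?$", path)) path <- paste0(path, ".tif")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(pages, function(g) g * meta$phase_scale + meta$phase_offset)
  truth <- tibble::as_tibble(meta$truth)
  scene <- scene_config(
    frame_shape = meta$scene$frame_shape,
    cells_per_frame_mean = meta$scene$cells_per_frame_mean,
    noise_sd = meta$scene$noise_sd,
    artifact_amplitude = meta$scene$artifact_amplitude,
    overlap_policy = meta$scene$overlap_policy)
  structure(list(frames = frames, truth = truth,
                 sample_id = meta$sample_id, subject_id = meta$subject_id,
                 matrix = meta$matrix,
                 day = if (is.null(meta$day)) NA_real_ else as.numeric(meta$day),
                 scene = scene),
            class = "dhm_recording")
}

#' Write / read a composition series CSV
#'
#' Plain CSV with columns subject_id, day, matrix, class, proportion,
#' source.
#'
#' @param series Composition tibble.
#' @param path File path.
#' @return `path` / the tibble.
#' @export
write_composition_csv <- function(series, path) {
  readr::write_csv(series[, intersect(
    c("subject_id", "day", "matrix", "class", "proportion", "source"),
    names(series))], path)
  invisible(path)
}

#' @rdname write_composition_csv
#' @export
read_composition_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
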