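#' Segmentation and patch-extraction parameters
#'
#' Defaults mirror the recording pipeline this package implements: threshold
#' segmentation at 0.8 rad on the background-subtracted phase image
#' (strictly greater), an area filter of 30 pixels (reported alongside as
#' `min_area_px * pixel_area_um2` in square micrometres; sub-filter objects
#' are typically isolation-process remnants), a per-pixel median background
#' over the first 1000 frames, 8-connectivity blob labeling, and 96 x 96
#' pixel patches centered on each detected cell.
#'
#' @param phase_threshold Foreground threshold in radians (> 0).
#' @param min_area_px Minimum component area in pixels (>= 1).
#' @param background_frames Number of leading frames used for the median
#'   background.
#' @param connectivity Pixel connectivity, 4 or 8.
#' @param patch_size Patch side length in pixels (even, >= 2).
#' @param pixel_area_um2 Area of one pixel in square micrometres (metadata
#'   for unit-bearing features; the pixel-count criterion is normative).
#' @param edge_policy `"discard"` drops cells whose patch window leaves the
#'   frame; `"zero_pad"` pads with zeros instead.
#' @return A `dhm_params` list; `min_area_um2` is derived.
#' @export
segmentation_params <- function(phase_threshold = 0.8,
                                min_area_px = 30L,
                                background_frames = 1000L,
                                connectivity = 8L,
                                patch_size = 96L,
                                pixel_area_um2 = 11.9,
                                edge_policy = c("discard", "zero_pad")) {
  edge_policy <- match.arg(edge_policy)
  if (phase_threshold <= 0) stop("phase_threshold must be > 0")
  if (min_area_px < 1) stop("min_area_px must be >= 1")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (patch_size < 2L || patch_size %% 2L != 0L)
    stop("patch_size must be even and >= 2")
  if (pixel_area_um2 <= 0) stop("pixel_area_um2 must be > 0")
  structure(
    list(phase_threshold = phase_threshold,
         min_area_px = as.integer(min_area_px),
         min_area_um2 = min_area_px * pixel_area_um2,
         background_frames = as.integer(background_frames),
         connectivity = as.integer(connectivity),
         patch_size = as.integer(patch_size),
         pixel_area_um2 = pixel_area_um2,
         edge_policy = edge_policy),
    class = "dhm_params")
}

#' Label connected foreground components
#'
#' Two-pass union-find labeling of a logical image under 4- or
#' 8-connectivity. Exposed because segmentation correctness hinges on it;
#' tested against an exhaustive flood-fill oracle.
#'
#' @param fg Logical matrix (TRUE = foreground).
#' @param connectivity 4 or 8.
#' @return Integer matrix of labels, 0 for background; component ids are
#'   1..k in first-touch raster order (columns within rows of the scan).
#' @export
label_components <- function(fg, connectivity = 8L) {
  stopifnot(is.matrix(fg))
  lab <- label_components_cpp(as.logical(fg), nrow(fg), ncol(fg),
                              as.integer(connectivity))
  matrix(lab, nrow(fg), ncol(fg))
}

as_frame_list <- function(frames) {
  if (inherits(frames, "dhm_recording")) frames$frames
  else if (is.matrix(frames)) list(frames)
  else frames
}

#' Estimate the static background of a recording
#'
#' Per-pixel median over the first `min(background_frames, n)` frames. The
#' channel environment is assumed static over a recording session, so the
#' median suppresses both noise and transient cells.
#'
#' @param frames A `dhm_recording`, a list of matrices, or one matrix.
#' @param params A [segmentation_params()].
#' @return A matrix of the same shape as the frames.
#' @export
estimate_background <- function(frames, params = segmentation_params()) {
  frames <- as_frame_list(frames)
  if (length(frames) == 0L) stop("need at least one frame")
  shp <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), shp), logical(1))))
    stop("all frames must share the same shape")
  use <- frames[seq_len(min(params$background_frames, length(frames)))]
  stack <- vapply(use, as.numeric, numeric(prod(shp)))
  if (is.null(dim(stack))) stack <- matrix(stack, nrow = 1L)
  matrix(matrixStats::rowMedians(stack), shp[1], shp[2])
}

#' Segment cells in one frame
#'
#' Thresholds the background-subtracted frame (strictly greater than
#' `phase_threshold`), labels connected components, and drops those smaller
#' than `min_area_px`. Components are returned in raster order of their
#' bounding boxes (min row, then min col), so downstream results are
#' reproducible.
#'
#' @param frame,background Numeric matrices of identical shape.
#' @param params A [segmentation_params()].
#' @return A tibble with one row per retained component: `component_index`,
#'   `area_px`, `centroid_row`, `centroid_col` (1-based), bbox columns
#'   (`bbox_rmin` .. inclusive), and a `pixels` list-column of linear pixel
#'   indices. Attribute `n_area_filtered` counts sub-filter components.
#' @export
segment_frame <- function(frame, background, params = segmentation_params()) {
  if (!identical(dim(frame), dim(background)))
    stop("frame and background must have identical shape")
  nr <- nrow(frame)
  fg <- (frame - background) > params$phase_threshold
  lab <- label_components_cpp(fg, nr, ncol(frame), params$connectivity)
  idx <- which(lab > 0L)
  empty_comp <- function(nf) {
    empty <- new_tbl(component_index = integer(), area_px = integer(),
                     centroid_row = double(), centroid_col = double(),
                     bbox_rmin = integer(), bbox_cmin = integer(),
                     bbox_rmax = integer(), bbox_cmax = integer(),
                     pixels = list())
    attr(empty, "n_area_filtered") <- nf
    empty
  }
  if (length(idx) == 0L) return(empty_comp(0L))
  l <- lab[idx]
  areas <- tabulate(l)
  keep <- which(areas >= params$min_area_px)
  n_filtered <- sum(areas > 0L) - length(keep)
  if (length(keep) == 0L) return(empty_comp(n_filtered))
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  # split by label: levels of a numeric factor sort numerically, so group
  # j corresponds to label j
  fl <- factor(l, levels = seq_along(areas))
  sp_idx <- split(idx, fl)[keep]
  sp_rows <- split(rows, fl)[keep]
  sp_cols <- split(cols, fl)[keep]
  rmin <- vapply(sp_rows, min, 1L)
  cmin <- vapply(sp_cols, min, 1L)
  ord <- order(rmin, cmin)
  comp <- new_tbl(
    component_index = seq_along(keep),
    area_px = areas[keep][ord],
    centroid_row = unname(vapply(sp_rows, mean, 0))[ord],
    centroid_col = unname(vapply(sp_cols, mean, 0))[ord],
    bbox_rmin = unname(rmin)[ord],
    bbox_cmin = unname(cmin)[ord],
    bbox_rmax = unname(vapply(sp_rows, max, 1L))[ord],
    bbox_cmax = unname(vapply(sp_cols, max, 1L))[ord],
    pixels = unname(sp_idx)[ord])
  attr(comp, "n_area_filtered") <- n_filtered
  comp
}

#' Extract centered single-cell patches
#'
#' Windows the background-subtracted frame so each component's rounded
#' centroid sits at the patch center. Under `edge_policy = "discard"`,
#' components whose window exceeds the frame are dropped (and counted);
#' under `"zero_pad"` out-of-frame pixels are zero.
#'
#' @param frame,background Numeric matrices of identical shape.
#' @param components Output of [segment_frame()] on the same frame.
#' @param params A [segmentation_params()].
#' @param frame_index,sample_id Provenance stamped into each patch.
#' @return A list of `dhm_patch` objects (`values`, logical `mask`,
#'   `provenance`); attribute `n_edge_discarded` counts dropped components.
#' @export
extract_patches <- function(frame, background, components,
                            params = segmentation_params(),
                            frame_index = NA_integer_, sample_id = NA_character_) {
  ps <- params$patch_size
  half <- ps %/% 2L
  nr <- nrow(frame); nc <- ncol(frame)
  diffm <- frame - background
  if (params$edge_policy == "discard" && (ps > nr || ps > nc))
    warning("patch_size exceeds frame size; all components discarded")
  patches <- list()
  discarded <- 0L
  for (i in seq_len(nrow(components))) {
    rc <- round(components$centroid_row[i])
    cc <- round(components$centroid_col[i])
    r0 <- rc - half; r1 <- rc + half - 1L   # inclusive window bounds
    c0 <- cc - half; c1 <- cc + half - 1L
    inside <- r0 >= 1L && c0 >= 1L && r1 <= nr && c1 <= nc
    if (!inside && params$edge_policy == "discard") {
      discarded <- discarded + 1L
      next
    }
    vals <- matrix(0, ps, ps)
    rr <- max(r0, 1L):min(r1, nr)
    cxx <- max(c0, 1L):min(c1, nc)
    vals[rr - r0 + 1L, cxx - c0 + 1L] <- diffm[rr, cxx, drop = FALSE]
    mask <- matrix(FALSE, ps, ps)
    px <- components$pixels[[i]]
    prow <- (px - 1L) %% nr + 1L - r0 + 1L
    pcol <- (px - 1L) %/% nr + 1L - c0 + 1L
    ok <- prow >= 1L & prow <= ps & pcol >= 1L & pcol <= ps
    mask[cbind(prow[ok], pcol[ok])] <- TRUE
    patches[[length(patches) + 1L]] <- structure(
      list(values = vals, mask = mask,
           provenance = list(sample_id = sample_id,
                             frame_index = frame_index,
                             component_index = components$component_index[i],
                             centroid_row = components$centroid_row[i],
                             centroid_col = components$centroid_col[i],
                             area_px = components$area_px[i])),
      class = "dhm_patch")
  }
  attr(patches, "n_edge_discarded") <- discarded
  patches
}

patch_manifest <- function(patches) {
  grab <- function(field, proto) vapply(patches, function(p)
    p$provenance[[field]], proto)
  new_tbl(
    sample_id = grab("sample_id", character(1)),
    frame_index = grab("frame_index", 1L),
    component_index = grab("component_index", 1L),
    centroid_row = grab("centroid_row", 1),
    centroid_col = grab("centroid_col", 1),
    area_px = grab("area_px", 1L))
}

#' Preprocess a recording into single-cell patches
#'
#' Composition of [estimate_background()], [segment_frame()] and
#' [extract_patches()] over all frames of a recording, with a summary log
#' of every filtering step.
#'
#' @param recording A `dhm_recording` or list of frame matrices.
#' @param params A [segmentation_params()].
#' @return A list of `dhm_patch` objects with attributes `manifest` (tibble:
#'   sample_id, frame_index, component_index, centroid, area_px) and `log`
#'   (frames, components found, area-filtered, edge-discarded).
#' @export
preprocess_recording <- function(recording, params = segmentation_params()) {
  frames <- as_frame_list(recording)
  sample_id <- if (inherits(recording, "dhm_recording"))
    recording$sample_id else NA_character_
  if (length(frames) == 0L) stop("need at least one frame")
  bg <- estimate_background(frames, params)
  all_patches <- list()
  n_comp <- 0L; n_filtered <- 0L; n_edge <- 0L
  for (f in seq_along(frames)) {
    comp <- segment_frame(frames[[f]], bg, params)
    n_comp <- n_comp + nrow(comp)
    n_filtered <- n_filtered + attr(comp, "n_area_filtered")
    if (nrow(comp) == 0L) next
    p <- extract_patches(frames[[f]], bg, comp, params,
                         frame_index = f, sample_id = sample_id)
    n_edge <- n_edge + attr(p, "n_edge_discarded")
    all_patches <- c(all_patches, p)
  }
  manifest <- patch_manifest(all_patches)
  attr(all_patches, "manifest") <- manifest
  attr(all_patches, "log") <- list(
    n_frames = length(frames), n_components = n_comp,
    n_area_filtered = n_filtered, n_edge_discarded = n_edge,
    n_patches = length(all_patches))
  all_patches
}
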