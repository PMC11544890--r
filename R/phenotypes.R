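#' Describe a synthetic leukocyte phenotype
#'
#' A phenotype parameterizes the cell phantom renderer: a raised-cosine phase
#' bump of random radius and peak height, optionally elongated, angularly
#' lobed (a proxy for nuclear lobation) and roughened by multiplicative
#' speckle. The knobs map onto the morphological axes that distinguish
#' leukocyte classes in quantitative phase images: size, optical height,
#' contrast/texture and shape.
#'
#' @param class_name Class label carried into truth records.
#' @param radius_mean,radius_sd Cell radius in pixels (mean, SD). Cell-role
#'   phenotypes must have `radius_mean >= 4` so phantoms exceed the default
#'   30-pixel area filter.
#' @param peak_phase_mean,peak_phase_sd Maximum phase shift in radians; cell
#'   phenotypes must exceed the 0.8 rad segmentation threshold.
#' @param lobe_count Integer count of angular phase lobes (0 = smooth).
#' @param granularity_sd SD of the multiplicative intra-cell speckle.
#' @param eccentricity_mean Target mask elongation in `[0, 1)`.
#' @param role `"cell"` for classifiable cells, `"debris"` for sub-filter
#'   fragments (e.g. milk isolation remnants), which are exempt from the
#'   size/height floors.
#' @return A `dhm_phenotype` list.
#' @examples
#' ph <- class_phenotype("lymphocyte", 6.5, 0.7, 2.2, 0.15)
#' cell <- render_cell(ph, seed = 1)
#' @export
class_phenotype <- function(class_name, radius_mean, radius_sd,
                            peak_phase_mean, peak_phase_sd,
                            lobe_count = 0L, granularity_sd = 0,
                            eccentricity_mean = 0,
                            role = c("cell", "debris")) {
  role <- match.arg(role)
  stopifnot_scalar_number(radius_mean, "radius_mean", min = 0)
  stopifnot_scalar_number(radius_sd, "radius_sd", min = 0)
  stopifnot_scalar_number(peak_phase_mean, "peak_phase_mean", min = 0)
  stopifnot_scalar_number(peak_phase_sd, "peak_phase_sd", min = 0)
  stopifnot_scalar_number(granularity_sd, "granularity_sd", min = 0)
  if (role == "cell" && radius_mean < 4)
    stop("cell phenotypes need radius_mean >= 4 px (area-filter floor)")
  if (role == "cell" && peak_phase_mean <= 0.8)
    stop("cell phenotypes need peak_phase_mean > 0.8 rad (threshold floor)")
  if (eccentricity_mean < 0 || eccentricity_mean >= 1)
    stop("eccentricity_mean must lie in [0, 1)")
  if (lobe_count < 0 || lobe_count != round(lobe_count))
    stop("lobe_count must be a non-negative integer")
  structure(
    list(class_name = as.character(class_name),
         radius_mean = radius_mean, radius_sd = radius_sd,
         peak_phase_mean = peak_phase_mean, peak_phase_sd = peak_phase_sd,
         lobe_count = as.integer(lobe_count),
         granularity_sd = granularity_sd,
         eccentricity_mean = eccentricity_mean,
         role = role),
    class = "dhm_phenotype")
}

#' Default phenotype sets per sample matrix
#'
#' Stand-in phenotypes for the three leukocyte classes found in each matrix
#' (blood: granulocyte/lymphocyte/monocyte; milk: granulocyte/lymphocyte/
#' macrophage). Values are chosen so classes are separable but overlapping:
#' lymphocytes small, round and optically tall; granulocytes medium-sized
#' with angular lobes and strong texture; monocytes/macrophages large,
#' flatter and eccentric. They are not calibrated to bovine cells.
#'
#' @return A named list of [class_phenotype()] objects.
#' @export
blood_phenotypes <- function() {
  list(
    granulocyte = class_phenotype("granulocyte", 9.0, 1.0, 1.80, 0.15,
                                  lobe_count = 3L, granularity_sd = 0.15,
                                  eccentricity_mean = 0.15),
    lymphocyte  = class_phenotype("lymphocyte", 6.5, 0.7, 2.20, 0.15,
                                  lobe_count = 0L, granularity_sd = 0.05,
                                  eccentricity_mean = 0.05),
    monocyte    = class_phenotype("monocyte", 12.0, 1.2, 1.50, 0.12,
                                  lobe_count = 1L, granularity_sd = 0.10,
                                  eccentricity_mean = 0.30))
}

#' @rdname blood_phenotypes
#' @export
milk_phenotypes <- function() {
  list(
    granulocyte = class_phenotype("granulocyte", 9.0, 1.0, 1.75, 0.15,
                                  lobe_count = 3L, granularity_sd = 0.18,
                                  eccentricity_mean = 0.15),
    lymphocyte  = class_phenotype("lymphocyte", 6.5, 0.7, 2.10, 0.15,
                                  lobe_count = 0L, granularity_sd = 0.08,
                                  eccentricity_mean = 0.05),
    macrophage  = class_phenotype("macrophage", 13.0, 1.3, 1.40, 0.12,
                                  lobe_count = 1L, granularity_sd = 0.20,
                                  eccentricity_mean = 0.35))
}

#' @rdname blood_phenotypes
#' @export
debris_phenotype <- function() {
  class_phenotype("debris", 2.2, 0.2, 1.2, 0.1, role = "debris")
}

#' Scene configuration for synthetic phase frames
#'
#' Describes one recording scene: frame geometry, expected cell density, the
#' static microfluidic-channel artifact, background noise, and the phantom
#' overlap policy. Defaults mirror the recording conditions the pipeline
#' assumes: 512 x 384 px frames with on average 5 cells per frame.
#'
#' @param frame_shape Integer `(rows, cols)`; default `c(384, 512)`.
#' @param cells_per_frame_mean Expected Poisson cell count per frame.
#' @param noise_sd SD of i.i.d. background phase noise (radians).
#' @param artifact_amplitude Amplitude of the static channel pattern (rad).
#' @param overlap_policy `"forbid"` (default) rejects placements whose masks
#'   would share a pixel; `"allow"` permits overlap.
#' @param debris Optional debris [class_phenotype()] added to frames (e.g.
#'   milk isolation remnants); `NULL` for none.
#' @param debris_per_frame_mean Expected Poisson debris count per frame.
#' @return A `dhm_scene` list.
#' @export
scene_config <- function(frame_shape = c(384L, 512L),
                         cells_per_frame_mean = 5,
                         noise_sd = 0.05,
                         artifact_amplitude = 0.1,
                         overlap_policy = c("forbid", "allow"),
                         debris = NULL,
                         debris_per_frame_mean = 0) {
  overlap_policy <- match.arg(overlap_policy)
  if (length(frame_shape) != 2L || any(frame_shape < 1))
    stop("frame_shape must be two positive integers (rows, cols)")
  stopifnot_scalar_number(cells_per_frame_mean, "cells_per_frame_mean", 0)
  stopifnot_scalar_number(noise_sd, "noise_sd", 0)
  stopifnot_scalar_number(artifact_amplitude, "artifact_amplitude", 0)
  if (!is.null(debris) && !inherits(debris, "dhm_phenotype"))
    stop("debris must be NULL or a class_phenotype()")
  structure(
    list(frame_shape = as.integer(frame_shape),
         cells_per_frame_mean = cells_per_frame_mean,
         noise_sd = noise_sd,
         artifact_amplitude = artifact_amplitude,
         overlap_policy = overlap_policy,
         debris = debris,
         debris_per_frame_mean = debris_per_frame_mean),
    class = "dhm_scene")
}

#' Longitudinal study design with known class compositions
#'
#' Builds the sampling scheme the longitudinal generator realizes: a set of
#' subjects sampled on a fixed grid of days, each with a smooth, subject-
#' specific ground-truth leukocyte composition per matrix. Compositions are
#' drawn once (seeded) from a logistic-normal perturbation of a matrix-
#' typical base composition, so subjects differ systematically and days
#' drift mildly. The default grid is five subjects at fourteen sampling days
#' spanning a 26-day window.
#'
#' @param subjects Character vector of subject IDs.
#' @param days Strictly increasing numeric sampling days.
#' @param matrix `"blood"`, `"milk"`, or both.
#' @param base_composition Optional named list `matrix -> named proportions`.
#' @param subject_sd,day_sd Log-scale SDs of subject and day effects.
#' @param reference_noise_sd SD of the additive truncated-Gaussian noise that
#'   turns realized truth into the reference-method (flow-cytometry analog)
#'   series; must be `>= 0`.
#' @param seed Integer seed fixing the drawn compositions.
#' @return A `dhm_design` list with a `compositions` tibble
#'   (subject, day, matrix, class, proportion).
#' @export
study_design <- function(subjects = paste0("S", 1:5),
                         days = c(1, 3, 5, 8, 9, 10, 11, 12, 15, 17, 19, 22,
                                  24, 26),
                         matrix = c("blood", "milk"),
                         base_composition = NULL,
                         subject_sd = 0.20,
                         day_sd = 0.10,
                         reference_noise_sd = 0.02,
                         seed = 1L) {
  matrix <- match.arg(matrix, several.ok = TRUE)
  if (length(subjects) < 1L) stop("need at least one subject")
  if (any(diff(days) <= 0)) stop("days must be strictly increasing")
  if (reference_noise_sd < 0) stop("reference_noise_sd must be >= 0")
  base_default <- list(
    blood = c(granulocyte = 0.55, lymphocyte = 0.35, monocyte = 0.10),
    milk  = c(granulocyte = 0.40, lymphocyte = 0.45, macrophage = 0.15))
  base <- base_composition %||% base_default[matrix]

  comp <- with_seed_if(derive_seed(seed, "design"), {
    purrr::map_dfr(matrix, function(m) {
      b <- base[[m]]
      if (is.null(b) || abs(sum(b) - 1) > 1e-9 || any(b < 0))
        stop("base composition for ", m, " must be non-negative and sum to 1")
      purrr::map_dfr(subjects, function(s) {
        subj_eff <- rnorm(length(b), 0, subject_sd)
        purrr::map_dfr(days, function(d) {
          eta <- log(b) + subj_eff + rnorm(length(b), 0, day_sd)
          p <- exp(eta) / sum(exp(eta))
          tibble::tibble(subject_id = s, day = d, matrix = m,
                         class = names(b), proportion = unname(p))
        })
      })
    })
  })
  structure(
    list(subjects = as.character(subjects), days = days, matrix = matrix,
         compositions = comp, reference_noise_sd = reference_noise_sd,
         seed = seed),
    class = "dhm_design")
}
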