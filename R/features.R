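#' The 24-feature morphological catalog
#'
#' Names, units and one-line definitions of the hand-crafted features
#' computed per cell patch: ten mask-shape descriptors, nine phase-intensity
#' statistics (including the "contrast" SD), the optical volume (dry-mass
#' proxy), and four spatial-texture measures. The ordered name list doubles
#' as the feature schema; tables carry a fingerprint of it so models refuse
#' mismatched inputs.
#'
#' @return A tibble with `name`, `unit`, `description`.
#' @export
feature_catalog <- function() {
  tibble::tribble(
    ~name, ~unit, ~description,
    "area_um2", "um^2", "mask area (pixel count x pixel area)",
    "equivalent_diameter_um", "um", "diameter of the equal-area circle",
    "perimeter_um", "um", "exposed pixel-edge length x pixel pitch",
    "circularity", "1", "4*pi*area / perimeter^2",
    "eccentricity", "1", "eccentricity of the second-moment ellipse",
    "major_axis_um", "um", "major axis of the second-moment ellipse",
    "minor_axis_um", "um", "minor axis of the second-moment ellipse",
    "aspect_ratio", "1", "major / minor axis length",
    "solidity", "1", "mask pixels / convex-hull pixels",
    "extent", "1", "mask pixels / bounding-box pixels",
    "mean_phase", "rad", "mean phase over the mask",
    "median_phase", "rad", "median phase over the mask",
    "max_phase", "rad", "maximum phase (optical height)",
    "min_phase", "rad", "minimum phase over the mask",
    "phase_range", "rad", "max - min phase",
    "std_phase", "rad", "population SD of phase (contrast)",
    "phase_skewness", "1", "moment skewness of phase (0 if constant)",
    "phase_kurtosis", "1", "excess kurtosis of phase (0 if constant)",
    "phase_entropy", "nat", "entropy of a 32-bin phase histogram",
    "optical_volume", "rad um^2", "integrated phase x pixel area",
    "mass_displacement_um", "um",
    "distance between binary and phase-weighted centroids",
    "mean_gradient", "rad/px", "mean central-difference gradient magnitude",
    "radial_contrast", "rad", "SD of mean phase over 4 concentric rings",
    "n_local_maxima", "count",
    "local phase maxima after 1-px Gaussian smoothing (lobation proxy)")
}

.feature_cache <- new.env(parent = emptyenv())

feature_names <- function() {
  if (is.null(.feature_cache$names))
    .feature_cache$names <- feature_catalog()$name
  .feature_cache$names
}

feature_fingerprint <- function() {
  if (is.null(.feature_cache$fingerprint)) {
    cat_ <- feature_catalog()
    .feature_cache$fingerprint <- rlang::hash(
      paste(cat_$name, cat_$unit, collapse = ";"))
  }
  .feature_cache$fingerprint
}

# exposed pixel-edge count of a logical mask (4-neighborhood)
mask_perimeter_edges <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  nbr <- pad[1:nr, 2:(nc + 1L)] + pad[3:(nr + 2L), 2:(nc + 1L)] +
    pad[2:(nr + 1L), 1:nc] + pad[2:(nr + 1L), 3:(nc + 2L)]
  sum((4L - nbr)[core])
}

# number of lattice points (pixel centers) inside the convex hull of the
# mask's pixel centers, boundary inclusive; degenerate hulls count the mask
count_hull_pixels <- function(rows, cols) {
  n <- length(rows)
  if (n < 3L) return(n)
  h <- grDevices::chull(cols, rows)         # pixel coords are unique
  hx <- cols[h]; hy <- rows[h]
  k <- length(hx)
  if (k < 3L) return(n)
  # orient counter-clockwise
  area2 <- sum(hx * hy[c(2:k, 1)] - hx[c(2:k, 1)] * hy)
  if (abs(area2) < 1e-12) return(n)
  if (area2 < 0) { hx <- rev(hx); hy <- rev(hy); }
  gx <- rep(min(cols):max(cols), each = max(rows) - min(rows) + 1L)
  gy <- rep(min(rows):max(rows), times = max(cols) - min(cols) + 1L)
  inside <- rep(TRUE, length(gx))
  for (i in seq_len(length(hx))) {
    j <- if (i == length(hx)) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (gy - hy[i]) - (hy[j] - hy[i]) * (gx - hx[i])
    inside <- inside & (cross >= -1e-9)
  }
  sum(inside)
}

.kernel_cache <- new.env(parent = emptyenv())

gaussian_band_matrix <- function(n, sigma = 1, radius = 3L) {
  key <- paste0(n, ":", sigma, ":", radius)
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- exp(-(0:radius)^2 / (2 * sigma^2))
  w <- w / (w[1] + 2 * sum(w[-1]))
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  k <- matrix(0, n, n)
  k[d <= radius] <- w[d[d <= radius] + 1L]
  .kernel_cache[[key]] <- k
  k
}

# numpy-style gradient: central differences, one-sided at the borders
grad_1d <- function(m, along_rows) {
  n <- if (along_rows) nrow(m) else ncol(m)
  if (n == 1L) return(m * 0)
  if (along_rows) {
    g <- (m[c(2:n, n), , drop = FALSE] - m[c(1, 1:(n - 1)), , drop = FALSE]) / 2
    g[1, ] <- m[2, ] - m[1, ]
    g[n, ] <- m[n, ] - m[n - 1, ]
  } else {
    g <- (m[, c(2:n, n), drop = FALSE] - m[, c(1, 1:(n - 1)), drop = FALSE]) / 2
    g[, 1] <- m[, 2] - m[, 1]
    g[, n] <- m[, n] - m[, n - 1]
  }
  g
}

#' Compute the 24 morphological features of one cell patch
#'
#' Features are computed on the patch's foreground mask `M` and its
#' (background-subtracted) phase values `P`; see [feature_catalog()] for the
#' full list. Moments use the in-patch mask rather than a re-threshold of
#' the patch, keeping segmentation and description consistent. The
#' perimeter uses exposed pixel-edge counting, kurtosis is excess kurtosis,
#' entropy uses natural logs with empty bins contributing zero, and
#' zero-variance patches have skewness/kurtosis defined as 0.
#'
#' @param patch A `dhm_patch` (or list with `values` and `mask` matrices).
#' @param params A [segmentation_params()] (pixel area/pitch).
#' @return A named numeric vector of length 24.
#' @export
compute_features <- function(patch, params = segmentation_params()) {
  mask <- patch$mask
  P <- patch$values
  n <- sum(mask)
  if (n == 0L) stop("empty mask")
  if (n < 4L) stop("mask has fewer than 4 pixels; moments undefined")
  A <- params$pixel_area_um2
  pitch <- sqrt(A)
  idx <- which(mask)
  nr <- nrow(mask)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  x <- P[idx]

  # -- shape -----------------------------------------------------------
  area_um2 <- n * A
  eqd <- 2 * sqrt(area_um2 / pi)
  bb <- mask[min(rows):max(rows), min(cols):max(cols), drop = FALSE]
  per_um <- mask_perimeter_edges(bb) * pitch
  circ <- 4 * pi * area_um2 / per_um^2
  mr <- mean(rows); mc <- mean(cols)
  mu20 <- mean((rows - mr)^2)
  mu02 <- mean((cols - mc)^2)
  mu11 <- mean((rows - mr) * (cols - mc))
  tr2 <- (mu20 + mu02) / 2
  det_rt <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- tr2 + det_rt; l2 <- max(tr2 - det_rt, 0)
  ecc <- if (l1 > 0) sqrt(1 - l2 / l1) else 0
  major <- 4 * sqrt(l1) * pitch
  minor <- 4 * sqrt(l2) * pitch
  aspect <- if (l2 > 0) sqrt(l1 / l2) else Inf
  solidity <- n / count_hull_pixels(rows, cols)
  bh <- diff(range(rows)) + 1L; bw <- diff(range(cols)) + 1L
  extent <- n / (bh * bw)

  # -- phase statistics -------------------------------------------------
  mp <- mean(x)
  m2 <- mean((x - mp)^2)
  stdp <- sqrt(m2)
  skew <- if (m2 > 1e-24) mean((x - mp)^3) / m2^1.5 else 0
  kurt <- if (m2 > 1e-24) mean((x - mp)^4) / m2^2 - 3 else 0
  rng <- max(x) - min(x)
  if (rng < 1e-12) {
    entropy <- 0
  } else {
    bins <- pmin(32L, floor((x - min(x)) / rng * 32) + 1L)
    p <- tabulate(bins, 32L) / n
    p <- p[p > 0]
    entropy <- -sum(p * log(p))
  }

  # -- optical mass -----------------------------------------------------
  vol <- sum(x) * A
  sx <- sum(x)
  md <- if (sx > 0) {
    wr <- sum(rows * x) / sx; wc <- sum(cols * x) / sx
    sqrt((wr - mr)^2 + (wc - mc)^2) * pitch
  } else 0

  # -- texture ----------------------------------------------------------
  margin <- 4L
  r0 <- max(min(rows) - margin, 1L); r1 <- min(max(rows) + margin, nrow(P))
  c0 <- max(min(cols) - margin, 1L); c1 <- min(max(cols) + margin, ncol(P))
  crop <- P[r0:r1, c0:c1, drop = FALSE]
  cmask <- mask[r0:r1, c0:c1, drop = FALSE]
  gr <- grad_1d(crop, TRUE); gc <- grad_1d(crop, FALSE)
  mean_grad <- mean(sqrt(gr^2 + gc^2)[cmask])

  d <- sqrt((rows - mr)^2 + (cols - mc)^2)
  rmax <- max(d)
  if (rmax < 1e-12) {
    radial <- 0
  } else {
    ring <- pmax(1L, ceiling(d * 4 / rmax))
    cnt <- tabulate(ring, 4L)
    sums <- c(rowsum(x, ring))              # sorted by ring id, present only
    means <- sums / cnt[cnt > 0L]
    radial <- if (length(means) >= 2L)
      sqrt(mean((means - mean(means))^2)) else 0
  }

  kr <- gaussian_band_matrix(nrow(crop))
  kc <- gaussian_band_matrix(ncol(crop))
  S <- kr %*% crop %*% t(kc)
  ncr <- nrow(S); ncc <- ncol(S)
  nmax <- 0L
  if (ncr >= 3L && ncc >= 3L) {
    eps <- 1e-9   # plateau guard: ties within eps are not maxima
    ctr <- S[2:(ncr - 1L), 2:(ncc - 1L), drop = FALSE]
    is_max <- ctr > S[1:(ncr - 2L), 2:(ncc - 1L)] + eps &
      ctr > S[3:ncr, 2:(ncc - 1L)] + eps &
      ctr > S[2:(ncr - 1L), 1:(ncc - 2L)] + eps &
      ctr > S[2:(ncr - 1L), 3:ncc] + eps &
      ctr > S[1:(ncr - 2L), 1:(ncc - 2L)] + eps &
      ctr > S[1:(ncr - 2L), 3:ncc] + eps &
      ctr > S[3:ncr, 1:(ncc - 2L)] + eps &
      ctr > S[3:ncr, 3:ncc] + eps
    nmax <- sum(is_max & cmask[2:(ncr - 1L), 2:(ncc - 1L)])
  }

  setNames(
    c(area_um2, eqd, per_um, circ, ecc, major, minor, aspect, solidity,
      extent, mp, median(x), max(x), min(x), rng, stdp, skew, kurt,
      entropy, vol, md, mean_grad, radial, nmax),
    feature_names())
}

#' Assemble a feature table from patches
#'
#' One row per patch, in patch order, with the 24 features, provenance
#' columns from each patch, optional per-patch labels and recycled sample
#' metadata. The table carries the feature-schema fingerprint; models
#' trained on it refuse tables with a different schema.
#'
#' @param patches List of `dhm_patch` objects.
#' @param metadata Optional named list / one-row tibble of sample metadata
#'   (e.g. `subject_id`, `matrix`, `day`) recycled to all rows.
#' @param labels Optional character vector of class labels, one per patch.
#' @param params A [segmentation_params()].
#' @return A tibble; attribute `dhm_schema` holds feature names, units and
#'   fingerprint.
#' @export
build_feature_table <- function(patches, metadata = NULL, labels = NULL,
                                params = segmentation_params()) {
  if (!is.null(labels) && length(labels) != length(patches))
    stop("labels must align 1:1 with patches")
  nms <- feature_names()
  if (length(patches) == 0L) {
    tbl <- tibble::as_tibble(setNames(
      rep(list(double()), length(nms)), nms))
    if (!is.null(labels)) tbl$class <- character()
  } else {
    fmat <- t(vapply(patches, compute_features, numeric(length(nms)),
                     params = params))
    tbl <- tibble::as_tibble(as.data.frame(fmat))
    tbl <- dplyr::bind_cols(patch_manifest(patches), tbl)
    if (!is.null(labels)) tbl$class <- as.character(labels)
  }
  if (!is.null(metadata)) {
    for (nm in names(metadata)) tbl[[nm]] <- metadata[[nm]]
  }
  attr(tbl, "dhm_schema") <- list(features = nms,
                                  fingerprint = feature_fingerprint())
  tbl
}

#' Feature columns present in a table
#'
#' @param table A feature table.
#' @return Character vector of catalog feature names found in `table`.
#' @export
feature_columns <- function(table) {
  intersect(feature_names(), names(table))
}

# feature matrix + fingerprint check used by models
feature_matrix <- function(table) {
  nms <- feature_names()
  missing <- setdiff(nms, names(table))
  if (length(missing))
    stop("table lacks feature columns: ", paste(missing, collapse = ", "))
  as.matrix(table[nms])
}
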