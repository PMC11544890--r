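# Independent oracles: naive per-definition implementations used to verify
# the package's vectorized/compiled code paths.

# --- exhaustive flood fill (stack-based, pixel-at-a-time) -------------------
oracle_label <- function(fg, connectivity = 8L) {
  nr <- nrow(fg); nc <- ncol(fg)
  offs <- if (connectivity == 4L) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!fg[r, c] || lab[r, c] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r, c))
    lab[r, c] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in offs) {
        rr <- p[1] + o[1]; cc <- p[2] + o[2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            fg[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# canonical renumbering by first occurrence in column-major order, so two
# labelings agree iff they induce the same partition
canon_labels <- function(lab) {
  v <- as.integer(lab)
  u <- unique(v[v > 0L])
  map <- integer(max(v))
  map[u] <- seq_along(u)
  v[v > 0L] <- map[v[v > 0L]]
  matrix(v, nrow(lab))
}

# --- Andrew monotone chain convex hull (independent of grDevices::chull) ----
oracle_hull <- function(x, y) {
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  n <- length(x)
  if (n < 3L) return(cbind(x, y))
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  build <- function(ix) {
    h <- integer(0)
    for (i in ix) {
      while (length(h) >= 2L &&
             cross(x[h[length(h) - 1L]], y[h[length(h) - 1L]],
                   x[h[length(h)]], y[h[length(h)]], x[i], y[i]) <= 0)
        h <- h[-length(h)]
      h <- c(h, i)
    }
    h
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  keep <- c(lower[-length(lower)], upper[-length(upper)])
  cbind(x[keep], y[keep])
}

point_in_convex <- function(px, py, hx, hy, tol = 1e-9) {
  k <- length(hx)
  if (k == 1L) return(px == hx && py == hy)
  if (k == 2L) {
    cr <- (hx[2] - hx[1]) * (py - hy[1]) - (hy[2] - hy[1]) * (px - hx[1])
    if (abs(cr) > tol) return(FALSE)
    return(px >= min(hx) - tol && px <= max(hx) + tol &&
             py >= min(hy) - tol && py <= max(hy) + tol)
  }
  sgn <- 0
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    cr <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    if (abs(cr) <= tol) next
    s <- sign(cr)
    if (sgn == 0) sgn <- s else if (s != sgn) return(FALSE)
  }
  TRUE
}

# --- per-definition feature oracle (explicit loops everywhere) --------------
oracle_features <- function(values, mask, pixel_area = 11.9) {
  pitch <- sqrt(pixel_area)
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- c(); cols <- c(); x <- c()
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (mask[rr, cc]) {
      rows <- c(rows, rr); cols <- c(cols, cc); x <- c(x, values[rr, cc])
    }
  }
  n <- length(rows)

  # perimeter: exposed 4-neighbor edges
  edges <- 0L
  for (i in seq_len(n)) {
    for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- rows[i] + o[1]; cc <- cols[i] + o[2]
      outside <- rr < 1 || rr > nr || cc < 1 || cc > nc || !mask[rr, cc]
      if (outside) edges <- edges + 1L
    }
  }
  area_um2 <- n * pixel_area
  per_um <- edges * pitch

  mr <- mean(rows); mc <- mean(cols)
  mu20 <- sum((rows - mr)^2) / n
  mu02 <- sum((cols - mc)^2) / n
  mu11 <- sum((rows - mr) * (cols - mc)) / n
  tr2 <- (mu20 + mu02) / 2
  rt <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- tr2 + rt; l2 <- max(tr2 - rt, 0)

  h <- oracle_hull(cols, rows)
  hull_n <- 0L
  for (cc in min(cols):max(cols)) for (rr in min(rows):max(rows)) {
    if (point_in_convex(cc, rr, h[, 1], h[, 2])) hull_n <- hull_n + 1L
  }

  mp <- sum(x) / n
  m2 <- sum((x - mp)^2) / n
  m3 <- sum((x - mp)^3) / n
  m4 <- sum((x - mp)^4) / n
  rng <- max(x) - min(x)
  if (rng < 1e-12) {
    entropy <- 0
  } else {
    counts <- integer(32)
    for (v in x) {
      b <- min(32L, floor((v - min(x)) / rng * 32) + 1L)
      counts[b] <- counts[b] + 1L
    }
    entropy <- 0
    for (b in 1:32) {
      p <- counts[b] / n
      if (p > 0) entropy <- entropy - p * log(p)
    }
  }

  sx <- sum(x)
  if (sx > 0) {
    wr <- sum(rows * x) / sx; wc <- sum(cols * x) / sx
    md <- sqrt((wr - mr)^2 + (wc - mc)^2) * pitch
  } else md <- 0

  # crop for texture features: bbox +/- 4, clipped
  r0 <- max(min(rows) - 4L, 1L); r1 <- min(max(rows) + 4L, nr)
  c0 <- max(min(cols) - 4L, 1L); c1 <- min(max(cols) + 4L, nc)
  crop <- values[r0:r1, c0:c1, drop = FALSE]
  ncr <- nrow(crop); ncc <- ncol(crop)

  grad_at <- function(m, r, c) {
    gr <- if (nrow(m) == 1L) 0
    else if (r == 1L) m[2, c] - m[1, c]
    else if (r == nrow(m)) m[r, c] - m[r - 1L, c]
    else (m[r + 1L, c] - m[r - 1L, c]) / 2
    gc <- if (ncol(m) == 1L) 0
    else if (c == 1L) m[r, 2] - m[r, 1]
    else if (c == ncol(m)) m[r, c] - m[r, c - 1L]
    else (m[r, c + 1L] - m[r, c - 1L]) / 2
    sqrt(gr^2 + gc^2)
  }
  gsum <- 0
  for (i in seq_len(n))
    gsum <- gsum + grad_at(crop, rows[i] - r0 + 1L, cols[i] - c0 + 1L)

  d <- sqrt((rows - mr)^2 + (cols - mc)^2)
  rmax <- max(d)
  if (rmax < 1e-12) {
    radial <- 0
  } else {
    ring <- pmax(1L, ceiling(d * 4 / rmax))
    means <- c()
    for (k in 1:4) if (any(ring == k)) means <- c(means, mean(x[ring == k]))
    radial <- if (length(means) >= 2L)
      sqrt(sum((means - mean(means))^2) / length(means)) else 0
  }

  # Gaussian smoothing (sigma 1, radius 3), zero-padded, explicit loops
  w <- exp(-(0:3)^2 / 2); w <- w / (w[1] + 2 * sum(w[-1]))
  kern <- function(dd) if (abs(dd) <= 3) w[abs(dd) + 1L] else 0
  S1 <- matrix(0, ncr, ncc)
  for (r in seq_len(ncr)) for (c in seq_len(ncc)) {
    acc <- 0
    for (dd in -3:3) {
      rr <- r + dd
      if (rr >= 1 && rr <= ncr) acc <- acc + kern(dd) * crop[rr, c]
    }
    S1[r, c] <- acc
  }
  S <- matrix(0, ncr, ncc)
  for (r in seq_len(ncr)) for (c in seq_len(ncc)) {
    acc <- 0
    for (dd in -3:3) {
      cc <- c + dd
      if (cc >= 1 && cc <= ncc) acc <- acc + kern(dd) * S1[r, cc]
    }
    S[r, c] <- acc
  }
  nmax <- 0L
  for (i in seq_len(n)) {
    r <- rows[i] - r0 + 1L; c <- cols[i] - c0 + 1L
    if (r <= 1L || r >= ncr || c <= 1L || c >= ncc) next
    is_max <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      if (S[r, c] <= S[r + dr, c + dc] + 1e-9) is_max <- FALSE
    }
    if (is_max) nmax <- nmax + 1L
  }

  c(area_um2 = area_um2,
    equivalent_diameter_um = 2 * sqrt(area_um2 / pi),
    perimeter_um = per_um,
    circularity = 4 * pi * area_um2 / per_um^2,
    eccentricity = if (l1 > 0) sqrt(1 - l2 / l1) else 0,
    major_axis_um = 4 * sqrt(l1) * pitch,
    minor_axis_um = 4 * sqrt(l2) * pitch,
    aspect_ratio = if (l2 > 0) sqrt(l1 / l2) else Inf,
    solidity = n / hull_n,
    extent = n / ((max(rows) - min(rows) + 1) * (max(cols) - min(cols) + 1)),
    mean_phase = mp,
    median_phase = median(x),
    max_phase = max(x),
    min_phase = min(x),
    phase_range = rng,
    std_phase = sqrt(m2),
    phase_skewness = if (m2 > 1e-24) m3 / m2^1.5 else 0,
    phase_kurtosis = if (m2 > 1e-24) m4 / m2^2 - 3 else 0,
    phase_entropy = entropy,
    optical_volume = sx * pixel_area,
    mass_displacement_um = md,
    mean_gradient = gsum / n,
    radial_contrast = radial,
    n_local_maxima = nmax)
}

# --- small builders ---------------------------------------------------------

# a patch whose mask is the digital disc of radius r at the patch center,
# with phase given by `fill(dr, dc)` (default: constant)
make_disc_patch <- function(size = 9L, r = 3, value = 2,
                            fill = NULL) {
  ctr <- (size + 1) / 2
  vals <- matrix(0, size, size)
  mask <- matrix(FALSE, size, size)
  for (cc in seq_len(size)) for (rr in seq_len(size)) {
    if ((rr - ctr)^2 + (cc - ctr)^2 <= r^2) {
      mask[rr, cc] <- TRUE
      vals[rr, cc] <- if (is.null(fill)) value else fill(rr - ctr, cc - ctr)
    }
  }
  structure(list(values = vals, mask = mask,
                 provenance = list(sample_id = "fixture", frame_index = 1L,
                                   component_index = 1L, centroid_row = ctr,
                                   centroid_col = ctr,
                                   area_px = sum(mask))),
            class = "dhm_patch")
}

make_rect_patch <- function(size = 9L, h = 2L, w = 5L, value = 1) {
  vals <- matrix(0, size, size)
  mask <- matrix(FALSE, size, size)
  r0 <- floor((size - h) / 2) + 1L
  c0 <- floor((size - w) / 2) + 1L
  mask[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- TRUE
  vals[mask] <- value
  structure(list(values = vals, mask = mask,
                 provenance = list(sample_id = "fixture", frame_index = 1L,
                                   component_index = 1L,
                                   centroid_row = mean(which(mask) %% size),
                                   centroid_col = 0, area_px = sum(mask))),
            class = "dhm_patch")
}

# random gaussian-cloud feature table for classifier tests: 3 classes whose
# means differ by `sep` pooled SDs on each of three informative features
gaussian_feature_table <- function(n_per_class = 150L, sep = 3,
                                   classes = c("A", "B", "C"),
                                   subjects = NULL, seed = 1L) {
  nms <- holodcc::feature_catalog()$name
  mu <- rbind(c(0, 0, 0), c(sep, sep, 0), c(0, sep, sep))
  withr::with_seed(seed, {
    rows <- lapply(seq_along(classes), function(ci) {
      m <- matrix(rnorm(n_per_class * length(nms)), n_per_class)
      m[, 1:3] <- m[, 1:3] + rep(mu[ci, ], each = n_per_class)
      colnames(m) <- nms
      d <- tibble::as_tibble(as.data.frame(m))
      d$class <- classes[ci]
      d
    })
    tbl <- dplyr::bind_rows(rows)
    if (!is.null(subjects))
      tbl$subject_id <- sample(subjects, nrow(tbl), replace = TRUE)
    tbl
  })
}

# small scene used across tests
tiny_scene <- function(...) {
  scene_config(frame_shape = c(128L, 192L), cells_per_frame_mean = 5, ...)
}

tiny_params <- function(...) {
  segmentation_params(background_frames = 50L, edge_policy = "zero_pad", ...)
}
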