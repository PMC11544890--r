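#' Balance a labeled feature table with SMOTE
#'
#' Synthetic minority over-sampling: every class is raised to
#' `target_count` rows by interpolating new samples
#' `x_i + lambda * (x_nn - x_i)`, with `lambda ~ U(0, 1)` and `x_nn` one of
#' the `k_neighbors` same-class nearest neighbors of `x_i` (Euclidean
#' distance on z-standardized features; interpolation is affine, so the
#' result is identical in original units). Original rows are preserved
#' verbatim and synthetic rows are flagged in the `.synthetic` column, which
#' downstream splitters use to keep interpolated rows out of test and
#' validation partitions.
#'
#' @param table Labeled feature table (column `class`).
#' @param k_neighbors Neighborhood size (>= 1); every class that needs
#'   oversampling must have more than `k_neighbors` real rows.
#' @param target_count Per-class row count after balancing; default is the
#'   majority-class count.
#' @param lambda Optional fixed interpolation weight (testing hook);
#'   `NULL` draws `U(0, 1)` per synthetic row.
#' @param seed Integer seed.
#' @return The balanced tibble (originals first, then synthetic rows), with
#'   `.synthetic` flags and an attribute `smote_parents` (tibble: base and
#'   neighbor row indices into the input) for auditing.
#' @export
smote_balance <- function(table, k_neighbors = 5L, target_count = NULL,
                          lambda = NULL, seed = 1L) {
  if (!"class" %in% names(table)) stop("table must have a `class` column")
  if (k_neighbors < 1L) stop("k_neighbors must be >= 1")
  counts <- table(table$class)
  if (length(counts) < 2L) stop("need at least 2 classes")
  target <- as.integer(target_count %||% max(counts))
  X <- feature_matrix(table)
  ctr <- colMeans(X)
  scl <- apply(X, 2, function(v) { s <- sd(v); if (is.na(s) || s == 0) 1 else s })
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  out <- dplyr::mutate(table, .synthetic = FALSE)
  parents <- list()
  synth <- list()
  with_seed_if(seed, {
    for (cl in names(counts)) {
      m <- counts[[cl]]
      need <- target - m
      if (need <= 0L) next
      if (m <= k_neighbors)
        stop(sprintf("class '%s' has %d rows; needs > %d for SMOTE",
                     cl, m, k_neighbors))
      rows_cl <- which(table$class == cl)
      Zc <- Z[rows_cl, , drop = FALSE]
      # k nearest same-class neighbors of every class row (excluding self)
      nn <- knn_index(Zc, min(k_neighbors, m - 1L))
      base <- sample.int(m, need, replace = TRUE)
      pick <- nn[cbind(base, sample.int(ncol(nn), need, replace = TRUE))]
      lam <- if (is.null(lambda)) runif(need) else rep(lambda, need)
      Xb <- X[rows_cl[base], , drop = FALSE]
      Xn <- X[rows_cl[pick], , drop = FALSE]
      Xs <- Xb + lam * (Xn - Xb)
      new_rows <- table[rows_cl[base], ]
      new_rows[, colnames(Xs)] <- Xs
      new_rows$.synthetic <- TRUE
      synth[[cl]] <- new_rows
      parents[[cl]] <- tibble::tibble(base_row = rows_cl[base],
                                      neighbor_row = rows_cl[pick])
    }
  })
  res <- dplyr::bind_rows(out, dplyr::bind_rows(synth))
  attr(res, "dhm_schema") <- attr(table, "dhm_schema")
  attr(res, "smote_parents") <- dplyr::bind_rows(parents)
  res
}

# indices of the k nearest neighbors (excluding self) per row, chunked
knn_index <- function(Z, k) {
  m <- nrow(Z)
  sq <- rowSums(Z^2)
  out <- matrix(0L, m, k)
  chunk <- max(1L, floor(2e6 / m))
  for (start in seq(1L, m, by = chunk)) {
    ii <- start:min(start + chunk - 1L, m)
    D <- outer(sq[ii], sq, "+") - 2 * Z[ii, , drop = FALSE] %*% t(Z)
    D[cbind(seq_along(ii), ii)] <- Inf   # exclude self
    for (r in seq_along(ii)) {
      out[ii[r], ] <- order(D[r, ])[seq_len(k)]
    }
  }
  out
}
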