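#' Derive a reproducible child seed
#'
#' Stages of the pipeline draw their own seeds from one global seed plus a
#' stage key, so each stage is individually reproducible and inserting a new
#' stage does not shift the streams of the others.
#'
#' @param seed Integer scalar master seed.
#' @param ... Character/numeric key components naming the consumer.
#' @return An integer seed in `[0, 2^28)`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, character(1))),
               collapse = "/")
  strtoi(substr(rlang::hash(key), 1, 7), 16L)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# `seed = NULL` uses the current stream untouched.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Truncated-normal draw by rejection, bounded at mean +/- trunc*sd.
rnorm_trunc <- function(n, mean, sd, trunc = 2.5) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- abs(x - mean) > trunc * sd
  tries <- 0L
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- abs(x - mean) > trunc * sd
    tries <- tries + 1L
    if (tries > 100L) {
      x[bad] <- pmin(pmax(x[bad], mean - trunc * sd), mean + trunc * sd)
      break
    }
  }
  x
}

# minimal-overhead tibble constructor for hot loops (columns pre-validated)
new_tbl <- function(...) {
  l <- list(...)
  n <- if (length(l)) length(l[[1]]) else 0L
  structure(l, names = names(l), row.names = c(NA_integer_, -n),
            class = c("tbl_df", "tbl", "data.frame"))
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    stop(sprintf("`%s` must be a finite scalar >= %s", name, format(min)),
         call. = FALSE)
  }
  invisible(x)
}
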