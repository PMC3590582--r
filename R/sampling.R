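#' Spatial bucket grid over image-1 points
#'
#' Partitions the bounding box of the image-1 points into `b x b` buckets and
#' assigns every correspondence to the bucket its image-1 point falls in
#' (right/bottom boundary points are clamped into the last bucket). Buckets
#' with no matches are excluded. A zero-extent bounding box along one axis
#' degenerates to a single stripe along that axis.
#'
#' @param P A [match_set] with at least one correspondence.
#' @param b Buckets per side (default 8).
#' @return An object of class `bucket_grid`: list with `b`, the bounding box
#'   (`x_min`, `x_max`, `y_min`, `y_max`), `assignment` (row-major 0-based
#'   bucket index per correspondence) and `members` (list mapping non-empty
#'   bucket index to the correspondence ids it holds).
#' @export
build_bucket_grid <- function(P, b = 8) {
  stopifnot(n_matches(P) >= 1, b >= 1)
  x <- P$df$x1
  y <- P$df$y1
  bb <- c(x_min = min(x), x_max = max(x), y_min = min(y), y_max = max(y))
  idx_axis <- function(v, lo, hi) {
    if (hi <= lo) return(rep(0L, length(v)))  # zero extent: single stripe
    pmin(as.integer(floor(b * (v - lo) / (hi - lo))), b - 1L)
  }
  ix <- idx_axis(x, bb["x_min"], bb["x_max"])
  iy <- idx_axis(y, bb["y_min"], bb["y_max"])
  assignment <- iy * b + ix
  members <- split(P$df$id, assignment)
  structure(list(b = as.integer(b), x_min = bb[["x_min"]], x_max = bb[["x_max"]],
                 y_min = bb[["y_min"]], y_max = bb[["y_max"]],
                 assignment = assignment, members = members),
            class = "bucket_grid")
}

#' @export
print.bucket_grid <- function(x, ...) {
  cat(sprintf("<bucket_grid %dx%d, %d non-empty buckets, %d matches>\n",
              x$b, x$b, length(x$members), length(x$assignment)))
  invisible(x)
}

#' Draw a minimal sample from mutually distinct buckets
#'
#' Draws `s` distinct non-empty buckets uniformly without replacement, then
#' one correspondence uniformly from each, so the sample is spatially spread
#' (clustered minimal samples give unstable model hypotheses). When the grid
#' has fewer than `s` non-empty buckets the draw falls back to
#' [draw_uniform_sample()] over all correspondences in the grid, with a
#' `relaxransac_bucket_fallback` message.
#'
#' @param grid A [build_bucket_grid()] result.
#' @param s Sample size (>= 1).
#' @param seed Optional integer seed (`set.seed` is called when given;
#'   otherwise the current RNG stream is used).
#' @return Integer vector of `s` correspondence ids, lying in `s` distinct
#'   buckets when no fallback occurred.
#' @export
draw_bucketed_sample <- function(grid, s, seed = NULL) {
  stopifnot(s >= 1)
  if (!is.null(seed)) set.seed(seed)
  nb <- length(grid$members)
  if (nb < s) {
    signal_rr("relaxransac_bucket_fallback",
              sprintf("only %d non-empty buckets for sample size %d; uniform fallback", nb, s))
    ids <- unlist(grid$members, use.names = FALSE)
    if (length(ids) < s) {
      stop_rr("relaxransac_too_few_matches",
              sprintf("cannot draw %d from %d matches", s, length(ids)))
    }
    return(ids[sample.int(length(ids), s)])
  }
  sel <- sample.int(nb, s)
  vapply(grid$members[sel], function(mem) {
    if (length(mem) == 1) mem else mem[sample.int(length(mem), 1)]
  }, integer(1), USE.NAMES = FALSE)
}

#' Draw a uniform minimal sample
#'
#' @param P A [match_set] with at least `s` correspondences.
#' @inheritParams draw_bucketed_sample
#' @return Integer vector of `s` distinct correspondence ids, uniform without
#'   replacement; deterministic under a fixed seed.
#' @export
draw_uniform_sample <- function(P, s, seed = NULL) {
  stopifnot(s >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- n_matches(P)
  if (n < s) {
    stop_rr("relaxransac_too_few_matches",
            sprintf("cannot draw %d from %d matches", s, n))
  }
  P$df$id[sample.int(n, s)]
}
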