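#' Putative correspondence sets
#'
#' A `match_set` holds putative correspondences between two images: a point
#' `(x1, y1)` in image 1 matched to `(x2, y2)` in image 2, in 0-based pixel
#' coordinates (x right, y down, pixel centres). The initial putative set has
#' role `"P"`; the reduced high-confidence subset extracted by relaxation has
#' role `"E"` and remembers the ids of its parent set. The `strength` column
#' is filled by [relax()] (or by the match score of [ncc_match()]) and may be
#' `NA` before that.
#'
#' @param x1,y1,x2,y2 Numeric vectors of equal length: point coordinates in
#'   image 1 and image 2, in pixels.
#' @param strength Optional nonnegative per-match confidence; `NA` when unset.
#' @param id Optional integer ids, unique within the set; defaults to
#'   `seq_along(x1)`.
#' @param image1_size,image2_size Optional `c(width, height)` in pixels.
#' @param role `"P"` (initial putative set) or `"E"` (reduced set).
#' @return An object of class `match_set`: a list with elements `df` (a
#'   `data.frame` with columns `id`, `x1`, `y1`, `x2`, `y2`, `strength`),
#'   `image1_size`, `image2_size`, `role`, and `parent_ids` (ids of the parent
#'   set when `role == "E"`).
#' @examples
#' m <- match_set(x1 = c(0, 10), y1 = c(0, 5), x2 = c(2, 12), y2 = c(1, 6))
#' n_matches(m)
#' @export
match_set <- function(x1, y1, x2, y2, strength = NULL, id = NULL,
                      image1_size = NULL, image2_size = NULL, role = "P") {
  n <- length(x1)
  stopifnot(length(y1) == n, length(x2) == n, length(y2) == n)
  if (is.null(id)) id <- seq_len(n)
  if (anyDuplicated(id)) {
    stop_rr("relaxransac_invalid_matchset", "correspondence ids must be unique")
  }
  co <- c(x1, y1, x2, y2)
  if (n > 0 && !all(is.finite(co))) {
    stop_rr("relaxransac_invalid_matchset", "coordinates must be finite")
  }
  if (is.null(strength)) strength <- rep(NA_real_, n)
  structure(
    list(df = data.frame(id = as.integer(id), x1 = as.numeric(x1),
                         y1 = as.numeric(y1), x2 = as.numeric(x2),
                         y2 = as.numeric(y2), strength = as.numeric(strength)),
         image1_size = image1_size, image2_size = image2_size,
         role = match.arg(role, c("P", "E")), parent_ids = NULL),
    class = "match_set")
}

#' @rdname match_set
#' @param m A `match_set`.
#' @export
n_matches <- function(m) nrow(m$df)

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("<match_set role=%s, %d correspondences>\n", x$role, n_matches(x)))
  if (!is.null(x$image1_size)) {
    cat(sprintf("  image 1: %d x %d px\n", x$image1_size[1], x$image1_size[2]))
  }
  if (n_matches(x) > 0) print(utils::head(x$df, 5))
  invisible(x)
}

# n x 2 coordinate matrices, used by the solvers
coords1 <- function(m) cbind(m$df$x1, m$df$y1)
coords2 <- function(m) cbind(m$df$x2, m$df$y2)

# Subset preserving metadata; used to carve E out of P.
ms_subset <- function(m, keep, role = m$role) {
  out <- m
  out$df <- m$df[keep, , drop = FALSE]
  rownames(out$df) <- NULL
  out$role <- role
  if (identical(role, "E")) out$parent_ids <- m$df$id
  out
}

#' Read and write correspondence tables
#'
#' Correspondence files are plain text with a header line
#' `x1 y1 x2 y2` and an optional fifth `strength` column, tab-delimited
#' (comma-delimited input is also accepted).
#'
#' @param path File path.
#' @param image1_size,image2_size Optional `c(width, height)` to attach.
#' @return `read_matches()` returns a [match_set]; `write_matches()` returns
#'   `path` invisibly.
#' @export
read_matches <- function(path, image1_size = NULL, image2_size = NULL) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          strip.white = TRUE, check.names = FALSE)
  need <- c("x1", "y1", "x2", "y2")
  if (!all(need %in% names(df))) {
    stop_rr("relaxransac_io_error",
            sprintf("expected columns %s in %s", paste(need, collapse = ", "), path))
  }
  strength <- if ("strength" %in% names(df)) df$strength else NULL
  match_set(df$x1, df$y1, df$x2, df$y2, strength = strength,
            image1_size = image1_size, image2_size = image2_size)
}

#' @rdname read_matches
#' @param m A [match_set].
#' @param strengths Logical: write the `strength` column (only when any value
#'   is set).
#' @export
write_matches <- function(m, path, strengths = TRUE) {
  df <- m$df[, c("x1", "y1", "x2", "y2", "strength")]
  if (!strengths || all(is.na(df$strength))) df$strength <- NULL
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
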