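#' Hartley normalization of image points
#'
#' Conditions a point set for the linear solvers: translates the centroid to
#' the origin and scales isotropically so the mean distance from the origin is
#' `sqrt(2)`.
#'
#' @param points An n x 2 numeric matrix (or data.frame) of pixel coordinates.
#' @return A list with `points` (the transformed n x 2 matrix) and `transform`
#'   (the 3 x 3 similarity such that `transform %*% c(x, y, 1)` gives the
#'   transformed homogeneous point).
#' @export
hartley_normalize <- function(points) {
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  if (nrow(pts) < 2) {
    stop_rr("relaxransac_degenerate_configuration",
            "need at least 2 points to normalize")
  }
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  md <- mean(d)
  if (md <= 0) {
    stop_rr("relaxransac_degenerate_configuration",
            "all points coincide; normalization undefined")
  }
  sc <- sqrt(2) / md
  Tm <- matrix(c(sc, 0, -sc * ctr[1],
                 0, sc, -sc * ctr[2],
                 0, 0, 1), 3, 3, byrow = TRUE)
  list(points = sweep(pts, 2, ctr) * sc, transform = Tm)
}

# unit Frobenius norm, largest-magnitude entry positive
canonicalize_model <- function(m) {
  m <- m / sqrt(sum(m^2))
  if (m[which.max(abs(m))] < 0) m <- -m
  m
}

new_model <- function(m, kind) {
  structure(canonicalize_model(m), class = c(kind, "twoview_model"))
}

#' @export
print.twoview_model <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1]))
  print(unclass(x))
  invisible(x)
}

as_coord_pair <- function(m) {
  if (inherits(m, "match_set")) {
    list(p1 = coords1(m), p2 = coords2(m), id = m$df$id)
  } else {
    df <- as.data.frame(m)
    list(p1 = cbind(df$x1, df$y1), p2 = cbind(df$x2, df$y2),
         id = if (!is.null(df$id)) df$id else seq_len(nrow(df)))
  }
}

#' Estimate a fundamental matrix by the normalized 8-point algorithm
#'
#' Solves the epipolar constraint `t(x2) %*% F %*% x1 = 0` (homogeneous points
#' with third coordinate 1) for the 3 x 3 rank-2 matrix `F`: Hartley
#' normalization in both images, null vector of the epipolar design matrix,
#' rank-2 enforcement by zeroing the smallest singular value after
#' denormalization, then canonicalization to unit Frobenius norm with the
#' largest-magnitude entry positive.
#'
#' @param sample A [match_set] (or data.frame with columns `x1,y1,x2,y2`) of
#'   at least 8 correspondences.
#' @return A 3 x 3 matrix of class `fundamental_matrix`.
#' @seealso [sampson_distance()], [estimate_homography_dlt()]
#' @export
estimate_fundamental_8pt <- function(sample) {
  cp <- as_coord_pair(sample)
  if (nrow(cp$p1) < 8) {
    stop_rr("relaxransac_too_few_matches",
            "need at least 8 correspondences for the 8-point solver")
  }
  res <- .fm_8pt_cpp(cp$p1, cp$p2)
  if (!res$ok) {
    stop_rr("relaxransac_degenerate_sample",
            "degenerate sample: epipolar design matrix has ambiguous null space")
  }
  new_model(res$m, "fundamental_matrix")
}

#' Estimate a homography by the normalized DLT
#'
#' Solves `x2 ~ H %*% x1` (projective equality) for the nonsingular 3 x 3
#' matrix `H` from at least 4 correspondences, with Hartley normalization and
#' the same canonicalization as [estimate_fundamental_8pt()].
#'
#' @inheritParams estimate_fundamental_8pt
#' @return A 3 x 3 matrix of class `homography`.
#' @export
estimate_homography_dlt <- function(sample) {
  cp <- as_coord_pair(sample)
  if (nrow(cp$p1) < 4) {
    stop_rr("relaxransac_too_few_matches",
            "need at least 4 correspondences for the DLT solver")
  }
  res <- .h_dlt_cpp(cp$p1, cp$p2)
  if (!res$ok) {
    stop_rr("relaxransac_degenerate_sample",
            "degenerate sample: DLT design matrix has ambiguous null space")
  }
  new_model(res$m, "homography")
}

residual_raw <- function(model, p1, p2) {
  if (inherits(model, "fundamental_matrix")) {
    as.numeric(.sampson_cpp(unclass(model), p1, p2))
  } else if (inherits(model, "homography")) {
    as.numeric(.transfer_cpp(unclass(model), p1, p2))
  } else {
    stop_rr("relaxransac_invalid_model",
            "model must be a fundamental_matrix or homography")
  }
}

#' Point-to-model residuals
#'
#' `sampson_distance()` is the first-order approximation of a
#' correspondence's geometric distance to the epipolar constraint manifold:
#' `sqrt((t(x2) F x1)^2 / ((F x1)[1]^2 + (F x1)[2]^2 + (t(F) x2)[1]^2 +
#' (t(F) x2)[2]^2))`, in pixels. `transfer_error()` is the symmetric transfer
#' error `sqrt((|q - pi(H p)|^2 + |p - pi(H^-1 q)|^2) / 2)` with `pi` the
#' dehomogenization.
#'
#' @param F,H A `fundamental_matrix` / `homography` (any 3 x 3 matrix is
#'   accepted and canonicalized).
#' @param m A [match_set] or data.frame of correspondences.
#' @return Numeric vector of nonnegative residuals, one per correspondence.
#' @export
sampson_distance <- function(F, m) {
  if (!inherits(F, "fundamental_matrix")) F <- new_model(as.matrix(F), "fundamental_matrix")
  cp <- as_coord_pair(m)
  r <- residual_raw(F, cp$p1, cp$p2)
  if (anyNA(r)) {
    stop_rr("relaxransac_undefined_residual",
            sprintf("Sampson distance undefined (all gradient terms zero) for correspondence id(s): %s",
                    paste(cp$id[is.na(r)], collapse = ", ")))
  }
  r
}

#' @rdname sampson_distance
#' @export
transfer_error <- function(H, m) {
  if (!inherits(H, "homography")) H <- new_model(as.matrix(H), "homography")
  cp <- as_coord_pair(m)
  r <- residual_raw(H, cp$p1, cp$p2)
  if (anyNA(r)) {
    stop_rr("relaxransac_undefined_residual",
            sprintf("transfer error undefined (point maps to infinity) for correspondence id(s): %s",
                    paste(cp$id[is.na(r)], collapse = ", ")))
  }
  r
}

#' Classify inliers of a geometric model
#'
#' Marks each correspondence inlier when its residual (Sampson distance for a
#' fundamental matrix, symmetric transfer error for a homography) is at most
#' `threshold` pixels. Correspondences whose residual is undefined are
#' classified outlier and reported via a message.
#'
#' @param model A `fundamental_matrix` or `homography`.
#' @param m A [match_set].
#' @param threshold Inlier threshold in pixels (> 0).
#' @return Logical mask of length `n_matches(m)`.
#' @export
classify_inliers <- function(model, m, threshold = 1.5) {
  stopifnot(threshold > 0)
  cp <- as_coord_pair(m)
  if (nrow(cp$p1) == 0) return(logical(0))
  r <- residual_raw(model, cp$p1, cp$p2)
  if (anyNA(r)) {
    signal_rr("relaxransac_undefined_residual_outlier",
              sprintf("residual undefined for id(s) %s; classified as outlier",
                      paste(cp$id[is.na(r)], collapse = ", ")))
  }
  !is.na(r) & r <= threshold
}

#' Read and write 3 x 3 model matrices
#'
#' Models are stored as three whitespace-delimited text lines, row-major, at
#' full double precision (17 significant digits).
#'
#' @param m A 3 x 3 model matrix.
#' @param path File path.
#' @param kind `"fundamental"` or `"homography"`, the class to attach on read.
#' @return `read_model()` returns the classed 3 x 3 matrix; `write_model()`
#'   returns `path` invisibly.
#' @export
write_model <- function(m, path) {
  m <- unclass(m)
  lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path, kind = c("fundamental", "homography")) {
  kind <- match.arg(kind)
  vals <- scan(path, what = double(), quiet = TRUE)
  if (length(vals) != 9) {
    stop_rr("relaxransac_io_error", "model file must contain exactly 9 numbers")
  }
  m <- matrix(vals, 3, 3, byrow = TRUE)
  new_model(m, if (kind == "fundamental") "fundamental_matrix" else "homography")
}
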