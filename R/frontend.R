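#' Read a grayscale image
#'
#' Reads PNG, TIFF or PGM (P2/P5, 8- or 16-bit) into a matrix of intensities
#' in `[0, 1]` (rows are image rows, so the point `(x, y)` in 0-based pixel
#' coordinates is `img[y + 1, x + 1]`). Colour images are converted to
#' grayscale by Rec. 709 luminance (0.2126 R + 0.7152 G + 0.0722 B).
#'
#' @param path Image file; format chosen by extension (`.png`, `.tif(f)`,
#'   `.pgm`).
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    pgm = read_pgm(path),
    stop_rr("relaxransac_io_error",
            sprintf("unsupported image format: .%s", ext)))
  if (length(dim(img)) == 3) {
    nc <- dim(img)[3]
    img <- if (nc >= 3) {
      0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    } else {
      img[, , 1]
    }
  }
  pmin(pmax(img, 0), 1)
}

# Minimal PGM (P2 ASCII / P5 binary) reader; 8- or 16-bit.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- pgm_tokenizer(con)
  magic <- tok()
  if (!magic %in% c("P2", "P5")) {
    stop_rr("relaxransac_io_error", "not a PGM file (expected P2 or P5)")
  }
  w <- as.integer(tok()); h <- as.integer(tok()); maxval <- as.integer(tok())
  if (magic == "P2") {
    vals <- as.numeric(scan(con, what = double(), n = w * h, quiet = TRUE,
                            comment.char = "#"))
  } else {
    if (maxval < 256) {
      vals <- as.numeric(readBin(con, "integer", n = w * h, size = 1,
                                 signed = FALSE))
    } else {
      vals <- as.numeric(readBin(con, "integer", n = w * h, size = 2,
                                 signed = FALSE, endian = "big"))
    }
  }
  if (length(vals) != w * h) {
    stop_rr("relaxransac_io_error", "truncated PGM payload")
  }
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

# Whitespace/comment-aware token reader for the PGM header; consumes exactly
# one whitespace byte after the last header token (PGM spec).
pgm_tokenizer <- function(con) {
  function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0) stop_rr("relaxransac_io_error", "truncated PGM header")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (length(ch) == 0 || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
      } else {
        tok <- paste0(tok, ch)
      }
    }
  }
}

#' Harris corner detector configuration
#'
#' @param sigma Gaussian scale of the structure tensor, pixels (default 1).
#' @param k Harris response constant (default 0.04; must be in (0, 0.25)).
#' @param nms_radius Non-maximum-suppression radius, pixels (default 3).
#' @param max_corners Keep at most this many strongest corners (default 500).
#' @param response_threshold Keep responses above this fraction of the
#'   maximum response (default 0.01).
#' @return A list of class `harris_config`.
#' @export
harris_config <- function(sigma = 1.0, k = 0.04, nms_radius = 3,
                          max_corners = 500, response_threshold = 0.01) {
  stopifnot(sigma > 0, k > 0, k < 0.25, nms_radius >= 1, max_corners >= 1,
            response_threshold > 0)
  structure(list(sigma = sigma, k = k, nms_radius = as.integer(nms_radius),
                 max_corners = as.integer(max_corners),
                 response_threshold = response_threshold),
            class = "harris_config")
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with replicate padding, via shifted adds.
convolve_sep <- function(img, k) {
  r <- (length(k) - 1L) / 2L
  shift_rows <- function(m, d) {
    nr <- nrow(m)
    idx <- pmin(pmax(seq_len(nr) + d, 1L), nr)
    m[idx, , drop = FALSE]
  }
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(k)) out <- out + k[i] * shift_rows(img, i - r - 1L)
  out2 <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(k)) {
    out2 <- out2 + k[i] * t(shift_rows(t(out), i - r - 1L))
  }
  out2
}

max_filter <- function(img, r) {
  out <- img
  nr <- nrow(img); nc <- ncol(img)
  for (dy in -r:r) {
    ridx <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
    for (dx in -r:r) {
      cidx <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
      out <- pmax(out, img[ridx, cidx, drop = FALSE])
    }
  }
  out
}

#' Harris corner detection
#'
#' Computes the Harris response `R = det(M) - k * trace(M)^2` on the
#' Gaussian-smoothed structure tensor `M` of the image gradients, suppresses
#' non-maxima within `nms_radius`, thresholds at
#' `response_threshold * max(R)`, and returns the strongest `max_corners`
#' corners in deterministic order (response descending, then y, then x).
#'
#' @param img Grayscale image matrix from [read_gray_image()] (at least
#'   3 x 3).
#' @param cfg A [harris_config()].
#' @return A data.frame with columns `x`, `y` (0-based pixel coordinates) and
#'   `response`; possibly empty.
#' @export
harris_corners <- function(img, cfg = harris_config()) {
  stopifnot(nrow(img) >= 3, ncol(img) >= 3)
  nr <- nrow(img); nc <- ncol(img)
  # central-difference gradients (replicate boundary)
  gx <- (img[, pmin(seq_len(nc) + 1, nc)] - img[, pmax(seq_len(nc) - 1, 1)]) / 2
  gy <- (img[pmin(seq_len(nr) + 1, nr), ] - img[pmax(seq_len(nr) - 1, 1), ]) / 2
  k1 <- gaussian_kernel_1d(cfg$sigma)
  a <- convolve_sep(gx * gx, k1)
  b <- convolve_sep(gy * gy, k1)
  c_ <- convolve_sep(gx * gy, k1)
  resp <- (a * b - c_ * c_) - cfg$k * (a + b)^2
  mx <- max(resp)
  if (mx <= 0) {
    return(data.frame(x = numeric(0), y = numeric(0), response = numeric(0)))
  }
  is_max <- resp == max_filter(resp, cfg$nms_radius) &
    resp >= cfg$response_threshold * mx
  idx <- which(is_max, arr.ind = TRUE)
  out <- data.frame(x = idx[, 2] - 1, y = idx[, 1] - 1,
                    response = resp[is_max])
  out <- out[order(-out$response, out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, cfg$max_corners)
}

#' Match corners by normalized cross-correlation
#'
#' Extracts a square patch of half-size `window` around every point, computes
#' the zero-mean normalized cross-correlation between all patch pairs, and
#' keeps a pair only when the two points are each other's best match
#' (mutual-best) and the correlation is at least `min_ncc`; the output is
#' one-to-one in both directions. Points within `window` pixels of the image
#' border are skipped, as are zero-variance (constant) patches.
#'
#' @param img1,img2 Grayscale image matrices.
#' @param pts1,pts2 Data frames with `x`, `y` columns (0-based), e.g. from
#'   [harris_corners()].
#' @param window Patch half-size in pixels (default 7, i.e. 15 x 15 patches).
#' @param min_ncc Correlation floor in `[-1, 1]` (default 0.8).
#' @return A [match_set] (role P, image sizes set, NCC stored as `strength`);
#'   possibly empty.
#' @export
ncc_match <- function(img1, pts1, img2, pts2, window = 7, min_ncc = 0.8) {
  e1 <- extract_patches(img1, pts1, window)
  e2 <- extract_patches(img2, pts2, window)
  sizes <- list(image1_size = c(ncol(img1), nrow(img1)),
                image2_size = c(ncol(img2), nrow(img2)))
  if (nrow(e1$patches) == 0 || nrow(e2$patches) == 0) {
    return(do.call(match_set,
                   c(list(x1 = numeric(0), y1 = numeric(0),
                          x2 = numeric(0), y2 = numeric(0)), sizes)))
  }
  C <- tcrossprod(e1$patches, e2$patches)
  best12 <- max.col(C, ties.method = "first")
  best21 <- max.col(t(C), ties.method = "first")
  i <- seq_len(nrow(C))
  ncc <- C[cbind(i, best12)]
  keep <- best21[best12] == i & ncc >= min_ncc
  do.call(match_set,
          c(list(x1 = e1$pts$x[keep], y1 = e1$pts$y[keep],
                 x2 = e2$pts$x[best12[keep]], y2 = e2$pts$y[best12[keep]],
                 strength = ncc[keep]), sizes))
}

# Zero-mean, unit-norm patch rows; drops border and constant patches.
extract_patches <- function(img, pts, w) {
  nr <- nrow(img); nc <- ncol(img)
  row0 <- round(pts$y) + 1L
  col0 <- round(pts$x) + 1L
  usable <- row0 - w >= 1 & row0 + w <= nr & col0 - w >= 1 & col0 + w <= nc
  pts <- pts[usable, , drop = FALSE]
  row0 <- row0[usable]; col0 <- col0[usable]
  m <- (2L * w + 1L)^2
  P <- matrix(0, length(row0), m)
  for (j in seq_along(row0)) {
    P[j, ] <- as.numeric(img[(row0[j] - w):(row0[j] + w),
                             (col0[j] - w):(col0[j] + w)])
  }
  P <- P - rowMeans(P)
  nrm <- sqrt(rowSums(P^2))
  flat <- nrm <= 1e-12
  if (any(flat)) {
    signal_rr("relaxransac_flat_patch",
              sprintf("%d constant patch(es) skipped in NCC matching", sum(flat)))
    P <- P[!flat, , drop = FALSE]
    pts <- pts[!flat, , drop = FALSE]
    nrm <- nrm[!flat]
  }
  list(patches = P / nrm, pts = pts)
}
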