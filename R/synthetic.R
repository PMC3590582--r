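#' Synthetic two-view scenes with known geometry
#'
#' Ground-truth generators for benchmarking the pipeline without external
#' images. `generate_f_scene()` builds a general two-view scene: random 3-D
#' points in a box in front of two cameras with a random relative pose
#' (rotation between 5 and 15 degrees about a random axis, baseline length
#' 0.25-0.5 scene units at point depths of 4-8), shared pinhole intrinsics
#' (focal length about one image width, principal point at the image
#' centre). The true fundamental matrix follows from the pose and
#' intrinsics. `generate_h_scene()` places the points on a 3-D plane (tilt at
#' most 20 degrees), so the two views are related by the induced homography.
#'
#' Inlier correspondences are the two projections of the same 3-D point with
#' isotropic Gaussian pixel noise of `sigma/sqrt(2)` added in each image (so
#' the Sampson residual scale matches `sigma`). Outliers pair independent
#' uniform points in the two image rectangles and are resampled until they
#' are farther than `inlier_threshold` from the true model, so the requested
#' inlier ratio is exact by construction. The rows are randomly permuted.
#'
#' @param n Number of correspondences (>= 8 for F-scenes, >= 4 for H-scenes).
#' @param phi Inlier ratio in `[0, 1]`; exactly `round(phi * n)` inliers are
#'   generated.
#' @param sigma Inlier noise standard deviation in pixels (>= 0).
#' @param image_size `c(width, height)` in pixels (default 640 x 480).
#' @param seed Integer seed; the same seed reproduces the scene exactly.
#' @param inlier_threshold Residual separating outliers from the true model
#'   (default 1.5 px, the pipeline's default threshold).
#' @return An object of class `synthetic_scene`: list with `matches` (a
#'   [match_set], role P, image sizes set), `true_model`, `true_inlier_mask`,
#'   `phi_true`, `sigma`, `seed`, and `camera` (intrinsics, rotation,
#'   translation, and for H-scenes the plane).
#' @examples
#' sc <- generate_f_scene(n = 50, phi = 0.5, sigma = 0.5, seed = 1)
#' sum(sc$true_inlier_mask)
#' @export
generate_f_scene <- function(n, phi, sigma, image_size = c(640, 480),
                             seed = 0, inlier_threshold = 1.5) {
  stopifnot(n >= 8, phi >= 0, phi <= 1, sigma >= 0)
  set.seed(seed)
  cam <- random_camera_pair(image_size)
  Fm <- fundamental_from_pose(cam)
  n_in <- round(phi * n)
  inl <- sample_f_inliers(n_in, cam, image_size)
  scene_assemble(inl, Fm, n, n_in, sigma, image_size, seed, phi,
                 inlier_threshold, cam)
}

#' @rdname generate_f_scene
#' @param rotation,translation Optional fixed relative pose (3 x 3 rotation,
#'   length-3 translation) overriding the random pose; H-scenes only.
#' @param plane_normal Optional fixed unit plane normal in the camera-1 frame
#'   (plane passes through `(0, 0, 6)`); H-scenes only.
#' @export
generate_h_scene <- function(n, phi, sigma, image_size = c(640, 480),
                             seed = 0, inlier_threshold = 1.5,
                             rotation = NULL, translation = NULL,
                             plane_normal = NULL) {
  stopifnot(n >= 4, phi >= 0, phi <= 1, sigma >= 0)
  set.seed(seed)
  cam <- random_camera_pair(image_size)
  if (!is.null(rotation)) cam$R <- rotation
  if (!is.null(translation)) cam$t <- as.numeric(translation)
  z0 <- 6
  if (is.null(plane_normal)) {
    tilt <- runif(1, 0, 20) * pi / 180
    az <- runif(1, 0, 2 * pi)
    plane_normal <- c(sin(tilt) * cos(az), sin(tilt) * sin(az), cos(tilt))
  }
  plane_normal <- plane_normal / sqrt(sum(plane_normal^2))
  d_plane <- plane_normal[3] * z0  # plane through (0, 0, z0)
  cam$plane <- list(normal = plane_normal, d = d_plane, z0 = z0)
  Hm <- with(cam, K %*% (R + tcrossprod(t, plane_normal) / d_plane) %*% solve(K))
  Hm <- new_model(Hm, "homography")
  n_in <- round(phi * n)
  inl <- sample_h_inliers(n_in, cam, image_size)
  scene_assemble(inl, Hm, n, n_in, sigma, image_size, seed, phi,
                 inlier_threshold, cam)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene %s: n = %d, phi = %.2f (%d inliers), sigma = %.2g px, seed = %d>\n",
              class(x$true_model)[1], n_matches(x$matches), x$phi_true,
              sum(x$true_inlier_mask), x$sigma, x$seed))
  invisible(x)
}

random_camera_pair <- function(image_size) {
  w <- image_size[1]; h <- image_size[2]
  f <- runif(1, 0.9, 1.1) * w
  K <- matrix(c(f, 0, (w - 1) / 2,
                0, f, (h - 1) / 2,
                0, 0, 1), 3, 3, byrow = TRUE)
  axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
  angle <- runif(1, 5, 15) * pi / 180
  R <- rotation_matrix(axis, angle)
  tdir <- rnorm(3); tdir <- tdir / sqrt(sum(tdir^2))
  t <- tdir * runif(1, 0.25, 0.5)
  list(K = K, R = R, t = t, axis = axis, angle_deg = angle * 180 / pi)
}

rotation_matrix <- function(axis, angle) {
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  C <- matrix(c(0, -z, y, z, 0, -x, -y, x, 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * C + (1 - cos(angle)) * (C %*% C)
}

fundamental_from_pose <- function(cam) {
  tx <- with(cam, matrix(c(0, -t[3], t[2], t[3], 0, -t[1], -t[2], t[1], 0),
                         3, 3, byrow = TRUE))
  Ki <- solve(cam$K)
  new_model(t(Ki) %*% tx %*% cam$R %*% Ki, "fundamental_matrix")
}

# Back-project uniform image-1 pixels at random depth, keep pairs visible in
# both views. Returns n x 4 matrix (x1 y1 x2 y2) of noise-free projections.
sample_f_inliers <- function(n_in, cam, image_size, max_tries = 1000) {
  w <- image_size[1]; h <- image_size[2]
  Ki <- solve(cam$K)
  out <- matrix(numeric(0), 0, 4)
  tries <- 0
  while (nrow(out) < n_in) {
    tries <- tries + 1
    if (tries > max_tries) {
      stop_rr("relaxransac_generation_error",
              "could not place enough scene points visible in both views")
    }
    m <- max(2L * (n_in - nrow(out)), 16L)
    x1 <- runif(m, 0.05 * w, 0.95 * w - 1)
    y1 <- runif(m, 0.05 * h, 0.95 * h - 1)
    z <- runif(m, 4, 8)
    X <- t(Ki %*% rbind(x1, y1, 1)) * z           # 3-D points, camera-1 frame
    X2 <- t(cam$R %*% t(X) + cam$t)
    ok <- X2[, 3] > 0.1
    x2 <- (cam$K[1, 1] * X2[, 1] + cam$K[1, 3] * X2[, 3]) / X2[, 3]
    y2 <- (cam$K[2, 2] * X2[, 2] + cam$K[2, 3] * X2[, 3]) / X2[, 3]
    ok <- ok & x2 >= 0 & x2 <= w - 1 & y2 >= 0 & y2 <= h - 1
    out <- rbind(out, cbind(x1, y1, x2, y2)[ok, , drop = FALSE])
  }
  out[seq_len(n_in), , drop = FALSE]
}

# Intersect the image-1 viewing ray with the scene plane instead of a random
# depth; otherwise identical to sample_f_inliers.
sample_h_inliers <- function(n_in, cam, image_size, max_tries = 1000) {
  w <- image_size[1]; h <- image_size[2]
  Ki <- solve(cam$K)
  nrm <- cam$plane$normal; d <- cam$plane$d
  out <- matrix(numeric(0), 0, 4)
  tries <- 0
  while (nrow(out) < n_in) {
    tries <- tries + 1
    if (tries > max_tries) {
      stop_rr("relaxransac_generation_error",
              "could not place enough plane points visible in both views")
    }
    m <- max(2L * (n_in - nrow(out)), 16L)
    x1 <- runif(m, 0.05 * w, 0.95 * w - 1)
    y1 <- runif(m, 0.05 * h, 0.95 * h - 1)
    ray <- t(Ki %*% rbind(x1, y1, 1))
    lambda <- d / as.numeric(ray %*% nrm)
    X <- ray * lambda
    ok <- lambda > 0.1
    X2 <- t(cam$R %*% t(X) + cam$t)
    ok <- ok & X2[, 3] > 0.1
    x2 <- (cam$K[1, 1] * X2[, 1] + cam$K[1, 3] * X2[, 3]) / X2[, 3]
    y2 <- (cam$K[2, 2] * X2[, 2] + cam$K[2, 3] * X2[, 3]) / X2[, 3]
    ok <- ok & x2 >= 0 & x2 <= w - 1 & y2 >= 0 & y2 <= h - 1
    out <- rbind(out, cbind(x1, y1, x2, y2)[ok, , drop = FALSE])
  }
  out[seq_len(n_in), , drop = FALSE]
}

# Add noise, draw model-inconsistent outliers, shuffle, wrap up.
scene_assemble <- function(inl, model, n, n_in, sigma, image_size, seed, phi,
                           inlier_threshold, cam) {
  w <- image_size[1]; h <- image_size[2]
  if (sigma > 0 && n_in > 0) {
    inl <- inl + matrix(rnorm(4 * n_in, sd = sigma / sqrt(2)), n_in, 4)
  }
  n_out <- n - n_in
  outl <- matrix(numeric(0), 0, 4)
  tries <- 0
  while (nrow(outl) < n_out) {
    tries <- tries + 1
    if (tries > 1000) {
      stop_rr("relaxransac_generation_error",
              "could not draw enough model-inconsistent outliers")
    }
    m <- max(2L * (n_out - nrow(outl)), 16L)
    cand <- cbind(runif(m, 0, w - 1), runif(m, 0, h - 1),
                  runif(m, 0, w - 1), runif(m, 0, h - 1))
    res <- residual_raw(model, cand[, 1:2, drop = FALSE],
                        cand[, 3:4, drop = FALSE])
    keep <- !is.na(res) & res > inlier_threshold
    outl <- rbind(outl, cand[keep, , drop = FALSE])
  }
  outl <- outl[seq_len(n_out), , drop = FALSE]
  all_m <- rbind(inl, outl)
  mask <- c(rep(TRUE, n_in), rep(FALSE, n_out))
  ord <- sample.int(n)
  all_m <- all_m[ord, , drop = FALSE]
  mask <- mask[ord]
  structure(list(
    matches = match_set(all_m[, 1], all_m[, 2], all_m[, 3], all_m[, 4],
                        image1_size = image_size, image2_size = image_size),
    true_model = model, true_inlier_mask = mask, phi_true = phi,
    sigma = sigma, seed = as.integer(seed), camera = cam),
    class = "synthetic_scene")
}
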