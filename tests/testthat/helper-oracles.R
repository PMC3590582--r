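# Independent oracles and fixture builders, kept deliberately naive so they
# share no code path with the implementation under test.

# Max absolute elementwise difference after aligning two homogeneous 3x3
# models for scale and sign.
model_gap <- function(a, b) {
  a <- unclass(a) / sqrt(sum(unclass(a)^2))
  b <- unclass(b) / sqrt(sum(unclass(b)^2))
  if (sum(a * b) < 0) b <- -b
  max(abs(a - b))
}

# Straight-loop re-implementation of the relaxation iteration.
relax_reference <- function(P, cfg, radius) {
  df <- P$df
  n <- nrow(df)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d1 <- sqrt((df$x1[i] - df$x1[j])^2 + (df$y1[i] - df$y1[j])^2)
      d2 <- sqrt((df$x2[i] - df$x2[j])^2 + (df$y2[i] - df$y2[j])^2)
      md <- (d1 + d2) / 2
      if (md <= 0) next
      r <- abs(d1 - d2) / md
      if (r >= cfg$epsilon_r || d1 > radius) next
      W[i, j] <- exp(-r / cfg$epsilon_r) / (1 + d1 / radius)
    }
  }
  norm1 <- function(s) if (max(s) > 0) s / max(s) else s
  shat <- norm1(rowSums(W))
  for (k in seq_len(cfg$q_max)) {
    snew <- norm1(as.numeric(W %*% shat))
    delta <- max(abs(snew - shat))
    shat <- snew
    if (delta < cfg$convergence_tol) break
  }
  shat
}

# Matches consistent with a pure translation of both images, plus optional
# uniform-random outliers appended after them.
translation_matches <- function(n_inlier, n_outlier = 0, t = c(7, -3),
                                extent = 200, seed = 1) {
  set.seed(seed)
  x1 <- runif(n_inlier + n_outlier, 0, extent)
  y1 <- runif(n_inlier + n_outlier, 0, extent)
  x2 <- x1 + t[1]
  y2 <- y1 + t[2]
  if (n_outlier > 0) {
    bad <- n_inlier + seq_len(n_outlier)
    x2[bad] <- runif(n_outlier, 0, extent)
    y2[bad] <- runif(n_outlier, 0, extent)
  }
  match_set(x1, y1, x2, y2)
}

# Eigen-decomposition null-space oracle for the normalized 8-point solver:
# smallest eigenvector of t(A) %*% A on Hartley-normalized coordinates,
# denormalized, then the same rank-2 projection.
fm_8pt_oracle <- function(m) {
  h1 <- hartley_normalize(cbind(m$df$x1, m$df$y1))
  h2 <- hartley_normalize(cbind(m$df$x2, m$df$y2))
  u1 <- h1$points[, 1]; v1 <- h1$points[, 2]
  u2 <- h2$points[, 1]; v2 <- h2$points[, 2]
  A <- cbind(u2 * u1, u2 * v1, u2, v2 * u1, v2 * v1, v2, u1, v1, 1)
  AtA <- crossprod(A)
  f <- eigen(AtA, symmetric = TRUE)$vectors[, 9]
  # polish by shifted inverse iteration (squaring A's condition number in
  # t(A) %*% A costs precision on ill-conditioned samples)
  for (it in 1:2) {
    f <- solve(AtA + 1e-12 * sum(diag(AtA)) * diag(9), f)
    f <- f / sqrt(sum(f^2))
  }
  Fn <- matrix(f, 3, 3, byrow = TRUE)
  Fd <- t(h2$transform) %*% Fn %*% h1$transform
  sv <- svd(Fd)
  Fr <- sv$u %*% diag(c(sv$d[1], sv$d[2], 0)) %*% t(sv$v)
  Fr / sqrt(sum(Fr^2))
}

# Random nondegenerate 8-match sample from a noise-free synthetic scene.
random_8pt_sample <- function(seed) {
  sc <- generate_f_scene(n = 30, phi = 1, sigma = 0, seed = seed)
  ms_take(sc$matches, sample(seq_len(30), 8))
}

# Row subset of a match_set (test-side convenience).
ms_take <- function(m, idx) {
  d <- m$df[idx, , drop = FALSE]
  match_set(d$x1, d$y1, d$x2, d$y2, strength = d$strength, id = d$id,
            image1_size = m$image1_size, image2_size = m$image2_size)
}
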