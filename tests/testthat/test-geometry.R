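test_that("hartley normalization centres, scales and round-trips", {
  h <- hartley_normalize(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2)))
  expect_equal(colMeans(h$points), c(0, 0), tolerance = 1e-12)
  expect_equal(mean(sqrt(rowSums(h$points^2))), sqrt(2), tolerance = 1e-12)

  set.seed(42)
  pts <- matrix(runif(40, -50, 400), 20, 2)
  h <- hartley_normalize(pts)
  # applying the transform reproduces the outputs; inverting recovers inputs
  hom <- t(h$transform %*% t(cbind(pts, 1)))
  expect_lt(max(abs(hom[, 1:2] - h$points)), 1e-12)
  back <- t(solve(h$transform) %*% t(cbind(h$points, 1)))
  expect_lt(max(abs(back[, 1:2] - pts)), 1e-12)

  expect_error(hartley_normalize(rbind(c(5, 5), c(5, 5))),
               class = "relaxransac_degenerate_configuration")
})

test_that("8-point solver recovers the rectified-stereo fundamental matrix", {
  # y2 = y1 for generic points forces F to the rectified form
  set.seed(7)
  x1 <- runif(8, 0, 100); y1 <- runif(8, 0, 100)
  m <- match_set(x1, y1, x2 = runif(8, 0, 100), y2 = y1)
  Fm <- estimate_fundamental_8pt(m)
  F_expect <- matrix(c(0, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE)
  expect_lt(model_gap(Fm, F_expect), 1e-8)
})

test_that("8-point solver interpolates noise-free projections of a camera pair", {
  sc <- generate_f_scene(n = 30, phi = 1, sigma = 0, seed = 11)
  m <- ms_take(sc$matches, 1:8)
  Fm <- estimate_fundamental_8pt(m)
  prod_epi <- vapply(1:8, function(i) {
    abs(sum(c(m$df$x2[i], m$df$y2[i], 1) *
            (unclass(Fm) %*% c(m$df$x1[i], m$df$y1[i], 1))))
  }, numeric(1))
  expect_lt(max(prod_epi), 1e-9)
  expect_lt(model_gap(Fm, sc$true_model), 1e-6)
})

test_that("collinear image-1 points are rejected as degenerate", {
  m <- match_set(x1 = 1:8, y1 = 2 * (1:8) + 3,
                 x2 = runif(8, 0, 100), y2 = runif(8, 0, 100))
  expect_error(estimate_fundamental_8pt(m),
               class = "relaxransac_degenerate_sample")
  expect_error(estimate_fundamental_8pt(ms_take(m, 1:7)),
               class = "relaxransac_too_few_matches")
})

test_that("8-point solution matches the eigen-decomposition null-space oracle", {
  for (seed in 1:10) {
    m <- random_8pt_sample(seed)
    Fm <- estimate_fundamental_8pt(m)
    expect_lt(model_gap(Fm, fm_8pt_oracle(m)), 1e-8)
    sv <- svd(unclass(Fm))$d
    expect_lt(sv[3], 1e-10 * sv[1])  # rank-2 constraint
  }
})

test_that("DLT recovers identity, translation and a random projective map", {
  sq <- list(x = c(0, 10, 0, 10), y = c(0, 0, 10, 10))
  m_id <- match_set(sq$x, sq$y, sq$x, sq$y)
  expect_lt(model_gap(estimate_homography_dlt(m_id), diag(3)), 1e-10)

  m_tr <- match_set(sq$x, sq$y, sq$x + 7, sq$y - 3)
  H_tr <- matrix(c(1, 0, 7, 0, 1, -3, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_lt(model_gap(estimate_homography_dlt(m_tr), H_tr), 1e-9)

  set.seed(3)
  H_true <- diag(3) + matrix(rnorm(9, sd = 0.1), 3, 3)
  p <- cbind(runif(4, 0, 100), runif(4, 0, 100), 1)
  q <- t(H_true %*% t(p))
  q <- q[, 1:2] / q[, 3]
  m_rand <- match_set(p[, 1], p[, 2], q[, 1], q[, 2])
  expect_lt(model_gap(estimate_homography_dlt(m_rand), H_true), 1e-9)

  m_coll <- match_set(c(0, 1, 2, 5), c(0, 1, 2, 9), sq$x, sq$y)
  expect_error(estimate_homography_dlt(m_coll),
               class = "relaxransac_degenerate_sample")
})

test_that("Sampson distance matches hand-computed values and is scale invariant", {
  F_rect <- matrix(c(0, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE)
  on_line <- match_set(5, 3, 9, 3)
  expect_equal(sampson_distance(F_rect, on_line), 0)
  off_line <- match_set(0, 0, 0, 1)
  expect_equal(sampson_distance(F_rect, off_line), 1 / sqrt(2),
               tolerance = 1e-12)
  # canonicalization makes the distance invariant to the scale of F
  expect_equal(sampson_distance(10 * F_rect, off_line),
               sampson_distance(F_rect, off_line))
})

test_that("Sampson distance is zero exactly on the epipolar constraint", {
  sc <- generate_f_scene(n = 40, phi = 0.5, sigma = 1, seed = 5)
  d <- sampson_distance(sc$true_model, sc$matches)
  epi <- vapply(seq_len(40), function(i) {
    sum(c(sc$matches$df$x2[i], sc$matches$df$y2[i], 1) *
        (unclass(sc$true_model) %*% c(sc$matches$df$x1[i], sc$matches$df$y1[i], 1)))
  }, numeric(1))
  expect_equal(d == 0, abs(epi) < 1e-14)
  expect_true(all(d >= 0))
})

test_that("transfer error matches hand-computed values", {
  H_id <- diag(3)
  expect_equal(transfer_error(H_id, match_set(3, 4, 3, 4)), 0)
  H_tr <- matrix(c(1, 0, 7, 0, 1, -3, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_equal(transfer_error(H_tr, match_set(0, 0, 7, -3)), 0,
               tolerance = 1e-12)
  expect_equal(transfer_error(H_tr, match_set(0, 0, 8, -3)), 1,
               tolerance = 1e-12)
})

test_that("inlier classification equals per-point residual thresholding", {
  empty <- match_set(numeric(0), numeric(0), numeric(0), numeric(0))
  sc0 <- generate_f_scene(n = 20, phi = 1, sigma = 0, seed = 2)
  expect_length(classify_inliers(sc0$true_model, empty, 1), 0)
  expect_true(all(classify_inliers(sc0$true_model, sc0$matches, 1)))

  sc <- generate_f_scene(n = 100, phi = 0.5, sigma = 1, seed = 9)
  mask <- classify_inliers(sc$true_model, sc$matches, 1.5)
  manual <- vapply(seq_len(100), function(i) {
    sampson_distance(sc$true_model, ms_take(sc$matches, i)) <= 1.5
  }, logical(1))
  expect_identical(mask, manual)
})

test_that("estimation is equivariant under a common coordinate scaling", {
  k <- 3.7
  S <- diag(c(k, k, 1))
  m <- random_8pt_sample(21)
  Fm <- estimate_fundamental_8pt(m)
  ms <- match_set(k * m$df$x1, k * m$df$y1, k * m$df$x2, k * m$df$y2)
  Fs <- estimate_fundamental_8pt(ms)
  expect_lt(model_gap(Fs, solve(t(S)) %*% unclass(Fm) %*% solve(S)), 1e-6)

  sq <- match_set(c(0, 10, 0, 10), c(0, 0, 10, 10),
                  c(1, 12, 0.5, 11), c(2, 1, 11, 12))
  Hm <- estimate_homography_dlt(sq)
  sqs <- match_set(k * sq$df$x1, k * sq$df$y1, k * sq$df$x2, k * sq$df$y2)
  Hs <- estimate_homography_dlt(sqs)
  expect_lt(model_gap(Hs, S %*% unclass(Hm) %*% solve(S)), 1e-6)
})

test_that("model matrices round-trip through text files at full precision", {
  m <- random_8pt_sample(33)
  Fm <- estimate_fundamental_8pt(m)
  path <- withr::local_tempfile(fileext = ".txt")
  write_model(Fm, path)
  expect_length(readLines(path), 3)
  back <- read_model(path, "fundamental")
  expect_equal(unclass(back), unclass(Fm), tolerance = 1e-15)
  expect_s3_class(back, "fundamental_matrix")
})
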