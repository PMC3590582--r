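# textured test image: smoothed uniform noise, values in [0, 1]
textured_image <- function(nr = 64, nc = 64, seed = 1) {
  set.seed(seed)
  img <- matrix(runif(nr * nc), nr, nc)
  k <- relaxransac:::gaussian_kernel_1d(1)
  img <- relaxransac:::convolve_sep(img, k)
  (img - min(img)) / (max(img) - min(img))
}

square_image <- function(nr = 64, nc = 64, from = 21, to = 45) {
  img <- matrix(0, nr, nc)
  img[from:to, from:to] <- 1
  img
}

test_that("harris finds no corners in a constant image and 4 in a square", {
  expect_equal(nrow(harris_corners(matrix(0.5, 32, 32))), 0)

  img <- square_image()
  pts <- harris_corners(img, harris_config(max_corners = 4))
  expect_equal(nrow(pts), 4)
  # 0-based corner positions of the white square
  truth <- rbind(c(20, 20), c(44, 20), c(20, 44), c(44, 44))
  d <- vapply(seq_len(4), function(i) {
    min(sqrt((pts$x - truth[i, 1])^2 + (pts$y - truth[i, 2])^2))
  }, numeric(1))
  expect_lt(max(d), 2)
})

test_that("harris corners map onto themselves under a 90-degree rotation", {
  img <- square_image(from = 11, to = 31)  # off-centre square
  rot <- t(img[nrow(img):1, ])             # 90-degree rotation
  p0 <- harris_corners(img, harris_config(max_corners = 4))
  p1 <- harris_corners(rot, harris_config(max_corners = 4))
  # (x, y) -> (nrow - 1 - y, x) under this rotation
  mapped <- cbind(nrow(img) - 1 - p0$y, p0$x)
  d <- vapply(seq_len(nrow(p1)), function(i) {
    min(sqrt((mapped[, 1] - p1$x[i])^2 + (mapped[, 2] - p1$y[i])^2))
  }, numeric(1))
  expect_lt(max(d), 1)
})

test_that("NCC matching is one-to-one, exact on identical and shifted images", {
  img <- textured_image()
  pts <- harris_corners(img, harris_config(max_corners = 30))
  self <- ncc_match(img, pts, img, pts)
  expect_gt(n_matches(self), 0)
  expect_equal(self$df$x1, self$df$x2)
  expect_equal(self$df$y1, self$df$y2)
  expect_true(all(abs(self$df$strength - 1) < 1e-12))
  expect_false(any(duplicated(cbind(self$df$x2, self$df$y2))))

  # integer shift by (dx, dy) = (3, 5)
  dx <- 3; dy <- 5
  nr <- nrow(img); nc <- ncol(img)
  img2 <- matrix(0, nr, nc)
  img2[(1 + dy):nr, (1 + dx):nc] <- img[1:(nr - dy), 1:(nc - dx)]
  pts2 <- data.frame(x = pts$x + dx, y = pts$y + dy)
  m <- ncc_match(img, pts, img2, pts2)
  expect_gt(n_matches(m), 0)
  expect_true(all(m$df$x2 - m$df$x1 == dx))
  expect_true(all(m$df$y2 - m$df$y1 == dy))
})

test_that("NCC skips constant patches and ignores affine intensity changes", {
  img <- textured_image(seed = 3)
  img[1:24, 1:24] <- 0.5  # flat region
  hc <- harris_corners(img, harris_config(max_corners = 10))
  pts <- rbind(data.frame(x = 11, y = 11),                 # inside flat block
               hc[, c("x", "y")])
  expect_message(m <- ncc_match(img, pts, img, pts),
                 class = "relaxransac_flat_patch")
  expect_false(any(m$df$x1 == 11 & m$df$y1 == 11))

  img_affine <- 0.6 * img + 0.3
  m2 <- suppressMessages(ncc_match(img, pts, img_affine, pts))
  expect_equal(m2$df[, c("x1", "y1", "x2", "y2")],
               suppressMessages(ncc_match(img, pts, img, pts))$df[, c("x1", "y1", "x2", "y2")])
})

test_that("PGM, PNG and TIFF readers agree on the same 8-bit payload", {
  img8 <- matrix(as.integer(seq(0, 255, length.out = 48)), 6, 8)
  p2 <- withr::local_tempfile(fileext = ".pgm")
  writeLines(c("P2", "# comment", "8 6", "255",
               paste(as.integer(t(img8)), collapse = " ")), p2)
  a <- read_gray_image(p2)
  expect_equal(dim(a), c(6, 8))
  expect_equal(a, img8 / 255, tolerance = 1e-12)

  p5 <- withr::local_tempfile(fileext = ".pgm")
  con <- file(p5, "wb")
  writeChar("P5\n8 6\n255\n", con, eos = NULL)
  writeBin(as.integer(t(img8)), con, size = 1)
  close(con)
  expect_equal(read_gray_image(p5), a, tolerance = 1e-12)

  pp <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img8 / 255, pp)
  expect_equal(read_gray_image(pp), a, tolerance = 1e-2)

  tf <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(img8 / 255, tf)
  expect_equal(read_gray_image(tf), a, tolerance = 1e-2)

  expect_error(read_gray_image("foo.xyz"), class = "relaxransac_io_error")
})

test_that("correspondence tables round-trip and accept commas", {
  m <- translation_matches(10, 2, seed = 9)
  m$df$strength <- seq(0.1, 1.2, length.out = 12)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_matches(m, tsv)
  expect_match(readLines(tsv, n = 1), "^x1\\ty1\\tx2\\ty2\\tstrength$")
  back <- read_matches(tsv)
  expect_equal(back$df[, 2:6], m$df[, 2:6], tolerance = 1e-12)

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x1,y1,x2,y2", "1,2,3,4", "5,6,7,8"), csv)
  mc <- read_matches(csv)
  expect_equal(mc$df$x2, c(3, 7))
})
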