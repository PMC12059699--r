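test_that("Gaussian smoothing preserves constants, identity at scale 0, matches kernel oracle", {
  const <- matrix(7, 20, 20)
  expect_equal(smooth_image(const, 3), const)

  set.seed(1)
  img <- matrix(runif(400), 20, 20)
  expect_identical(smooth_image(img, 0), img)

  n <- 65
  imp <- matrix(0, n, n); imp[33, 33] <- 1
  sm <- smooth_image(imp, 2)
  r <- ceiling(4 * 2)
  k2 <- oracle_gaussian_kernel_2d(2, r)
  expect_lt(max(abs(sm[(33 - r):(33 + r), (33 - r):(33 + r)] - k2)), 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)

  expect_error(smooth_image(img, -1), "non-negative")
})

test_that("Otsu threshold separates two-valued images and is scale-equivariant", {
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  thr <- otsu_threshold(img)
  expect_gt(thr, 10)
  expect_lt(thr, 200)

  set.seed(7)
  m <- matrix(c(rnorm(500, 50, 10), rnorm(500, 200, 10)), 25, 40)
  t1 <- otsu_threshold(m)
  t2 <- otsu_threshold(m * 2)
  expect_equal(t2 / t1, 2, tolerance = 1e-9)

  expect_error(otsu_threshold(matrix(5, 4, 4)), "degenerate")
})

test_that("Otsu threshold equals the exhaustive between-class-variance scan", {
  set.seed(11)
  fixtures <- list(
    matrix(c(rnorm(500, 50, 10), rnorm(500, 200, 10)), 25, 40),
    matrix(runif(400, 0, 255), 20, 20),
    matrix(rexp(400, 1 / 40), 20, 20),
    matrix(c(rep(10, 380), rnorm(20, 180, 5)), 20, 20),
    matrix(c(rlnorm(300, 3, 0.4), rlnorm(100, 5, 0.2)), 20, 20))
  for (m in fixtures)
    expect_equal(otsu_threshold(m), oracle_otsu_scan(m))
})

test_that("threshold_mask area is non-increasing in the correction factor", {
  set.seed(3)
  img <- matrix(c(rnorm(300, 40, 8), rnorm(100, 150, 15)), 20, 20)
  img <- pmax(img, 0)
  areas <- vapply(c(0.5, 1, 1.5, 2), function(cf)
    sum(threshold_mask(img, threshold_spec("global", correction_factor = cf))), 0)
  expect_true(all(diff(areas) <= 0))
})

test_that("threshold_mask recovers a bright disk and warns into an empty mask on constants", {
  n <- 100
  truth <- disk_mask(n, 50, 50, 20)
  img <- matrix(10, n, n); img[truth] <- 120
  set.seed(5)
  img <- img + matrix(rnorm(n * n, 0, 2), n, n)
  mask <- threshold_mask(img, threshold_spec("global"))
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.95)
  expect_identical(dim(mask), dim(img))

  expect_warning(empty <- threshold_mask(matrix(4, 20, 20)), "constant")
  expect_false(any(empty))
})

test_that("adaptive thresholding recovers both disks under step illumination, global at most one", {
  n <- 200
  img <- matrix(0, n, n); img[, 101:200] <- 100
  img[20:40, 20:40] <- img[20:40, 20:40] + 50
  img[160:180, 160:180] <- img[160:180, 160:180] + 50
  adaptive <- threshold_mask(img, threshold_spec("adaptive", window = 50))
  global <- threshold_mask(img, threshold_spec("global"))
  rec <- function(m, rows, cols) mean(m[rows, cols])
  expect_gte(rec(adaptive, 20:40, 20:40), 0.9)
  expect_gte(rec(adaptive, 160:180, 160:180), 0.9)
  n_rec_global <- (rec(global, 20:40, 20:40) > 0.5) +
    (rec(global, 160:180, 160:180) > 0.5)
  expect_lte(n_rec_global, 1)
})

test_that("line enhancement scores ridges above blobs, is zero on constants and rotation-equivariant", {
  expect_true(all(enhance_line_structures(matrix(5, 30, 30), 10) == 0))

  line <- matrix(0, 80, 80); line[39:41, 10:70] <- 1
  disk <- matrix(0, 80, 80); disk[disk_mask(80, 40, 40, 15)] <- 1
  expect_gt(max(enhance_line_structures(line, 10)),
            max(enhance_line_structures(disk, 10)))

  set.seed(2)
  a <- matrix(runif(900), 30, 30)
  d <- rotate90(enhance_line_structures(a, 6)) -
    enhance_line_structures(rotate90(a), 6)
  expect_lt(max(abs(d[5:26, 5:26])), 1e-10)
})

test_that("Sobel magnitude is zero on constants, 4h on a step, transpose-symmetric", {
  expect_true(all(sobel_magnitude(matrix(3, 15, 15)) == 0))

  h <- 7
  img <- matrix(0, 20, 20); img[, 11:20] <- h
  sb <- sobel_magnitude(img)
  expect_equal(unname(sb[10, 10]), 4 * h)
  expect_equal(unname(sb[10, 11]), 4 * h)
  expect_equal(max(sb[5:15, 5:15]), 4 * h)

  set.seed(4)
  m <- matrix(runif(400), 20, 20)
  expect_equal(t(sobel_magnitude(m)), sobel_magnitude(t(m)))
})

test_that("object labelling counts, merges and fills holes as constructed", {
  m <- matrix(FALSE, 20, 20)
  m[2:5, 2:5] <- TRUE; m[10:14, 10:14] <- TRUE
  expect_equal(object_count(label_objects(m)), 2L)
  expect_equal(object_count(label_objects(m, merge_all = TRUE)), 1L)

  ring <- matrix(FALSE, 20, 20)
  d2 <- (row(ring) - 10)^2 + (col(ring) - 10)^2
  ring[d2 <= 36 & d2 > 9] <- TRUE
  hole_area <- sum(d2 <= 9)
  expect_lte(hole_area, 50)
  filled <- label_objects(ring, merge_all = TRUE, fill_hole_max = 50)
  expect_equal(sum(filled > 0), sum(ring) + hole_area)
  kept <- label_objects(ring, merge_all = TRUE, fill_hole_max = 10)
  expect_equal(sum(kept > 0), sum(ring))
})

test_that("labelling matches an independent flood-fill oracle on random masks", {
  for (seed in 1:8) {
    set.seed(seed)
    mask <- matrix(runif(625) < 0.35, 25, 25)
    expect_equal(object_count(label_objects(mask)), oracle_flood_count(mask))
  }
})

test_that("all operators are deterministic and geometry-preserving", {
  set.seed(9)
  img <- matrix(runif(600, 0, 100), 20, 30)
  expect_identical(smooth_image(img, 1.7), smooth_image(img, 1.7))
  expect_identical(unclass(threshold_mask(img)), unclass(threshold_mask(img)))
  for (out in list(smooth_image(img, 2), sobel_magnitude(img),
                   enhance_line_structures(img, 6),
                   threshold_mask(img), label_objects(img > 50)))
    expect_identical(dim(out), dim(img))
})
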