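test_that("nucleus segmentation finds simulated nuclei with high overlap", {
  sim <- make_nucleus_images(n_nuclei = 6, translocation = 0, seed = 3)
  labs <- segment_nuclei(sim$dapi)
  expect_equal(object_count(labs), 6L)
  for (k in 1:6) {
    truth <- sim$truth$nucleus_labels == k
    best <- max(vapply(seq_len(object_count(labs)), function(j)
      sum(truth & labs == j) / sum(truth | labs == j), 0))
    expect_gte(best, 0.9)
  }

  expect_equal(object_count(suppressWarnings(segment_nuclei(matrix(3, 50, 50)))), 0L)

  # correction factor high enough to exceed the nuclei kills all objects
  img <- matrix(10, 80, 80); img[disk_mask(80, 40, 40, 15)] <- 20
  expect_equal(object_count(segment_nuclei(img, smoothing_scale = 0,
                                           correction_factor = 3)), 0L)
})

test_that("neuron-area segmentation covers the soma and resists gradient illumination", {
  sim <- make_nucleus_images(translocation = 0, seed = 4)
  tub <- sim$tubulin$pixels
  truth <- matrix(FALSE, nrow(tub), ncol(tub))
  for (k in which(sim$truth$neuronal))
    truth <- truth | disk_mask(nrow(tub), sim$truth$centers[k, 1],
                               sim$truth$centers[k, 2], 40)
  flat <- segment_neuron_area(tub)
  recall_flat <- sum(flat & truth) / sum(truth)
  expect_gte(recall_flat, 0.8)

  grad <- matrix(rep(seq(0, 20, length.out = ncol(tub)), each = nrow(tub)),
                 nrow(tub))
  shaded <- segment_neuron_area(tub + grad)
  recall_grad <- sum(shaded & truth) / sum(truth)
  expect_lt(abs(recall_flat - recall_grad), 0.05)

  expect_false(any(suppressWarnings(segment_neuron_area(matrix(1, 60, 60)))))
})

test_that("neuronal-nucleus filter applies the 50% overlap rule with ties retained", {
  labs <- label_map(matrix(0L, 20, 40))
  labs[2:5, 2:5] <- 1L       # fully inside
  labs[2:5, 30:33] <- 2L     # fully outside
  labs[10:13, 9:12] <- 3L    # exactly 50%: columns 9:10 in, 11:12 out
  neuron <- matrix(FALSE, 20, 40); neuron[, 1:10] <- TRUE
  kept <- filter_neuronal_nuclei(label_map(unclass(labs)), neuron)
  expect_equal(object_count(kept), 2L)
  expect_true(any(kept[2:5, 2:5] > 0))     # inside nucleus retained
  expect_true(any(kept[10:13, 9:12] > 0))  # boundary tie retained
  expect_false(any(kept[2:5, 30:33] > 0))  # outside nucleus dropped
})

test_that("nucleolus segmentation recovers inner disks and flags featureless nuclei", {
  n <- 100
  nucleus <- disk_mask(n, 50, 50, 30)
  labs <- label_map(matrix(as.integer(nucleus), n, n))
  npm1 <- matrix(5, n, n); npm1[nucleus] <- 50
  inner <- disk_mask(n, 50, 50, 8)
  npm1[inner] <- 200
  seg <- segment_nucleoli(npm1, labs)
  got <- unclass(seg$nucleoli) == 1L
  expect_gte(sum(got & inner) / sum(got | inner), 0.7)

  # two nucleoli merge into one object of roughly summed area
  npm2 <- matrix(5, n, n); npm2[nucleus] <- 50
  a <- disk_mask(n, 42, 42, 8); b <- disk_mask(n, 60, 60, 8)
  npm2[a | b] <- 200
  seg2 <- segment_nucleoli(npm2, labs)
  area <- sum(unclass(seg2$nucleoli) == 1L)
  expect_equal(area, sum(a | b), tolerance = 0.1)

  # uniform NPM1 inside the nucleus: nothing to segment, nucleus flagged
  npm3 <- matrix(0, n, n); npm3[nucleus] <- 80
  seg3 <- segment_nucleoli(npm3, labs)
  expect_equal(seg3$flagged, 1L)

  # the edge-based route also stays inside the nucleus
  seg4 <- segment_nucleoli(npm1, labs, method = "edge")
  expect_true(all(nucleus[unclass(seg4$nucleoli) == 1L]))
})

test_that("NPM1 ratio arithmetic, compartment containment and scale invariance hold", {
  n <- 60
  nucleus <- disk_mask(n, 30, 30, 20)
  nucleolus <- disk_mask(n, 30, 30, 6)

  uniform <- matrix(80, n, n)
  m1 <- npm1_ratio(uniform, nucleus, nucleolus)
  expect_equal(m1$ratio, 1.0)

  img <- matrix(0, n, n); img[nucleus] <- 50; img[nucleolus] <- 200
  m2 <- npm1_ratio(img, nucleus, nucleolus)
  expect_equal(m2$ratio, 0.25)
  expect_equal(m2$nucleolar_area + m2$nucleoplasm_area, sum(nucleus))

  m3 <- npm1_ratio(img * 7.3, nucleus, nucleolus)
  expect_equal(m3$ratio, m2$ratio, tolerance = 1e-12)

  expect_error(npm1_ratio(img, nucleolus, nucleus), "inside")
  invalid <- npm1_ratio(img, nucleus, matrix(FALSE, n, n))
  expect_false(invalid$valid)
})

test_that("measured ratio rises with simulated translocation and conserves nuclear NPM1", {
  medians <- c(); truths <- c()
  for (s in c(0, 0.5, 1)) {
    sim <- make_nucleus_images(translocation = s, seed = 11)
    run <- run_npm1_pipeline(sim$dapi, sim$tubulin, sim$npm1)
    ratios <- vapply(run$measurements, function(m) m$ratio, 0)
    medians <- c(medians, stats::median(ratios))
    truths <- c(truths, sim$truth$ratio)
    # both compartments non-empty for every measured cell
    for (m in run$measurements) {
      expect_gt(m$nucleolar_area, 0)
      expect_gt(m$nucleoplasm_area, 0)
    }
  }
  expect_true(all(diff(medians) > 0))
  expect_true(all(abs(medians / truths - 1) < 0.05))

  # integrated intensity recovered by the two compartments is conserved
  sim0 <- make_nucleus_images(translocation = 0, seed = 12)
  sim1 <- make_nucleus_images(translocation = 1, seed = 12)
  expect_equal(sim0$truth$total_npm1_noiseless, sim1$truth$total_npm1_noiseless,
               tolerance = 1e-12)
  run0 <- run_npm1_pipeline(sim0$dapi, sim0$tubulin, sim0$npm1)
  tot <- sum(vapply(run0$measurements, function(m)
    m$nucleolar_mean_intensity * m$nucleolar_area +
      m$nucleoplasm_mean_intensity * m$nucleoplasm_area, 0))
  expect_equal(tot, sim0$truth$total_npm1_noiseless, tolerance = 0.05)
})

test_that("group medians summarize per-cell ratios", {
  mk <- function(r, valid = TRUE)
    structure(list(image_id = "x", nucleus_label = 1L, nucleolar_area = 10,
                   nucleoplasm_area = 90, nucleolar_mean_intensity = 100,
                   nucleoplasm_mean_intensity = 100 * r, ratio = r,
                   valid = valid), class = "NucleusMeasurement")
  out <- summarize_npm1(list(mk(0.2), mk(0.4), mk(0.9)),
                        cell_line = rep("L", 3), condition = rep("A", 3))
  expect_equal(out$median_ratio, 0.4)

  single <- summarize_npm1(list(mk(0.7)), "L", "B")
  expect_equal(single$median_ratio, 0.7)

  expect_warning(summarize_npm1(list(mk(NA, valid = FALSE)), "L", "C"),
                 "omitted")
})
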