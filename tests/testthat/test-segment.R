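test_that("a blank image segments to nothing", {
  seg <- segment_nuclei(matrix(0, 64, 64), 0.2)
  expect_equal(nrow(seg$nuclei), 0)
  expect_true(all(seg$labels == 0))
})

test_that("well-separated synthetic nuclei are all recovered near truth", {
  sim <- default_sim()
  seg <- segment_nuclei(sim$field$channels$DAPI, sim$field$pixel_size_um)
  truth <- sim$truth$nuclei
  expect_equal(nrow(seg$nuclei), nrow(truth))
  d <- sqrt(outer(seg$nuclei$x_um, truth$x_um, "-")^2 +
              outer(seg$nuclei$y_um, truth$y_um, "-")^2)
  nearest <- apply(d, 2, min)
  expect_lt(max(nearest), sim$field$pixel_size_um)  # within one pixel
})

test_that("aggressiveness controls the splitting of touching nuclei", {
  img <- make_disk_pair(r_px = 15, frac = 0.2)
  loose <- segmentation_params(aggressiveness = 0, min_nuclear_area_um2 = 1,
                               max_nuclear_area_um2 = 1e4, min_roundness = 0)
  split <- segmentation_params(aggressiveness = 0.5, min_nuclear_area_um2 = 1,
                               max_nuclear_area_um2 = 1e4, min_roundness = 0)
  expect_equal(nrow(segment_nuclei(img, 0.2, loose)$nuclei), 1)
  expect_equal(nrow(segment_nuclei(img, 0.2, split)$nuclei), 2)
})

test_that("more aggressiveness never yields fewer objects", {
  imgs <- list(make_disk_pair(), default_sim()$field$channels$DAPI)
  for (img in imgs) {
    counts <- vapply(c(0, 0.25, 0.5, 0.75, 0.95), function(a) {
      p <- segmentation_params(aggressiveness = a, min_nuclear_area_um2 = 1,
                               max_nuclear_area_um2 = 1e4, min_roundness = 0,
                               min_mean_intensity = 0)
      nrow(segment_nuclei(img, 0.2, p)$nuclei)
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("masks are disjoint and confined to above-threshold foreground", {
  sim <- default_sim()
  img <- sim$field$channels$DAPI
  params <- segmentation_params()
  seg <- segment_nuclei(img, sim$field$pixel_size_um, params)
  # a label matrix is disjoint by construction; check coverage instead
  thr <- 2 * params$contrast_threshold * EBImage::otsu(img, range = c(0, 1))
  expect_true(all(img[seg$labels > 0] > thr))
  expect_equal(sort(unique(as.vector(seg$labels))),
               c(0L, seg$nuclei$id))
})

test_that("morphometrics match closed forms on elementary shapes", {
  disk <- make_disk(20)
  m <- compute_morphometrics(disk, disk, 0.2)
  expect_gte(m$roundness, 0.9)
  expect_lte(m$roundness, 1.0)
  expect_equal(m$area_um2, sum(disk) * 0.04)

  sq <- matrix(0, 60, 60); sq[20:39, 20:39] <- 1
  m <- compute_morphometrics(sq, sq, 0.2)
  expect_lt(abs(m$roundness - pi / 4), 0.05)
  expect_equal(m$centroid_um, c(px_to_um(29.5, 0.2), px_to_um(29.5, 0.2)))

  px <- matrix(0, 5, 5); px[3, 3] <- 1
  expect_equal(compute_morphometrics(px, px, 0.2)$area_um2, 0.04)
})

test_that("degenerate segmentation inputs are rejected", {
  expect_error(segment_nuclei(array(0, c(4, 4, 2)), 0.2), "2-D")
  expect_error(segment_nuclei(matrix(0, 4, 4), 0), "positive")
  expect_error(compute_morphometrics(matrix(0, 4, 4), matrix(0, 4, 4), 0.2),
               "empty mask")
  expect_error(segmentation_params(min_nuclear_area_um2 = 10,
                                   max_nuclear_area_um2 = 5))
  expect_error(segmentation_params(aggressiveness = 1.5), "\\[0, 1\\]")
})
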