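# shared small phantom with airway + two lungs for this file
airway_phantom <- function(noise_sd = 0) {
  # vertical air tube reaching the top of the volume, inside a 0 HU body
  spec <- phantom_spec(
    shape = c(64, 64, 64), spacing = c(1.5, 1.5, 1.5),
    lungs = list(list(center = c(-22, 0, 0), semi = c(16, 28, 36)),
                 list(center = c(22, 0, 0), semi = c(16, 28, 36))),
    tubes = list(list(control_points = cbind(0, 0, c(46, -20)), radius = 2.2,
                      identity = "airway")),
    hu = list(parenchyma = -850, vessel = 300, airway = -1000, body = 0,
              noise_sd = noise_sd),
    seed = 5L)
  make_phantom(spec)
}

test_that("airway growing recovers the air tube from the auto seed", {
  ph <- airway_phantom()
  aw <- segment_airways(ph$volume)
  truth <- ph$airway_mask$labels == 3L
  pred <- aw$labels == 3L
  dice <- 2 * sum(truth & pred) / (sum(truth) + sum(pred))
  expect_gt(dice, 0.95)
  # volume against the generator's ground-truth rasterization
  expect_lt(abs(sum(pred) - sum(truth)) / sum(truth), 0.05)
})

test_that("a 2.0 mL airway is recovered within 5% of its analytic volume", {
  # capsule of radius 4 mm and axis length 34.7 mm (generator tubes carry
  # rounded end caps): pi r^2 L + 4/3 pi r^3 = 2012 mm^3 (2.0 mL), on a
  # 0.75 mm grid where rasterization error is small
  spec <- phantom_spec(
    shape = c(64, 64, 80), spacing = c(0.75, 0.75, 0.75),
    lungs = list(),
    tubes = list(list(control_points = cbind(0, 0, c(17.35, -17.35)),
                      radius = 4, identity = "airway")),
    hu = list(parenchyma = -850, vessel = 300, airway = -1000, body = 0,
              noise_sd = 10),
    seed = 6L)
  ph <- make_phantom(spec)
  aw <- segment_airways(ph$volume)
  vol_mL <- sum(aw$labels == 3L) * prod(ph$volume$spacing) * 1e-3
  analytic_mL <- (pi * 4^2 * 34.7 + 4 / 3 * pi * 4^3) * 1e-3
  expect_lt(abs(vol_mL - analytic_mL) / analytic_mL, 0.05)
})

test_that("a uniform volume yields a segmentation-failure signal", {
  v <- ct_volume(array(0, c(16, 16, 16)), spacing = c(1, 1, 1))
  expect_error(segment_airways(v),
               class = "pulmovasc_segmentation_failure")
  res <- process_scan(v)
  expect_identical(res$status, "segmentation-failed")
})

test_that("lungs are segmented with correct volume and laterality", {
  ph <- airway_phantom(noise_sd = 20)
  aw <- segment_airways(ph$volume)
  lm <- segment_lungs(ph$volume, aw)
  truth_L <- ph$lungs$lung_volume_L
  expect_lt(abs(lm$lung_volume_L - truth_L) / truth_L, 0.05)
  # left lung (smaller world x) coded 1, right coded 2
  idx1 <- which(lm$lung_mask$labels == 1L, arr.ind = TRUE)
  idx2 <- which(lm$lung_mask$labels == 2L, arr.ind = TRUE)
  expect_lt(mean(idx1[, 1]), mean(idx2[, 1]))
  # masks disjoint from the airway
  expect_equal(sum(lm$lung_mask$labels != 0L & aw$labels != 0L), 0)
})

test_that("mirroring the volume swaps the left/right lung codes", {
  ph <- airway_phantom()
  aw <- segment_airways(ph$volume)
  lm <- segment_lungs(ph$volume, aw)
  flip <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
  vm <- ct_volume(flip(ph$volume$data), spacing = ph$volume$spacing,
                  origin = ph$volume$origin)
  awm <- mask_volume(flip(aw$labels), spacing = aw$spacing, origin = aw$origin)
  lmm <- segment_lungs(vm, awm)
  expect_equal(sum(lmm$lung_mask$labels == 1L), sum(lm$lung_mask$labels == 2L))
  expect_equal(sum(lmm$lung_mask$labels == 2L), sum(lm$lung_mask$labels == 1L))
  expect_equal(lmm$lung_volume_L, lm$lung_volume_L)
})

test_that("a single lung-like component is labelled with a warning", {
  spec <- phantom_spec(
    shape = c(48, 48, 48), spacing = c(1.5, 1.5, 1.5),
    lungs = list(list(center = c(-10, 0, 0), semi = c(14, 22, 28))),
    tubes = list(list(control_points = cbind(25, 0, c(34, 10)), radius = 2,
                      identity = "airway")),
    hu = list(parenchyma = -850, vessel = 300, airway = -1000, body = 0,
              noise_sd = 0),
    seed = 2L)
  ph <- make_phantom(spec)
  aw <- segment_airways(ph$volume)
  expect_warning(lm <- segment_lungs(ph$volume, aw), "one lung")
  expect_gt(lm$lung_volume_L, 0)
})

test_that("lung volume is voxel count times voxel volume, in litres", {
  lab <- array(0L, c(20, 20, 20))
  lab[2:11, 2:11, 2:11] <- 1L   # 1000 voxels
  m <- mask_volume(lab, spacing = c(2, 2, 2))
  model <- structure(list(lung_mask = m, airway_mask = NULL,
                          lung_volume_L = NA), class = "lung_model")
  expect_equal(lung_volume_litres(model), 1000 * 8 * 1e-6)
  # ground-truth identity on a generated phantom
  ph <- airway_phantom()
  n <- sum(ph$lungs$lung_mask$labels %in% c(1L, 2L))
  expect_equal(ph$lungs$lung_volume_L,
               n * prod(ph$volume$spacing) * 1e-6)
  # empty mask -> 0 with warning
  m0 <- mask_volume(array(0L, c(4, 4, 4)))
  expect_warning(v0 <- lung_volume_litres(m0), "empty")
  expect_equal(v0, 0)
})
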