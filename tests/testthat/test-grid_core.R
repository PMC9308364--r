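test_that("world/index conversions follow the voxel-center convention", {
  v <- volume_grid(array(0, c(4, 5, 6)), spacing = c(1.5, 1.5, 3), origin = c(10, -4, 2))
  expect_equal(as.numeric(index_to_world(c(0, 0, 0), v)), c(10, -4, 2))
  expect_equal(as.numeric(index_to_world(c(2, 1, 3), v)), c(13, -2.5, 11))
  expect_equal(as.numeric(world_to_index(c(13, -2.5, 11), v)), c(2, 1, 3))
})

test_that("constructors validate their invariants", {
  expect_error(volume_grid(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)), "positive")
  expect_error(volume_grid(matrix(0, 2, 2), c(1, 1, 1)), "3D")
  expect_error(roi_box(c(0, 0, 0), c(1, -1, 1)), "lower < upper")
  expect_error(label_map(array(3L, c(2, 2, 2)), c(1, 1, 1), legend = c("a")), "legend")
})

test_that("trilinear sampling reproduces voxel centers and interpolates midpoints", {
  set.seed(42)
  vals <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  v <- volume_grid(vals, spacing = c(2, 1, 3), origin = c(0, 0, 0))
  # grid-point reproduction, exactly
  idx <- as.matrix(expand.grid(0:3, 0:3, 0:3))
  w <- index_to_world(idx, v)
  expect_identical(sample_trilinear(v, w), vals[idx + 1])
  # midpoint of two voxels valued 0 and 10 -> 5
  v2 <- volume_grid(array(c(0, 10, rep(0, 6)), c(2, 2, 2))[, , , drop = FALSE],
                    spacing = c(1, 1, 1))
  expect_equal(sample_trilinear(v2, c(0.5, 0, 0)), 5)
  # constant cell -> the constant
  v3 <- volume_grid(array(7, c(2, 2, 2)), c(1, 1, 1))
  expect_equal(sample_trilinear(v3, c(0.5, 0.5, 0.5)), 7)
  # out-of-bounds errors, no clamping
  expect_error(sample_trilinear(v, c(-1, 0, 0)), "outside")
  expect_error(sample_trilinear(v, c(0, 0, 9.1)), "outside")
})

test_that("resample_isotropic conserves extent, identity and constants", {
  set.seed(7)
  vals <- array(rnorm(6 * 8 * 4), c(6, 8, 4))
  v <- volume_grid(vals, spacing = c(1, 1, 1), origin = c(5, 5, 5))
  # identity: same spacing -> bitwise identical
  r <- resample_isotropic(v, 1, "trilinear")
  expect_identical(r$values, vals)
  expect_identical(r$origin, v$origin)
  # constant volume stays constant under any target spacing
  vc <- volume_grid(array(3.5, c(5, 7, 6)), spacing = c(1.5, 1.5, 3))
  rc <- resample_isotropic(vc, 1.1, "trilinear")
  expect_equal(max(abs(rc$values - 3.5)), 0, tolerance = 1e-12)
  # extent conserved within one output voxel per axis; dims = ceil(extent/t)
  v2 <- volume_grid(array(0, c(10, 12, 7)), spacing = c(1.5, 1.5, 3))
  for (t in c(0.8, 1, 2, 2.5)) {
    r2 <- resample_isotropic(v2, t)
    expect_identical(dim(r2$values), as.integer(ceiling(c(15, 18, 21) / t - 1e-9)))
    extent_out <- dim(r2$values) * t
    expect_true(all(abs(extent_out - c(15, 18, 21)) <= t + 1e-9))
  }
  expect_error(resample_isotropic(v, -1), "positive")
  expect_error(resample_isotropic(structure_mask(array(TRUE, c(2, 2, 2)), c(1, 1, 1)),
                                  1, "trilinear"), "nearest")
})

test_that("hand-computed linear interpolation case: 0/10 at 1 mm, midpoint -> 5", {
  v <- volume_grid(array(c(0, 10), c(2, 1, 1)), spacing = c(1, 1, 1))
  r <- resample_isotropic(v, 0.5, "trilinear")
  # output voxel at index 1 sits at world x = 0.5, the midpoint
  expect_equal(r$values[2, 1, 1], 5)
})

test_that("crop_to_roi retains exactly the voxel centers inside the half-open box", {
  v <- volume_grid(array(seq_len(100^2), c(100, 100, 1)), spacing = c(1, 1, 1))
  crop <- crop_to_roi(v, roi_box(c(30, 30, -0.5), c(70, 70, 0.5)))
  expect_identical(dim(crop$values), c(40L, 40L, 1L))
  expect_equal(crop$origin, c(30, 30, 0))
  # identity crop
  full <- crop_to_roi(v, roi_box(c(-0.5, -0.5, -0.5), c(99.5, 99.5, 0.5)))
  expect_identical(full$values, v$values)
  # box beyond the volume on one side: clipped, no padding
  part <- crop_to_roi(v, roi_box(c(90, 0, -0.5), c(200, 10, 0.5)))
  expect_identical(dim(part$values), c(10L, 10L, 1L))
  expect_equal(part$origin, c(90, 0, 0))
  # empty intersection errors
  expect_error(crop_to_roi(v, roi_box(c(500, 500, 500), c(600, 600, 600))), "empty ROI")
})

test_that("crop then re-embed at the recorded origin reproduces the voxels", {
  set.seed(3)
  v <- volume_grid(array(rnorm(20^3), c(20, 20, 20)), spacing = c(1.5, 1.5, 3))
  crop <- crop_to_roi(v, roi_box(c(4, 6, 9), c(20, 18, 40)))
  i0 <- round(as.numeric(world_to_index(crop$origin, v)))
  d <- dim(crop$values)
  re <- v$values[i0[1] + seq_len(d[1]), i0[2] + seq_len(d[2]), i0[3] + seq_len(d[3])]
  expect_identical(crop$values, re)
})

test_that("mask resampling is binary, preserves identity, and round-trips volume", {
  set.seed(5)
  occ <- array(runif(16^3) < 0.4, c(16, 16, 16))
  m <- structure_mask(occ, c(1, 1, 1), structure_name = "blob")
  # identity
  r <- resample_mask_to_grid(m, grid_meta(m))
  expect_identical(r$occupancy, occ)
  # binarity for arbitrary targets
  t2 <- list(dims = c(11L, 13L, 9L), spacing = c(1.4, 1.2, 1.9), origin = c(0.3, -1, 0.7))
  r2 <- resample_mask_to_grid(m, t2)
  expect_true(is.logical(r2$occupancy))
  # downsample then upsample a solid cube: volume within 5%
  cube <- cube_mask(c(40, 40, 40), c(1, 1, 1), c(5, 5, 5), c(34, 34, 34))
  down <- resample_isotropic(cube, 2, "nearest")
  back <- resample_mask_to_grid(down, grid_meta(cube))
  expect_lt(abs(volume_ml(back) - volume_ml(cube)) / volume_ml(cube), 0.05)
  # empty mask stays empty on any target
  e <- structure_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1))
  expect_false(any(resample_mask_to_grid(e, t2)$occupancy))
})

test_that("aggregate_masks applies priority and conserves voxel counts", {
  d <- c(10, 10, 3)
  a <- cube_mask(d, c(1, 1, 1), c(1, 1, 1), c(2, 5, 1), name = "A") # 10 voxels
  b <- cube_mask(d, c(1, 1, 1), c(5, 1, 1), c(8, 5, 1), name = "B") # 20 voxels
  lm <- aggregate_masks(list(a, b))
  expect_identical(as.integer(table(lm$labels[lm$labels > 0])), c(10L, 20L))
  expect_identical(lm$legend, c("A", "B"))
  # overlap: earliest in priority wins
  ov <- cube_mask(d, c(1, 1, 1), c(2, 1, 1), c(2, 5, 1), name = "B2") # overlaps A in 5
  lm2 <- aggregate_masks(list(a, ov), priority = c("A", "B2"))
  expect_equal(sum(lm2$labels == 1L), 10)
  expect_equal(sum(lm2$labels == 2L), sum(ov$occupancy) - 5)
  # voxel-count conservation: union counted once
  expect_equal(sum(lm2$labels > 0), sum(a$occupancy | ov$occupancy))
  # swapped priority
  lm3 <- aggregate_masks(list(a, ov), priority = c("B2", "A"))
  expect_equal(sum(lm3$labels == 1L), sum(ov$occupancy))
  # mismatched grids error
  shifted <- structure_mask(a$occupancy, c(1, 1, 1), origin = c(1, 0, 0), "A")
  expect_error(aggregate_masks(list(shifted, b)), "grid mismatch")
})

test_that("NIfTI round trip preserves grid metadata and values (LPS frame)", {
  skip_if_not_installed("RNifti")
  set.seed(9)
  v <- volume_grid(array(rnorm(5 * 6 * 7), c(5, 6, 7)), spacing = c(1.5, 1.5, 3),
                   origin = c(10, 20, -5))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(v, path)
  v2 <- read_volume(path)
  expect_equal(v2$spacing, v$spacing)
  expect_equal(v2$origin, v$origin)
  expect_equal(v2$values, v$values, tolerance = 1e-6)
  m <- structure_mask(array(runif(5 * 6 * 7) < 0.5, c(5, 6, 7)), c(1.5, 1.5, 3),
                      c(10, 20, -5), "heart")
  path2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(m, path2)
  m2 <- read_mask(path2, "heart")
  expect_identical(m2$occupancy, m$occupancy)
})

test_that("ROI JSON sidecar round trip", {
  boxes <- list(heart = roi_box(c(1, 2, 3), c(4, 5, 6)),
                bladder = roi_box(c(-10, 0, 5.5), c(0, 10, 20)))
  path <- withr::local_tempfile(fileext = ".json")
  write_roi_json(boxes, path)
  back <- read_roi_json(path)
  expect_equal(back$heart$lower, c(1, 2, 3))
  expect_equal(back$bladder$upper, c(0, 10, 20))
})
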