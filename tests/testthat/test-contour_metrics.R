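test_that("volume_ml is voxel count times voxel volume", {
  e <- structure_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1))
  expect_equal(volume_ml(e), 0)
  m1 <- cube_mask(c(10, 10, 10), c(1, 1, 1), c(1, 1, 1), c(10, 10, 10))
  expect_equal(volume_ml(m1), 1.0)
  m2 <- cube_mask(c(10, 10, 1), c(1, 1, 3), c(1, 1, 1), c(10, 10, 1))
  expect_equal(volume_ml(m2), 0.3)
})

test_that("overlap metrics match the hand-counted shifted-block case", {
  # 4x4x1 domain, man = 2x2 block, auto = man shifted one voxel in x
  man <- cube_mask(c(4, 4, 1), c(1, 1, 1), c(1, 1, 1), c(2, 2, 1), name = "man")
  auto <- cube_mask(c(4, 4, 1), c(1, 1, 1), c(2, 1, 1), c(3, 2, 1), name = "auto")
  om <- overlap_metrics(auto, man)
  expect_equal(om$sensitivity, 0.5)
  expect_equal(om$dice, 0.5)
  expect_equal(om$jaccard, 1 / 3)
  expect_equal(om$discordance, 0.5)
  expect_equal(om$gmi, 0.5)
  expect_equal(om$specificity, 10 / 12)
})

test_that("overlap metrics: identity and superset cases", {
  set.seed(21)
  m <- random_mask(c(8, 9, 5), c(1, 1.5, 2))
  om <- overlap_metrics(m, m)
  expect_equal(om$sensitivity, 1)
  expect_equal(om$dice, 1)
  expect_equal(om$jaccard, 1)
  expect_equal(om$discordance, 0)
  expect_equal(om$gmi, 0)
  # auto strictly contains man
  man <- cube_mask(c(12, 12, 12), c(1, 1, 1), c(4, 4, 4), c(8, 8, 8), name = "man")
  auto <- cube_mask(c(12, 12, 12), c(1, 1, 1), c(3, 3, 3), c(9, 9, 9), name = "auto")
  om2 <- overlap_metrics(auto, man)
  expect_equal(om2$sensitivity, 1)
  expect_equal(om2$gmi, 0)
  expect_gt(om2$discordance, 0)
})

test_that("empty masks make the affected metrics undefined, never silently 0", {
  e <- structure_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1))
  f <- cube_mask(c(4, 4, 4), c(1, 1, 1), c(2, 2, 2), c(3, 3, 3))
  expect_error(overlap_metrics(f, e), "sensitivity/GMI")
  expect_error(overlap_metrics(e, f), "discordance")
  expect_error(overlap_metrics(e, e), "undefined")
  expect_error(surface_distance_summary(surface_voxels(f), surface_voxels(e)),
               "undefined")
  # evaluate_pair records NA instead
  pm <- evaluate_pair(e, f)
  expect_equal(unname(pm["volume_auto_ml"]), 0)
  expect_equal(unname(pm["sensitivity"]), 0)
  expect_equal(unname(pm["dice"]), 0)
  expect_true(is.na(pm["discordance"]))
  expect_true(is.na(pm["msd_mm"]))
  expect_true(is.na(pm["volume_ratio"]))
  expect_true(is.na(pm["boundary_left_mm"]))
})

test_that("surface voxels follow the 6-connectivity convention", {
  # single voxel: all surface
  s1 <- structure_mask(array(c(rep(FALSE, 13), TRUE, rep(FALSE, 13)), c(3, 3, 3)),
                       c(1, 1, 1))
  expect_equal(nrow(surface_voxels(s1)$points), 1)
  # solid 3x3x3 cube: 26 surface voxels
  cube <- cube_mask(c(5, 5, 5), c(1, 1, 1), c(2, 2, 2), c(4, 4, 4))
  expect_equal(nrow(surface_voxels(cube)$points), 26)
  # one-voxel-thick slab: every voxel is surface
  slab <- cube_mask(c(6, 6, 3), c(1, 1, 1), c(1, 1, 2), c(6, 6, 2))
  expect_equal(nrow(surface_voxels(slab)$points), 36)
  # grid-boundary voxels count as surface
  full <- structure_mask(array(TRUE, c(3, 3, 3)), c(1, 1, 1))
  expect_equal(nrow(surface_voxels(full)$points), 26) # all but the center
})

test_that("directed distances: identity, single pair, minimum over candidates", {
  mk <- function(pts) structure(list(points = pts, voxels = NULL,
                                     structure_name = "s",
                                     meta = list(dims = NULL, spacing = NULL,
                                                 origin = NULL)),
                                class = "surface_points")
  s0 <- mk(matrix(c(0, 0, 0), 1))
  s1 <- mk(matrix(c(3, 0, 0), 1))
  s2 <- mk(rbind(c(2, 0, 0), c(4, 0, 0)))
  expect_equal(directed_distances(s0, s0), 0)
  expect_equal(directed_distances(s0, s1), 3)
  expect_equal(directed_distances(s0, s2), 2)
  expect_error(directed_distances(s0, mk(matrix(numeric(), 0, 3))), "empty")
})

test_that("surface distance summary matches the hand-evaluated example", {
  mk <- function(pts) structure(list(points = pts, voxels = NULL,
                                     structure_name = "s",
                                     meta = list(dims = NULL, spacing = NULL,
                                                 origin = NULL)),
                                class = "surface_points")
  s <- mk(matrix(c(0, 0, 0), 1))
  sp <- mk(rbind(c(2, 0, 0), c(4, 0, 0)))
  res <- surface_distance_summary(s, sp, percentile = 95)
  expect_equal(res$msd_mm, 8 / 3)
  expect_equal(res$rmsd_mm, sqrt(24 / 3))
  expect_equal(res$hd_mm, 4)
  expect_equal(res$hd_p_mm, 3.9) # linear-interpolation percentile of (2,4)
})

test_that("rigid translation along the surface normal gives msd = rmsd = hd = |t|", {
  # one-voxel-thick slab normal to x, translated 3 mm along x: every pointwise
  # nearest-surface distance equals the translation length
  slab <- cube_mask(c(40, 20, 20), c(1, 1, 1), c(10, 1, 1), c(10, 20, 20))
  shifted <- perturb_mask(slab, perturbation_spec(translation = c(3, 0, 0)))
  res <- surface_distance_summary(surface_voxels(slab), surface_voxels(shifted))
  expect_equal(res$msd_mm, 3)
  expect_equal(res$rmsd_mm, 3)
  expect_equal(res$hd_mm, 3)
  # for a solid translated cube the maximum (corner-to-corner) is still |t|
  cube <- cube_mask(c(40, 40, 40), c(1, 1, 1), c(10, 10, 10), c(30, 30, 30))
  moved <- perturb_mask(cube, perturbation_spec(translation = c(3, 0, 0)))
  expect_equal(surface_distance_summary(surface_voxels(cube),
                                        surface_voxels(moved))$hd_mm, 3)
})

test_that("centroid distance: identity, Pythagoras, symmetric dilation", {
  cube <- cube_mask(c(40, 40, 40), c(1, 1, 1), c(10, 10, 10), c(30, 30, 30))
  expect_equal(centroid_distance(cube, cube), 0)
  moved <- perturb_mask(cube, perturbation_spec(translation = c(3, 4, 0)))
  expect_equal(centroid_distance(moved, cube), 5)
  grown <- perturb_mask(cube, perturbation_spec(dilation_voxels = 1))
  expect_equal(centroid_distance(grown, cube), 0)
})

test_that("boundary differences follow the documented sign convention", {
  man <- cube_mask(c(20, 20, 20), c(1, 1, 1), c(1, 1, 1), c(10, 10, 10), name = "man")
  expect_equal(unname(boundary_differences(man, man)), rep(0, 6))
  # auto extends indices 0..11 in x where man spans 0..9 (+x = left)
  auto <- cube_mask(c(20, 20, 20), c(1, 1, 1), c(1, 1, 1), c(12, 10, 10), name = "auto")
  bd <- boundary_differences(auto, man)
  expect_equal(unname(bd["left"]), 2)
  expect_equal(unname(bd["right"]), 0)
  # translation +4 mm superiorly shifts both z extrema
  up <- perturb_mask(man, perturbation_spec(translation = c(0, 0, 4)))
  bd2 <- boundary_differences(up, man)
  expect_equal(unname(bd2["superior"]), 4)
  expect_equal(unname(bd2["inferior"]), 4)
  expect_equal(unname(bd2["left"]), 0)
})

test_that("evaluate_pair composes the per-operation results", {
  man <- cube_mask(c(4, 4, 1), c(1, 1, 1), c(1, 1, 1), c(2, 2, 1), name = "man")
  auto <- cube_mask(c(4, 4, 1), c(1, 1, 1), c(2, 1, 1), c(3, 2, 1), name = "auto")
  pm <- evaluate_pair(auto, man)
  expect_equal(unname(pm["dice"]), 0.5)
  expect_equal(unname(pm["jaccard"]), 1 / 3)
  expect_equal(unname(pm["specificity"]), 10 / 12)
  expect_equal(unname(pm["volume_man_ml"]), 0.004)
  expect_equal(unname(pm["volume_diff_ml"]), 0)
  expect_equal(unname(pm["volume_ratio"]), 1)
  expect_equal(unname(pm["centroid_distance_mm"]), 1)
  expect_equal(unname(pm["boundary_right_mm"]), 1)
  expect_equal(unname(pm["boundary_left_mm"]), 1)
  # identity pair
  id <- evaluate_pair(man, man)
  expect_equal(unname(id["dice"]), 1)
  expect_equal(unname(id[c("msd_mm", "rmsd_mm", "hd_mm", "hd95_mm",
                           "centroid_distance_mm")]), rep(0, 5))
})

test_that("accelerated metrics equal the brute-force oracle on random pairs", {
  set.seed(1234)
  for (rep in 1:12) {
    pair <- random_mask_pair(max_dim = 14)
    pm <- evaluate_pair(pair$auto, pair$man)
    or <- oracle_pair_metrics(pair$auto, pair$man)
    expect_equal(unname(pm["sensitivity"]), or$sensitivity)
    expect_equal(unname(pm["specificity"]), or$specificity)
    expect_equal(unname(pm["jaccard"]), or$jaccard)
    expect_equal(unname(pm["dice"]), or$dice)
    expect_equal(unname(pm["discordance"]), or$discordance)
    expect_equal(unname(pm["gmi"]), or$gmi)
    expect_equal(unname(pm["msd_mm"]), or$msd, tolerance = 1e-9)
    expect_equal(unname(pm["rmsd_mm"]), or$rmsd, tolerance = 1e-9)
    expect_equal(unname(pm["hd_mm"]), or$hd, tolerance = 1e-9)
    expect_equal(unname(pm["hd95_mm"]), or$hd_p, tolerance = 1e-9)
  }
})

test_that("metric identities and orderings hold on random pairs", {
  set.seed(99)
  for (rep in 1:15) {
    pair <- random_mask_pair(max_dim = 12)
    pm <- evaluate_pair(pair$auto, pair$man)
    expect_equal(unname(pm["dice"]), 2 * pm[["jaccard"]] / (1 + pm[["jaccard"]]),
                 tolerance = 1e-12)
    expect_equal(unname(pm["gmi"]), 1 - pm[["sensitivity"]], tolerance = 1e-12)
    expect_lte(pm[["msd_mm"]], pm[["rmsd_mm"]] + 1e-12)
    expect_lte(pm[["rmsd_mm"]], pm[["hd_mm"]] + 1e-12)
    expect_lte(pm[["hd95_mm"]], pm[["hd_mm"]] + 1e-12)
  }
})

test_that("symmetry and asymmetry relations under AUTO/MAN swap", {
  set.seed(7)
  for (rep in 1:8) {
    pair <- random_mask_pair(max_dim = 12)
    ab <- evaluate_pair(pair$auto, pair$man)
    ba <- evaluate_pair(pair$man, pair$auto)
    for (k in c("dice", "jaccard", "msd_mm", "rmsd_mm", "hd_mm"))
      expect_equal(unname(ab[k]), unname(ba[k]), tolerance = 1e-12)
    # sensitivity(auto, man) = 1 - discordance(man, auto)
    expect_equal(unname(ab["sensitivity"]), 1 - unname(ba["discordance"]),
                 tolerance = 1e-12)
  }
})

test_that("translation invariance and monotone response to nested dilations", {
  set.seed(31)
  pair <- random_mask_pair(max_dim = 10)
  pm <- evaluate_pair(pair$auto, pair$man)
  shift_mask <- function(m, dx) structure_mask(m$occupancy, m$spacing,
                                               m$origin + dx, m$structure_name)
  pm2 <- evaluate_pair(shift_mask(pair$auto, c(5, -3, 2)),
                       shift_mask(pair$man, c(5, -3, 2)))
  expect_equal(unname(pm2), unname(pm), tolerance = 1e-9)
  # nested dilations of man: sensitivity stays 1, discordance non-decreasing
  man <- cube_mask(c(20, 20, 20), c(1, 1, 1), c(8, 8, 8), c(13, 13, 13), name = "man")
  d1 <- perturb_mask(man, perturbation_spec(dilation_voxels = 1))
  d2 <- perturb_mask(man, perturbation_spec(dilation_voxels = 2))
  o1 <- overlap_metrics(d1, man)
  o2 <- overlap_metrics(d2, man)
  expect_equal(o1$sensitivity, 1)
  expect_equal(o2$sensitivity, 1)
  expect_gt(o2$discordance, o1$discordance)
})
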