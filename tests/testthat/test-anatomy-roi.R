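test_that("filled bone volume solidifies a hollow shaft and keeps the
           largest bone", {
  hs <- fixture("shaft_r12", make_structure_phantom(
    "hollow_shaft", spacing_mm = 0.3, outer_radius_mm = 12, wall_mm = 2,
    extent_mm = c(27, 27, 12)))
  f <- fill_bone_volume(hs$volume, 400)
  analytic <- pi * 12^2 * dim(hs$volume$values)[3] * 0.3 / 0.3^3
  expect_lt(abs(sum(f$mask) / analytic - 1), 0.02)

  # solid cube is already filled
  cube <- array(100, c(20, 20, 20))
  cube[5:15, 5:15, 5:15] <- 900
  vc <- density_volume(cube, 0.3, units = "mg_cc")
  fc <- fill_bone_volume(vc, 400, closing_radii_mm = 0.3)
  expect_equal(fc$mask, cube >= 400)

  # two disjoint bones: only the larger survives
  two <- array(100, c(30, 20, 20))
  two[3:16, 5:15, 5:15] <- 900          # large
  two[20:24, 8:12, 8:12] <- 900         # small
  vt <- density_volume(two, 0.3, units = "mg_cc")
  ft <- fill_bone_volume(vt, 400, closing_radii_mm = 0.3)
  expect_true(all(ft$mask[3:16, 5:15, 5:15]))
  expect_false(any(ft$mask[20:24, , ]))

  expect_error(fill_bone_volume(density_volume(array(0, c(5, 5, 5)), 1,
                                               units = "mg_cc"), 400),
               class = "bonemicro_segmentation_failure")
})

test_that("end plateau sits just proximal to the first holed slice", {
  tp <- tibia_run(0)$phantom
  f <- fill_bone_volume(tp$volume, 400)
  pl <- locate_end_plateau(f)
  expect_equal(pl, tp$truth$plateau_slice)

  # solid cylinder: no hole anywhere
  hs <- fixture("shaft_r12", make_structure_phantom(
    "hollow_shaft", spacing_mm = 0.3, outer_radius_mm = 12, wall_mm = 2,
    extent_mm = c(27, 27, 12)))
  f2 <- fill_bone_volume(hs$volume, 400)
  expect_error(locate_end_plateau(f2),
               class = "bonemicro_plateau_not_found")

  # hole at the very first traced (topmost) slice: proximal-neighbor rule
  # clamps to that slice
  d <- c(21L, 21L, 9L)
  m <- array(FALSE, d)
  for (k in 1:9) m[6:16, 6:16, k] <- TRUE
  m[9:13, 9:13, 9] <- FALSE   # enclosed 2D hole on the top slice
  expect_equal(locate_end_plateau(roi_mask(m, 0.3)), 9L)
})

test_that("tibial axis is recovered for aligned and tilted shafts", {
  tp0 <- tibia_run(0)$phantom
  f0 <- fill_bone_volume(tp0$volume, 400)
  fr0 <- fit_tibial_axis(f0, locate_end_plateau(f0),
                         tp0$truth$tibial_length_mm)
  expect_equal(unname(fr0$axis_direction), c(0, 0, 1), tolerance = 5e-3)
  expect_gte(fr0$axis_direction[3], 0)   # canonical distal-to-proximal

  tp1 <- tibia_run(10)$phantom
  f1 <- fill_bone_volume(tp1$volume, 400)
  fr1 <- fit_tibial_axis(f1, locate_end_plateau(f1),
                         tp1$truth$tibial_length_mm)
  ang <- acos(min(1, abs(sum(fr1$axis_direction *
                               tp1$truth$axis_direction)))) * 180 / pi
  expect_lt(ang, 1)
})

test_that("percent peel follows the distance-fraction rule and is
           monotone", {
  hs <- fixture("shaft_r12", make_structure_phantom(
    "hollow_shaft", spacing_mm = 0.3, outer_radius_mm = 12, wall_mm = 2,
    extent_mm = c(27, 27, 12)))
  f <- fill_bone_volume(hs$volume, 400)   # solid disk per slice
  expect_identical(compute_peel(f, 0)$mask, f$mask)

  p60 <- compute_peel(f, 60)
  # disk of radius R peeled at 60%: a disk of radius ~0.4 R, area ~0.16
  expect_lt(abs(sum(p60$mask) / sum(f$mask) - 0.16), 0.02)

  p100 <- compute_peel(f, 100)
  nz <- dim(f$mask)[3]
  expect_lte(sum(p100$mask), 5 * nz)   # at most the per-slice maxima

  # monotone nesting
  p30 <- compute_peel(f, 30)
  expect_true(all(p60$mask <= p30$mask))
  expect_true(all(p30$mask <= f$mask))
  expect_error(compute_peel(f, 140), class = "bonemicro_config")
})

test_that("axial ROIs honor site arithmetic and peel set algebra", {
  tp <- tibia_run(0)$phantom
  f <- fill_bone_volume(tp$volume, 400)
  pl <- locate_end_plateau(f)
  fr <- fit_tibial_axis(f, pl, tp$truth$tibial_length_mm)

  h <- tp$truth$spacing_mm
  band <- make_axial_roi(fr, f, c(4, 6), NULL)
  zs <- which(apply(band$mask, 3, any))
  # slab between 4% and 6% of tibial length above the plateau
  expect_equal(min(zs), pl + ceiling(0.04 * 100 / h))
  expect_equal(max(zs), pl + floor(0.06 * 100 / h))

  inner <- make_axial_roi(fr, f, c(4, 6), 60)
  outer <- make_axial_roi(fr, f, c(4, 6), c(30, 60))
  p30 <- compute_peel(band, 30)
  expect_equal(sum(inner$mask & outer$mask), 0L)     # disjoint
  expect_true(all((inner$mask | outer$mask) <= p30$mask))  # nested in 30%

  cb_band <- make_axial_roi(fr, f, c(14, 16), NULL)  # cortical site band
  expect_gt(sum(cb_band$mask), 0)
  expect_error(make_axial_roi(fr, f, c(60, 70), NULL),
               class = "bonemicro_empty_roi")
})

test_that("spherical ROI sampling is contained, deterministic, and spans
           47 voxels at the printed geometry", {
  d <- c(80L, 80L, 80L)
  region <- roi_mask(array(TRUE, d), 0.15)
  rois <- sample_spherical_rois(region, 3, 7.05, seed = 5)
  expect_length(rois, 3)
  for (r in rois) {
    expect_true(all(r$mask <= region$mask))
    idx <- which(r$mask, arr.ind = TRUE)
    expect_equal(max(idx[, 1]) - min(idx[, 1]) + 1L, 47L)
  }
  rois2 <- sample_spherical_rois(region, 3, 7.05, seed = 5)
  expect_identical(lapply(rois, `[[`, "mask"), lapply(rois2, `[[`, "mask"))
  expect_length(sample_spherical_rois(region, 0, 7.05), 0)
  small <- roi_mask(array(TRUE, c(10L, 10L, 10L)), 0.15)
  expect_error(sample_spherical_rois(small, 1, 7.05),
               class = "bonemicro_sampling")
})
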