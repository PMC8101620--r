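test_that("tensor scale recovers slab thickness, rod diameter and sphere
           radius", {
  h <- 0.15
  # slab: a3 ~ half thickness; in-plane axes capped at max scale for
  # voxels farther than the max scale from the lateral faces
  ps <- fixture("plate_stack_wide", make_structure_phantom(
    "plate_stack", extent_mm = c(10, 10, 6.4)))
  mem <- bone_membership(ps$volume, 100, 800)
  sk <- fuzzy_skeletonize(mem)
  ls <- tensor_scale_at(sk, mem, max_scale_mm = 3)
  d <- dim(mem$values)
  interior <- ls$table$x > 21 & ls$table$x < d[1] - 20 &
    ls$table$y > 21 & ls$table$y < d[2] - 20
  expect_lt(abs(median(ls$table$a3[interior]) - 0.15), 0.5 * h)
  expect_gt(mean(ls$table$capped[interior]), 0.85)

  # rod lattice: plate width ~ diameter within one voxel, measured over
  # whole rods (an interior box excludes rod fragments clipped by the
  # volume faces and axial rays truncated by the z cut planes)
  rl <- fixture("rod_lattice", make_structure_phantom("rod_lattice"))
  mem2 <- bone_membership(rl$volume, 100, 800)
  sk2 <- fuzzy_skeletonize(mem2)
  ls2 <- tensor_scale_at(sk2, mem2, max_scale_mm = 3)
  d2 <- dim(mem2$values)
  roi2 <- roi_mask(array(FALSE, d2), h)
  roi2$mask[8:(d2[1] - 7), 8:(d2[2] - 7), 22:(d2[3] - 21)] <- TRUE
  pw <- tb_pw(ls2, roi2)
  expect_lt(abs(pw - 450), 150)

  # sphere: all three semi-axes near the radius at the center
  sp <- make_structure_phantom("sphere", spacing_mm = h,
                               sphere_radius_mm = 1.2)
  mem3 <- bone_membership(sp$volume, 100, 800)
  sk3 <- fuzzy_skeletonize(mem3)
  ls3 <- tensor_scale_at(sk3, mem3, max_scale_mm = 3)
  ctr <- ls3$table[which.max(ls3$table$a3), ]
  expect_lt(abs(ctr$a1 - 1.2), 0.1)
  expect_lt(abs(ctr$a2 - 1.2), 0.1)
  expect_lt(abs(ctr$a3 - 1.2), 0.1)

  expect_error(tensor_scale_at(sk, mem, max_scale_mm = 0.05),
               class = "bonemicro_config")
})

test_that("plate/rod classification separates slabs from rods and is
           monotone in the threshold", {
  ps <- fixture("plate_stack_wide", make_structure_phantom(
    "plate_stack", extent_mm = c(10, 10, 6.4)))
  mem <- bone_membership(ps$volume, 100, 800)
  ls <- tensor_scale_at(fuzzy_skeletonize(mem), mem, 3)
  d <- dim(mem$values)
  interior <- ls$table$x > 21 & ls$table$x < d[1] - 20 &
    ls$table$y > 21 & ls$table$y < d[2] - 20
  expect_gt(mean(classify_plate_rod(ls)[interior] == "plate"), 0.9)

  rl <- fixture("rod_lattice", make_structure_phantom("rod_lattice"))
  mem2 <- bone_membership(rl$volume, 100, 800)
  ls2 <- tensor_scale_at(fuzzy_skeletonize(mem2), mem2, 3)
  expect_gt(mean(classify_plate_rod(ls2) == "rod"), 0.9)

  # plate fraction falls monotonically as the ratio threshold grows
  fr <- vapply(c(1.2, 2, 4, 1e6), function(t)
    mean(classify_plate_rod(ls, t) == "plate"), numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_equal(fr[4], 0)   # threshold -> infinity: everything rod
})

test_that("orientation classes follow the axis rule table and recover the
           generator mix", {
  h <- 0.15
  # vertical rod lattice: longitudinal
  rl <- fixture("rod_lattice", make_structure_phantom("rod_lattice"))
  mem <- bone_membership(rl$volume, 100, 800)
  ls <- tensor_scale_at(fuzzy_skeletonize(mem), mem, 3)
  ori <- classify_orientation(ls, c(0, 0, 1))
  expect_gt(mean(ori == "longitudinal"), 0.9)

  # the same lattice viewed with the axis along x: transverse
  ori_x <- classify_orientation(ls, c(1, 0, 0))
  expect_gt(mean(ori_x == "transverse"), 0.9)

  # mixed lattice: recovered transverse fraction within 10 points
  ml <- fixture("mixed_lattice", make_structure_phantom("mixed_lattice"))
  mem2 <- bone_membership(ml$volume, 100, 800)
  sk2 <- fuzzy_skeletonize(mem2)
  ls2 <- tensor_scale_at(sk2, mem2, 3)
  ori2 <- classify_orientation(ls2, c(0, 0, 1))
  expect_lt(abs(mean(ori2 == "transverse") - ml$truth$transverse_fraction),
            0.10)
})

test_that("density measures match brute-force oracles and mass
           accounting", {
  h <- 0.15
  d <- c(12L, 12L, 12L)
  set.seed(4)
  vals <- array(runif(prod(d), 0, 1000), d)
  v <- density_volume(vals, h, units = "mg_cc")
  roi <- box_roi(d, 2, h)
  expect_equal(tb_vbmd(v, roi), sum(vals[roi$mask]) / sum(roi$mask),
               tolerance = 1e-9)
  cst <- density_volume(array(500, d), h, units = "mg_cc")
  expect_equal(tb_vbmd(cst, roi), 500)
  expect_error(tb_vbmd(v, roi_mask(array(FALSE, d), h)),
               class = "bonemicro_empty_roi")

  # transverse density: zero without transverse voxels, equal to the
  # structural density when everything is transverse
  none <- roi_mask(array(FALSE, d), h)
  expect_equal(tb_tbmd(v, roi, none), 0)
  all_t <- roi_mask(array(TRUE, d), h)
  expect_equal(tb_tbmd(v, roi, all_t), tb_vbmd(v, roi), tolerance = 1e-9)

  # generator mass fraction recovered within 10%
  ml <- fixture("mixed_lattice", make_structure_phantom("mixed_lattice"))
  mem <- bone_membership(ml$volume, 100, 800)
  sk <- fuzzy_skeletonize(mem)
  ls <- tensor_scale_at(sk, mem, 3)
  ori <- classify_orientation(ls, c(0, 0, 1))
  tsup <- propagate_orientation(sk, mem, ori, "transverse")
  dd <- dim(mem$values)
  roi_all <- full_roi(dd, h)
  tb_t <- tb_tbmd(ml$volume, roi_all, tsup)
  struct_sup <- roi_mask(mem$values >= 0.5, h)
  tb_struct <- tb_tbmd(ml$volume, roi_all, struct_sup)
  expect_lt(abs(tb_t / tb_struct - ml$truth$transverse_fraction), 0.10)
  # mass subset invariant
  expect_lte(tb_t, tb_vbmd(ml$volume, roi_all))
})

test_that("plate width averaging behaves like a mean and is stable under
           quarter-turn rotation", {
  h <- 0.15
  # hand-built widths: constant and mixed
  d <- c(9L, 9L, 9L)
  sk <- mk_skeleton(array(c(TRUE), d), h)
  ls <- structure(list(
    table = tibble::tibble(x = sk$voxels$x, y = sk$voxels$y,
                           z = sk$voxels$z,
                           a1 = 1, a2 = 0.3, a3 = 0.1,
                           plate_width_mm = 0.6, capped = FALSE),
    dir1 = matrix(0, nrow(sk$voxels), 3),
    dir3 = matrix(0, nrow(sk$voxels), 3), max_scale_mm = 3),
    class = "local_structure")
  expect_equal(tb_pw(ls, full_roi(d, h)), 600)
  ls$table$plate_width_mm <- rep(c(0.3, 0.9), length.out = nrow(ls$table))
  expect_equal(tb_pw(ls, full_roi(d, h)),
               1000 * mean(ls$table$plate_width_mm))

  # quarter-turn rotation changes mean width by < 2%
  rl <- fixture("rod_lattice", make_structure_phantom("rod_lattice"))
  mem <- bone_membership(rl$volume, 100, 800)
  ls0 <- tensor_scale_at(fuzzy_skeletonize(mem), mem, 3)
  rotate_z90 <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , ]
  mem_r <- mk_membership(rotate_z90(mem$values), h)
  ls_r <- tensor_scale_at(fuzzy_skeletonize(mem_r), mem_r, 3)
  expect_lt(abs(mean(ls_r$table$plate_width_mm) /
                  mean(ls0$table$plate_width_mm) - 1), 0.02)
})
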