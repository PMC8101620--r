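shaft_segmented <- function() {
  fixture("porous_shaft_seg", {
    ph <- make_structure_phantom("hollow_shaft", spacing_mm = 0.15,
                                 outer_radius_mm = 6, wall_mm = 1.5,
                                 porosity = 0.15, extent_mm = c(15, 15, 12),
                                 seed = 4)
    f <- fill_bone_volume(ph$volume, 400)
    band <- roi_mask(f$mask, ph$volume$spacing, kind = "axial_band")
    list(phantom = ph,
         seg = segment_cortex(ph$volume, f, band, cortex_threshold = 600))
  })
}

test_that("cortical segmentation recovers the wall and its pores", {
  hs <- fixture("shaft_r12", make_structure_phantom(
    "hollow_shaft", spacing_mm = 0.3, outer_radius_mm = 12, wall_mm = 2,
    extent_mm = c(27, 27, 12)))
  f <- fill_bone_volume(hs$volume, 400)
  band <- roi_mask(f$mask, rep(0.3, 3), kind = "axial_band")
  seg <- segment_cortex(hs$volume, f, band, cortex_threshold = 600)
  nz <- dim(hs$volume$values)[3]
  analytic <- pi * (12^2 - 10^2) * nz * 0.3 / 0.3^3
  expect_lt(abs(sum(seg$cortex$mask) / analytic - 1), 0.02)

  # no density contrast: segmentation failure
  flat <- hs$volume; flat$values[] <- 100
  expect_error(segment_cortex(flat, f, band),
               class = "bonemicro_segmentation_failure")

  # generator-placed pores: at least 90% of pore voxels recovered
  ps <- shaft_segmented()
  pm <- ps$phantom$truth$pore_mask
  expect_gt(sum(ps$seg$pores$mask & pm) / sum(pm), 0.9)
})

test_that("cortical thickness matches analytic walls across radii and
           scales linearly", {
  for (R in c(8, 12, 15)) {
    hs <- if (R == 12) fixture("shaft_r12", make_structure_phantom(
      "hollow_shaft", spacing_mm = 0.3, outer_radius_mm = 12, wall_mm = 2,
      extent_mm = c(27, 27, 12)))
    else make_structure_phantom("hollow_shaft", spacing_mm = 0.3,
                                outer_radius_mm = R, wall_mm = 2,
                                extent_mm = c(2 * R + 3, 2 * R + 3, 9))
    f <- fill_bone_volume(hs$volume, 400)
    band <- roi_mask(f$mask, rep(0.3, 3), kind = "axial_band")
    seg <- segment_cortex(hs$volume, f, band, cortex_threshold = 600)
    expect_lt(abs(cortical_thickness(seg$cortex, seg$pores) - 2), 0.3)
  }
  # doubling the wall doubles the estimate
  hs4 <- make_structure_phantom("hollow_shaft", spacing_mm = 0.3,
                                outer_radius_mm = 12, wall_mm = 4,
                                extent_mm = c(27, 27, 9))
  f4 <- fill_bone_volume(hs4$volume, 400)
  seg4 <- segment_cortex(hs4$volume, f4,
                         roi_mask(f4$mask, rep(0.3, 3)), 600)
  expect_lt(abs(cortical_thickness(seg4$cortex, seg4$pores) - 4), 0.4)

  # wedge wall varying 1 -> 3 mm: mean near 2 mm
  h <- 0.2
  d <- as.integer(round(c(28, 28, 6) / h))
  x <- (seq_len(d[1]) - 1) * h; y <- (seq_len(d[2]) - 1) * h
  cx <- mean(range(x)); cy <- mean(range(y))
  theta <- outer(x - cx, y - cy, function(a, b) atan2(b, a))
  r2 <- outer((x - cx)^2, (y - cy)^2, "+")
  wall <- 2 + cos(theta)          # 1..3 mm
  ring <- sqrt(r2) <= 10 & sqrt(r2) >= 10 - wall
  vals <- array(100, d)
  vals[array(rep(ring, d[3]), d)] <- 1200
  v <- density_volume(vals, h, units = "mg_cc")
  fw <- fill_bone_volume(v, 400)
  segw <- segment_cortex(v, fw, roi_mask(fw$mask, rep(h, 3)), 600)
  expect_lt(abs(cortical_thickness(segw$cortex, segw$pores) - 2), 0.3)
})

test_that("cortical porosity matches the generator fraction and is
           rotation stable", {
  ps <- shaft_segmented()
  poro <- cortical_porosity(ps$seg$cortex, ps$seg$pores)
  expect_lt(abs(poro - ps$phantom$truth$porosity), 0.02)

  # no pores -> 0
  hs <- fixture("shaft_r12", make_structure_phantom(
    "hollow_shaft", spacing_mm = 0.3, outer_radius_mm = 12, wall_mm = 2,
    extent_mm = c(27, 27, 12)))
  f <- fill_bone_volume(hs$volume, 400)
  seg0 <- segment_cortex(hs$volume, f, roi_mask(f$mask, rep(0.3, 3)), 600)
  expect_equal(cortical_porosity(seg0$cortex, seg0$pores), 0)

  # porosity is monotone in the pore load
  ph_lo <- make_structure_phantom("hollow_shaft", spacing_mm = 0.15,
                                  outer_radius_mm = 6, wall_mm = 1.5,
                                  porosity = 0.05,
                                  extent_mm = c(15, 15, 12), seed = 4)
  f_lo <- fill_bone_volume(ph_lo$volume, 400)
  seg_lo <- segment_cortex(ph_lo$volume, f_lo,
                           roi_mask(f_lo$mask, rep(0.15, 3)), 600)
  expect_lt(cortical_porosity(seg_lo$cortex, seg_lo$pores), poro)

  # rigid rotation of the porous shaft moves porosity < 0.01
  ph_r <- make_structure_phantom("hollow_shaft", spacing_mm = 0.15,
                                 outer_radius_mm = 6, wall_mm = 1.5,
                                 porosity = 0.15, tilt_deg = 8,
                                 extent_mm = c(16.5, 15, 12), seed = 4)
  f_r <- fill_bone_volume(ph_r$volume, 400)
  seg_r <- segment_cortex(ph_r$volume, f_r,
                          roi_mask(f_r$mask, rep(0.15, 3)), 600)
  poro_r <- cortical_porosity(seg_r$cortex, seg_r$pores)
  expect_lt(abs(poro_r - poro), 0.01)
})
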