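test_that("density calibration recovers exact and noisy rod lines", {
  # identity mapping: rods at HU {0, 1000} with matching densities
  cp <- make_calibration_phantom(densities_mg_cc = c(0, 1000), slope = 1,
                                 intercept = 0)
  line <- fit_density_calibration(cp$volume, cp$spec)
  expect_equal(line$slope, 1, tolerance = 1e-10)
  expect_equal(line$intercept, 0, tolerance = 1e-8)

  # collinear rods on d = 0.8 HU + 50
  cp2 <- make_calibration_phantom(slope = 0.8, intercept = 50)
  line2 <- fit_density_calibration(cp2$volume, cp2$spec)
  expect_equal(line2$slope, 0.8, tolerance = 1e-10)
  expect_equal(line2$intercept, 50, tolerance = 1e-6)
  expect_equal(line2$r, 1, tolerance = 1e-12)

  # noisy rods: coefficients equal the closed-form normal-equation solution
  cp3 <- make_calibration_phantom(slope = 0.8, intercept = 50,
                                  noise_sd_hu = 8, seed = 11)
  line3 <- fit_density_calibration(cp3$volume, cp3$spec)
  x <- line3$rods$mean_hu
  y <- line3$rods$density_mg_cc
  slope_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept_oracle <- mean(y) - slope_oracle * mean(x)
  expect_equal(line3$slope, slope_oracle, tolerance = 1e-12)
  expect_equal(line3$intercept, intercept_oracle, tolerance = 1e-12)
  # OLS identity: the line passes through the centroid
  expect_equal(line3$intercept + line3$slope * mean(x), mean(y),
               tolerance = 1e-9)
})

test_that("calibration fitting rejects degenerate configurations", {
  cp <- make_calibration_phantom()
  expect_error(phantom_spec(matrix(c(5, 5), 1, 2), 3, 500),
               class = "bonemicro_config")
  expect_error(phantom_spec(cp$spec$centers_mm[1:2, ], 3, c(100, 100)),
               class = "bonemicro_config")
  # zero HU variance: two rods with identical HU
  flat <- cp$volume
  flat$values[] <- 100
  expect_error(fit_density_calibration(flat, cp$spec),
               class = "bonemicro_degenerate")
})

test_that("apply_calibration is an affine map that preserves geometry", {
  cp <- make_calibration_phantom()
  v <- cp$volume
  id <- list(slope = 1, intercept = 0)
  out <- apply_calibration(v, id)
  expect_equal(out$values, v$values)
  expect_equal(out$units, "mg_cc")
  expect_equal(out$spacing, v$spacing)
  expect_equal(dim(out), dim(v))

  cst <- density_volume(array(100, c(4, 4, 4)), 0.5, units = "HU")
  out2 <- apply_calibration(cst, list(slope = 2, intercept = 10))
  expect_true(all(out2$values == 210))

  # round trip through the inverse affine map
  cal <- list(slope = 0.8, intercept = 50)
  fwd <- apply_calibration(v, cal)
  back <- (fwd$values - cal$intercept) / cal$slope
  expect_equal(back, v$values, tolerance = 1e-12)

  expect_error(apply_calibration(fwd, cal), class = "bonemicro_unit")
})

test_that("windowed-sinc resampling reproduces constants, ramps and
           band-limited fields", {
  cst <- density_volume(array(7, c(12, 12, 12)), c(0.2, 0.3, 0.25),
                        units = "mg_cc")
  iso <- resample_isotropic(cst, 0.15)
  expect_equal(unname(iso$spacing), rep(0.15, 3))
  expect_true(max(abs(iso$values - 7)) < 1e-9)

  # already isotropic at the target: identity
  v0 <- density_volume(array(rnorm(8^3), c(8, 8, 8)), 0.15,
                       units = "mg_cc")
  expect_equal(resample_isotropic(v0, 0.15)$values, v0$values,
               tolerance = 1e-6)

  # physical extent preserved within one voxel
  ext_in <- (dim(cst)[1:3] - 1) * cst$spacing
  ext_out <- (dim(iso)[1:3] - 1) * iso$spacing
  expect_true(all(abs(ext_in - ext_out) <= 0.15 + 1e-9))

  # unit linear ramp: analytic values away from the window-truncated edges
  arr <- array(rep(seq(0, 1, length.out = 40), times = 20 * 20),
               c(40, 20, 20))
  vr <- density_volume(arr, c(0.2, 0.3, 0.3), units = "mg_cc")
  ir <- resample_isotropic(vr, 0.15)
  xout <- (seq_len(dim(ir)[1]) - 1) * 0.15
  analytic <- xout / (39 * 0.2)
  n <- length(xout)
  expect_lt(max(abs(ir$values[5:(n - 4), 10, 10] - analytic[5:(n - 4)])),
            1e-3)

  # band-limited sinusoid (period 2 mm at 0.2 mm sampling)
  x <- (0:39) * 0.2
  s <- array(rep(sin(2 * pi * x / 2), times = 400), c(40, 20, 20))
  vs <- density_volume(s, c(0.2, 0.3, 0.3), units = "mg_cc")
  is2 <- resample_isotropic(vs, 0.15)
  analytic2 <- sin(2 * pi * xout / 2)
  expect_lt(max(abs(is2$values[5:(n - 4), 10, 10] - analytic2[5:(n - 4)])),
            0.01)

  expect_error(resample_isotropic(cst, -1), class = "bonemicro_config")
})
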