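# Synthetic phantom generators. All geometry is evaluated in continuous
# coordinates and voxelized with subvoxel supersampling (occupancy
# fractions), so boundary voxels carry partial-volume densities the way
# band-limited CT reconstructions do; the fuzzy membership of a phantom is
# then an honest fuzzy representation, not a binary mask.

# separable Gaussian blur (truncated at 3 sigma, renormalized); emulates
# the finite resolution of the scanner so phantoms are band-limited
gaussian_blur <- function(arr, sigma_mm, spacing) {
  if (sigma_mm <= 0) return(arr)
  for (ax in 1:3) {
    h <- spacing[ax]
    r <- max(1L, ceiling(3 * sigma_mm / h))
    w <- exp(-0.5 * ((-r:r) * h / sigma_mm)^2)
    w <- w / sum(w)
    n <- dim(arr)[ax]
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      idx <- pmin(pmax(i + (-r:r), 1L), n)   # replicate edges
      for (k in seq_along(idx)) W[i, idx[k]] <- W[i, idx[k]] + w[k]
    }
    arr <- apply_axis(arr, ax, W)
  }
  arr
}

# occupancy fraction of a predicate over each voxel: mean over aa^3
# subvoxel offsets. `coords(dx,dy,dz)` returns shifted coordinate arrays.
occupancy <- function(pred, coords, aa) {
  if (aa <= 1) return(pred(coords(0, 0, 0)) + 0)
  off <- (seq_len(aa) - (aa + 1) / 2) / aa
  acc <- NULL
  for (dx in off) for (dy in off) for (dz in off) {
    v <- pred(coords(dx, dy, dz))
    acc <- if (is.null(acc)) v + 0 else acc + v
  }
  acc / aa^3
}

# occupancy of a union of spheres given in shaft-frame coordinates,
# evaluated only on per-sphere bounding boxes (lab frame). Rmat maps lab
# to shaft frame about `ctr`: q = Rmat (p - ctr) + ctr.
stamp_spheres <- function(d, h, centers_q, r, Rmat, ctr, aa) {
  occ <- array(0, d)
  off <- if (aa <= 1) 0 else (seq_len(aa) - (aa + 1) / 2) / aa * h
  for (i in seq_len(nrow(centers_q))) {
    cq <- centers_q[i, ]
    clab <- drop(t(Rmat) %*% (cq - ctr)) + ctr
    lo <- pmax(1L, as.integer(floor((clab - r - h) / h)) + 1L)
    hi <- pmin(d, as.integer(ceiling((clab + r + h) / h)) + 1L)
    if (any(lo > hi)) next
    rngs <- lapply(1:3, function(a) lo[a]:hi[a])
    pts <- as.matrix(expand.grid(x = (rngs[[1]] - 1) * h,
                                 y = (rngs[[2]] - 1) * h,
                                 z = (rngs[[3]] - 1) * h))
    frac <- numeric(nrow(pts))
    for (dx in off) for (dy in off) for (dz in off) {
      q <- sweep(sweep(pts, 2, ctr - c(dx, dy, dz), "-") %*% t(Rmat), 2,
                 ctr, "+")
      frac <- frac + (rowSums(sweep(q, 2, cq, "-")^2) <= r^2)
    }
    frac <- frac / max(1, length(off))^3
    blk <- array(frac, hi - lo + 1L)
    occ[rngs[[1]], rngs[[2]], rngs[[3]]] <-
      pmax(occ[rngs[[1]], rngs[[2]], rngs[[3]]], blk)
  }
  occ
}

#' Synthetic structure phantoms with analytic ground truth
#'
#' Voxelizes idealized structures -- parallel plate stacks, rod lattices,
#' mixed plate/rod lattices, spheres, and hollow shafts -- at a requested
#' voxel size, with bone density on the structure and marrow density
#' elsewhere, plus optional additive Gaussian noise. Geometry is
#' antialiased: each voxel stores its occupancy-weighted density, so
#' boundary voxels carry partial-volume values as in real CT. Every
#' phantom returns the analytic ground truth needed to test the
#' microstructural measures (thickness, spacing, diameter, orientation
#' mix, wall thickness, porosity), so no external image file is ever
#' required.
#'
#' Default densities (bone 800, marrow 100, cortical 1200 mg/cc) are
#' synthetic magnitudes on the calibrated mg/cc scale, not physiologic
#' claims.
#'
#' @param kind structure type.
#' @param spacing_mm isotropic voxel size (mm).
#' @param extent_mm physical extent, length 3 (mm); defaults per kind.
#' @param thickness_mm plate thickness (plate_stack).
#' @param gap_mm marrow gap between plates (plate_stack).
#' @param rod_diameter_mm rod diameter (rod_lattice, mixed_lattice).
#' @param pitch_mm lattice pitch (rod_lattice, mixed_lattice).
#' @param transverse_fraction target fraction of transverse (in-plane)
#'   rod voxels in a mixed lattice.
#' @param sphere_radius_mm sphere radius.
#' @param outer_radius_mm,wall_mm hollow-shaft outer radius and wall
#'   thickness.
#' @param porosity target pore volume fraction inside a hollow-shaft
#'   wall.
#' @param tilt_deg tilt of the shaft axis about the x-axis, degrees.
#' @param bone_mg_cc,marrow_mg_cc,cortical_mg_cc densities.
#' @param noise_sd additive Gaussian noise SD, mg/cc.
#' @param blur_sigma_mm isotropic Gaussian point-spread SD (mm) applied
#'   to the density image, emulating finite scanner resolution
#'   (band-limits the phantom; 0 = none).
#' @param antialias subvoxel samples per axis (1 = binary voxelization).
#' @param seed RNG seed (noise and pore placement); fixed seed gives
#'   bit-identical output.
#' @return A list with elements `volume` (a [density_volume()] in mg/cc)
#'   and `truth` (a list of analytic ground-truth values, including the
#'   occupancy-thresholded `bone_mask`).
#' @export
make_structure_phantom <- function(kind = c("plate_stack", "rod_lattice",
                                            "mixed_lattice", "sphere",
                                            "hollow_shaft"),
                                   spacing_mm = 0.15,
                                   extent_mm = NULL,
                                   thickness_mm = 0.3, gap_mm = 0.5,
                                   rod_diameter_mm = 0.45, pitch_mm = 1.5,
                                   transverse_fraction = 0.3,
                                   sphere_radius_mm = 2,
                                   outer_radius_mm = 5, wall_mm = 1.2,
                                   porosity = 0, tilt_deg = 0,
                                   bone_mg_cc = 800, marrow_mg_cc = 100,
                                   cortical_mg_cc = 1200,
                                   noise_sd = 0, blur_sigma_mm = 0,
                                   antialias = 3, seed = 1L) {
  kind <- match.arg(kind)
  h <- spacing_mm
  if (min(thickness_mm, rod_diameter_mm, wall_mm) < h && kind != "sphere")
    abort_bad("structure thinner than one voxel is infeasible", "infeasible")
  extent_mm <- extent_mm %||% switch(kind,
    plate_stack = rep(6.4, 3),
    rod_lattice = c(7.5, 7.5, 9),
    mixed_lattice = c(9, 9, 9),
    sphere = rep(2 * sphere_radius_mm + 12 * h, 3),
    hollow_shaft = c(2 * outer_radius_mm + 3, 2 * outer_radius_mm + 3, 12))
  d <- pmax(8L, as.integer(round(extent_mm / h)))
  x <- axis_coords(d[1], h); y <- axis_coords(d[2], h); z <- axis_coords(d[3], h)
  ctr <- c(mean(range(x)), mean(range(y)), mean(range(z)))
  X0 <- array(rep(x, times = d[2] * d[3]), d)
  Y0 <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  Z0 <- array(rep(z, each = d[1] * d[2]), d)
  R <- if (tilt_deg != 0)
    rotation_between(c(sin(tilt_deg * pi / 180), 0,
                       cos(tilt_deg * pi / 180)), c(0, 0, 1)) else diag(3)
  # shaft-frame coordinates of voxel center + lab-space subvoxel offset
  base <- list(
    X = array((as.vector(X0) - ctr[1]) * R[1, 1] +
                (as.vector(Z0) - ctr[3]) * R[1, 3] + ctr[1], d),
    Y = Y0,
    Z = array((as.vector(X0) - ctr[1]) * R[3, 1] +
                (as.vector(Z0) - ctr[3]) * R[3, 3] + ctr[3], d))
  coords <- function(dx, dy, dz) {
    dd <- drop(R %*% (c(dx, dy, dz) * h))
    list(X = base$X + dd[1], Y = base$Y + dd[2], Z = base$Z + dd[3])
  }

  truth <- list(kind = kind, spacing_mm = h, tilt_deg = tilt_deg)
  cx <- ctr[1]; cy <- ctr[2]; cz <- ctr[3]
  pore_centers <- NULL
  pore_r <- NULL
  if (kind == "hollow_shaft" && porosity > 0) {
    # deterministic pore placement in the (shaft-frame) wall midline
    set.seed(seed)
    pore_r <- max(2.2 * h, wall_mm / 4)
    n_pores <- max(1L, round(porosity * pi *
                               (outer_radius_mm^2 -
                                  (outer_radius_mm - wall_mm)^2) *
                               diff(range(z)) / (4 / 3 * pi * pore_r^3)))
    ang <- runif(n_pores, 0, 2 * pi)
    rr <- outer_radius_mm - wall_mm / 2
    zz <- runif(n_pores, min(z) + 2 * pore_r, max(z) - 2 * pore_r)
    pore_centers <- cbind(cx + rr * cos(ang), cy + rr * sin(ang), zz)
  }

  pred <- switch(kind,
    plate_stack = function(co)
      ((co$Z - cz) %% (thickness_mm + gap_mm)) < thickness_mm,
    rod_lattice = function(co) {
      ux <- ((co$X - cx) %% pitch_mm) - pitch_mm / 2
      uy <- ((co$Y - cy) %% pitch_mm) - pitch_mm / 2
      (ux^2 + uy^2) <= (rod_diameter_mm / 2)^2
    },
    mixed_lattice = function(co) {
      mixed_lattice_parts(co, cx, cy, cz, pitch_mm, rod_diameter_mm,
                          transverse_fraction)$bone
    },
    sphere = function(co)
      ((co$X - cx)^2 + (co$Y - cy)^2 + (co$Z - cz)^2) <= sphere_radius_mm^2,
    hollow_shaft = function(co) {
      r2 <- (co$X - cx)^2 + (co$Y - cy)^2
      r2 <= outer_radius_mm^2 & r2 >= (outer_radius_mm - wall_mm)^2
    })

  occ <- occupancy(pred, coords, antialias)
  occ_pore <- NULL
  if (!is.null(pore_centers)) {
    occ_pore <- pmin(stamp_spheres(d, h, pore_centers, pore_r, R, ctr,
                                   antialias), occ)
    occ <- occ - occ_pore
  }
  dens <- if (kind == "hollow_shaft") cortical_mg_cc else bone_mg_cc
  vals <- marrow_mg_cc + (dens - marrow_mg_cc) * occ
  if (kind == "hollow_shaft") {
    # outside the shaft is air at density 0
    r2c <- (base$X - cx)^2 + (base$Y - cy)^2
    outside <- r2c > (outer_radius_mm + h)^2
    vals[outside] <- 0
  }
  vals <- gaussian_blur(vals, blur_sigma_mm, rep(h, 3))
  if (noise_sd > 0) {
    set.seed(seed + 1L)
    vals <- vals + array(rnorm(prod(d), 0, noise_sd), d)
  }

  bone_mask <- occ >= 0.5
  truth$bone_mask <- bone_mask
  truth$bone_mg_cc <- bone_mg_cc
  truth$marrow_mg_cc <- marrow_mg_cc

  if (kind == "plate_stack") {
    truth$thickness_mm <- thickness_mm
    truth$spacing_gap_mm <- gap_mm
    truth$period_mm <- thickness_mm + gap_mm
    truth$normal <- drop(t(R) %*% c(0, 0, 1))
  } else if (kind == "rod_lattice") {
    truth$rod_diameter_mm <- rod_diameter_mm
    truth$pitch_mm <- pitch_mm
    truth$axis <- drop(t(R) %*% c(0, 0, 1))
    truth$transverse_fraction <- 0
  } else if (kind == "mixed_lattice") {
    parts <- mixed_lattice_parts(base, cx, cy, cz, pitch_mm,
                                 rod_diameter_mm, transverse_fraction)
    trans_mask <- parts$transverse & bone_mask
    truth$rod_diameter_mm <- rod_diameter_mm
    truth$pitch_mm <- pitch_mm
    truth$transverse_mask <- trans_mask
    truth$transverse_fraction <- sum(trans_mask) / max(1, sum(bone_mask))
  } else if (kind == "sphere") {
    truth$radius_mm <- sphere_radius_mm
  } else {
    truth$outer_radius_mm <- outer_radius_mm
    truth$wall_mm <- wall_mm
    truth$marrow_radius_mm <- outer_radius_mm - wall_mm
    truth$axis <- drop(t(R) %*% c(0, 0, 1))
    if (!is.null(occ_pore)) {
      pore_mask <- occ_pore >= 0.5
      truth$pore_mask <- pore_mask
      truth$porosity <- sum(pore_mask) / (sum(pore_mask) + sum(bone_mask))
    } else truth$porosity <- 0
  }

  list(volume = density_volume(vals, h, units = "mg_cc"), truth = truth)
}

# mixed lattice geometry: longitudinal rods along z on an xy grid plus
# transverse rods along x on a yz grid, with a transverse rod kept only on
# every m-th yz grid line so the voxel mix approaches the requested
# transverse fraction
mixed_lattice_parts <- function(co, cx, cy, cz, pitch, diam, tfrac) {
  r <- diam / 2
  ux <- ((co$X - cx) %% pitch) - pitch / 2
  uy <- ((co$Y - cy) %% pitch) - pitch / 2
  uz <- ((co$Z - cz) %% pitch) - pitch / 2
  long <- (ux^2 + uy^2) <= r^2
  # per-rod volume is about equal for the two families, so the count ratio
  # of kept transverse grid lines sets the voxel ratio
  keep_every <- max(1L, round((1 - tfrac) / max(tfrac, 1e-6)))
  plane <- round((co$Z - cz) / pitch)
  trans <- (uy^2 + uz^2) <= r^2 & (plane %% keep_every == 0)
  list(bone = long | trans, transverse = trans & !long)
}

#' Distal-tibia-like phantom
#'
#' Emulates the anatomy the region-of-interest machinery relies on: a
#' cortical shaft whose distal end carries a solid end-plateau cap and,
#' distal to it, a cup whose axial cross-sections are annular (each
#' contains a 2D hole in the filled bone), an internal trabecular lattice
#' of longitudinal plates and transverse rods, optional cortical wall
#' pores, and a tiltable long axis. Voxelization is antialiased as in
#' [make_structure_phantom()]. Ground truth records the plateau slice,
#' axis direction, wall thickness, lattice parameters, and the realized
#' transverse voxel fraction.
#'
#' @param spacing_mm isotropic voxel size (mm).
#' @param length_mm scanned length along z (mm).
#' @param outer_radius_mm shaft outer radius.
#' @param wall_mm cortical wall thickness.
#' @param plateau_mm height of the distal end plateau above the volume
#'   floor (mm).
#' @param tibial_length_mm nominal full tibial length used to convert
#'   percent sites to mm (the scan covers only its distal portion).
#' @param plate_thickness_mm,plate_pitch_mm vertical (longitudinal) plate
#'   lattice parameters.
#' @param rod_diameter_mm,rod_pitch_mm transverse rod lattice parameters
#'   (in-plane pitch).
#' @param rod_pitch_z_mm axial pitch of the transverse rod planes; kept
#'   well below the percent-site band height so the lattice is
#'   z-homogeneous at band scale.
#' @param trab_top_mm proximal extent of the trabecular lattice above the
#'   plateau (mm); the diaphysis above it is hollow, as in the real bone.
#' @param wall_porosity target cortical pore volume fraction.
#' @param tilt_deg axis tilt about x (<= 20).
#' @param bone_mg_cc,marrow_mg_cc,cortical_mg_cc densities (mg/cc).
#' @param noise_sd additive Gaussian noise SD (mg/cc).
#' @param blur_sigma_mm isotropic Gaussian point-spread SD (mm); the
#'   default band-limits the lattice roughly like the scanner's true
#'   resolution, so rigid reorientation and windowed-sinc resampling are
#'   nearly information-preserving.
#' @param antialias subvoxel samples per axis.
#' @param seed RNG seed.
#' @return list(volume, truth) as in [make_structure_phantom()].
#' @export
make_tibia_phantom <- function(spacing_mm = 0.15, length_mm = 26,
                               outer_radius_mm = 6, wall_mm = 1.2,
                               plateau_mm = 3, tibial_length_mm = 100,
                               plate_thickness_mm = 0.45,
                               plate_pitch_mm = 1.5,
                               rod_diameter_mm = 0.45, rod_pitch_mm = 1.5,
                               rod_pitch_z_mm = 0.9,
                               trab_top_mm = 11,
                               wall_porosity = 0, tilt_deg = 0,
                               bone_mg_cc = 800, marrow_mg_cc = 100,
                               cortical_mg_cc = 1200,
                               noise_sd = 0, blur_sigma_mm = 0.1,
                               antialias = 3, seed = 1L) {
  if (abs(tilt_deg) > 20)
    abort_bad("axis tilt above 20 degrees is unsupported", "infeasible")
  h <- spacing_mm
  pad <- if (tilt_deg != 0) 0.55 * length_mm * sin(abs(tilt_deg) * pi / 180) +
    3 * h else 0
  ext <- c(2 * outer_radius_mm + 2 + 2 * pad, 2 * outer_radius_mm + 2,
           length_mm)
  d <- as.integer(round(ext / h))
  x <- axis_coords(d[1], h); y <- axis_coords(d[2], h); z <- axis_coords(d[3], h)
  ctr <- c(mean(range(x)), mean(range(y)), mean(range(z)))
  cx <- ctr[1]; cy <- ctr[2]; cz <- ctr[3]
  X0 <- array(rep(x, times = d[2] * d[3]), d)
  Y0 <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  Z0 <- array(rep(z, each = d[1] * d[2]), d)
  axis_dir <- c(sin(tilt_deg * pi / 180), 0, cos(tilt_deg * pi / 180))
  R <- if (tilt_deg != 0) rotation_between(axis_dir, c(0, 0, 1)) else diag(3)
  base <- list(
    X = array((as.vector(X0) - cx) * R[1, 1] +
                (as.vector(Z0) - cz) * R[1, 3] + cx, d),
    Y = Y0,
    Z = array((as.vector(X0) - cx) * R[3, 1] +
                (as.vector(Z0) - cz) * R[3, 3] + cz, d))
  coords <- function(dx, dy, dz) {
    dd <- drop(R %*% (c(dx, dy, dz) * h))
    list(X = base$X + dd[1], Y = base$Y + dd[2], Z = base$Z + dd[3])
  }

  z_cup0 <- 1.0                 # below: empty, keeps the cup open distally
  z_plat <- plateau_mm
  cap_mm <- 0.6
  pore_centers <- NULL
  pore_r <- NULL
  if (wall_porosity > 0) {
    set.seed(seed)
    pore_r <- max(2.2 * h, wall_mm / 4)
    wall_area <- pi * (outer_radius_mm^2 - (outer_radius_mm - wall_mm)^2)
    span <- max(z) - (z_plat + 2) - 2 * pore_r
    n_pores <- max(1L, round(wall_porosity * wall_area * span /
                               (4 / 3 * pi * pore_r^3)))
    ang <- runif(n_pores, 0, 2 * pi)
    rr <- outer_radius_mm - wall_mm / 2
    zz <- runif(n_pores, z_plat + 2 + pore_r, max(z) - pore_r)
    pore_centers <- cbind(cx + rr * cos(ang), cy + rr * sin(ang), zz)
  }

  # The trabecular lattice lives in a deliberately oblique frame anchored
  # to the bone (plateau center): real trabeculae are never aligned with
  # the reconstruction grid, and an axis-aligned lattice would make the
  # untilted phantom an idealized special case that a reoriented scan of
  # the same bone could never reproduce. The oblique angles keep rod axes
  # and plate normals far from the 45-degree orientation cutoff.
  Qlat <- rotation_between(c(sin(12 * pi / 180), 0, cos(12 * pi / 180)),
                           c(0, 0, 1)) %*%
    matrix(c(cos(18 * pi / 180), -sin(18 * pi / 180), 0,
             sin(18 * pi / 180), cos(18 * pi / 180), 0, 0, 0, 1), 3, 3)
  parts_fun <- function(co) {
    r2 <- (co$X - cx)^2 + (co$Y - cy)^2
    shaft <- co$Z >= z_plat
    cup <- co$Z >= z_cup0 & co$Z < z_plat
    outer <- r2 <= outer_radius_mm^2
    inner <- r2 <= (outer_radius_mm - wall_mm)^2
    cortical <- outer & !inner & (shaft | cup)
    cap <- outer & shaft & co$Z < z_plat + cap_mm
    lx <- Qlat[1, 1] * (co$X - cx) + Qlat[1, 2] * (co$Y - cy) +
      Qlat[1, 3] * (co$Z - z_plat)
    ly <- Qlat[2, 1] * (co$X - cx) + Qlat[2, 2] * (co$Y - cy) +
      Qlat[2, 3] * (co$Z - z_plat)
    lz <- Qlat[3, 1] * (co$X - cx) + Qlat[3, 2] * (co$Y - cy) +
      Qlat[3, 3] * (co$Z - z_plat)
    ux <- (lx %% plate_pitch_mm) - plate_pitch_mm / 2
    plates <- abs(ux) <= plate_thickness_mm / 2
    uy <- (ly %% rod_pitch_mm) - rod_pitch_mm / 2
    uz <- (lz %% rod_pitch_z_mm) - rod_pitch_z_mm / 2
    rods <- (uy^2 + uz^2) <= (rod_diameter_mm / 2)^2
    cavity <- inner & shaft & co$Z >= z_plat + cap_mm &
      co$Z <= z_plat + trab_top_mm
    trab <- (plates | rods) & cavity
    marrow <- inner & (shaft | cup) & !trab
    list(cortical = cortical | cap, trab = trab & !cap,
         transverse = rods & !plates & cavity & !cap, marrow = marrow)
  }

  occ_c <- occupancy(function(co) parts_fun(co)$cortical, coords, antialias)
  occ_t <- occupancy(function(co) parts_fun(co)$trab, coords, antialias)
  occ_m <- occupancy(function(co) parts_fun(co)$marrow, coords, antialias)
  occ_pore <- NULL
  if (!is.null(pore_centers)) {
    occ_pore <- pmin(stamp_spheres(d, h, pore_centers, pore_r, R, ctr,
                                   antialias), occ_c)
    occ_c <- occ_c - occ_pore     # pores are marrow-density holes in the wall
    occ_m <- pmin(1, occ_m + occ_pore)
  }
  vals <- occ_c * cortical_mg_cc + occ_t * bone_mg_cc + occ_m * marrow_mg_cc
  vals <- gaussian_blur(vals, blur_sigma_mm, rep(h, 3))
  if (noise_sd > 0) {
    set.seed(seed + 1L)
    vals <- vals + array(rnorm(prod(d), 0, noise_sd), d)
  }

  parts0 <- parts_fun(base)
  trab_mask <- occ_t >= 0.5
  trans_mask <- parts0$transverse & trab_mask
  pore_mask <- if (!is.null(occ_pore)) occ_pore >= 0.5 else NULL

  truth <- list(
    kind = "tibia_like", spacing_mm = h,
    plateau_slice = min(which(z >= z_plat)),
    plateau_mm = z_plat,
    axis_direction = axis_dir, tilt_deg = tilt_deg,
    tibial_length_mm = tibial_length_mm,
    outer_radius_mm = outer_radius_mm, wall_mm = wall_mm,
    plate_thickness_mm = plate_thickness_mm,
    plate_pitch_mm = plate_pitch_mm,
    rod_diameter_mm = rod_diameter_mm, rod_pitch_mm = rod_pitch_mm,
    trab_mask = trab_mask, transverse_mask = trans_mask,
    transverse_fraction = sum(trans_mask) / max(1, sum(trab_mask)),
    wall_porosity = if (wall_porosity > 0)
      sum(pore_mask) / (sum(pore_mask) + sum(occ_c >= 0.5)) else 0,
    pore_mask = pore_mask,
    bone_mg_cc = bone_mg_cc, marrow_mg_cc = marrow_mg_cc,
    cortical_mg_cc = cortical_mg_cc
  )
  list(volume = density_volume(vals, h, units = "mg_cc"), truth = truth)
}

#' Synthetic rod calibration phantom in HU
#'
#' Builds an HU volume containing cylindrical rods of known density whose
#' HU values follow a declared affine ground-truth line, plus optional
#' noise, together with the matching [phantom_spec()].
#'
#' @param densities_mg_cc known rod densities.
#' @param slope,intercept ground-truth density = intercept + slope * HU
#'   line used to synthesize rod HU values.
#' @param spacing_mm voxel size.
#' @param rod_radius_mm rod radius.
#' @param noise_sd_hu additive HU noise.
#' @param seed RNG seed.
#' @return list(volume, spec, truth).
#' @export
make_calibration_phantom <- function(densities_mg_cc = c(0, 200, 400, 800,
                                                         1200),
                                     slope = 0.8, intercept = 50,
                                     spacing_mm = 0.5, rod_radius_mm = 3,
                                     noise_sd_hu = 0, seed = 1L) {
  n <- length(densities_mg_cc)
  h <- spacing_mm
  step <- 2 * rod_radius_mm + 4
  ext <- c(step * n + 4, step + 8, 6)
  d <- as.integer(round(ext / h))
  x <- axis_coords(d[1], h); y <- axis_coords(d[2], h)
  centers <- cbind(step * (seq_len(n) - 0.5) + 2, mean(range(y)))
  hu_true <- (densities_mg_cc - intercept) / slope
  vals <- array(-1000, d)
  for (i in seq_len(n)) {
    r2 <- outer((x - centers[i, 1])^2, (y - centers[i, 2])^2, "+")
    reg <- array(rep(r2 <= rod_radius_mm^2, d[3]), d)
    vals[reg] <- hu_true[i]
  }
  if (noise_sd_hu > 0) {
    set.seed(seed)
    vals <- vals + array(rnorm(prod(d), 0, noise_sd_hu), d)
  }
  list(volume = density_volume(vals, h, units = "HU"),
       spec = phantom_spec(centers, rod_radius_mm, densities_mg_cc),
       truth = list(slope = slope, intercept = intercept,
                    hu_true = hu_true))
}

#' Simulate a long-format measure table with known effects
#'
#' Draws outcomes from the linear mixed model
#' `value = mu + group_effect * group + covariate_effect * covariate +
#' b_unit + e`, with unit effects `b ~ N(0, sigma_between^2)` and
#' replicate noise `e ~ N(0, sigma_within^2)`. Feeds the statistics layer
#' with known ground truth for parameter-recovery tests (ICC, group
#' comparisons, power).
#'
#' @param n_per_group integer vector of group sizes (length 1 or 2).
#' @param k_replicates repeat scans per unit.
#' @param mu grand mean.
#' @param group_effect additive effect of group 1 vs group 0.
#' @param covariate_effect additive effect of the binary covariate.
#' @param covariate_prob probability a unit carries the covariate.
#' @param sigma_between,sigma_within variance-component SDs.
#' @param measure measure name tag.
#' @param seed RNG seed.
#' @return A tibble with columns `unit_id`, `group`, `covariate`,
#'   `replicate`, `measure`, `value`, with ground truth in attributes.
#' @export
simulate_measure_table <- function(n_per_group = c(9, 21), k_replicates = 1,
                                   mu = 0, group_effect = 0,
                                   covariate_effect = 0,
                                   covariate_prob = 0.5,
                                   sigma_between = 1, sigma_within = 1,
                                   measure = "sim", seed = 1L) {
  set.seed(seed)
  if (length(n_per_group) == 1) n_per_group <- c(n_per_group, 0)
  n <- sum(n_per_group)
  group <- rep(c(0L, 1L), times = n_per_group)
  covariate <- as.integer(runif(n) < covariate_prob)
  b <- rnorm(n, 0, sigma_between)
  df <- tidyr::expand_grid(unit_id = seq_len(n),
                           replicate = seq_len(k_replicates))
  df$group <- group[df$unit_id]
  df$covariate <- covariate[df$unit_id]
  df$measure <- measure
  df$value <- mu + group_effect * df$group + covariate_effect * df$covariate +
    b[df$unit_id] + rnorm(nrow(df), 0, sigma_within)
  out <- tibble::as_tibble(df[, c("unit_id", "group", "covariate",
                                  "replicate", "measure", "value")])
  attr(out, "truth") <- list(mu = mu, group_effect = group_effect,
                             covariate_effect = covariate_effect,
                             sigma_between = sigma_between,
                             sigma_within = sigma_within,
                             icc = sigma_between^2 /
                               (sigma_between^2 + sigma_within^2))
  out
}
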