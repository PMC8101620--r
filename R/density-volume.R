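#' Construct a density volume
#'
#' A `density_volume` is a 3D scalar grid with physical voxel spacing and an
#' origin, carrying either raw CT intensities in Hounsfield units (`"HU"`) or
#' calibrated bone mineral density in mg/cc (`"mg_cc"`). It is the common
#' container for every image-processing step in the package.
#'
#' @param values 3D numeric array of voxel values.
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin numeric length-3, physical position (mm) of voxel (1,1,1).
#' @param units `"HU"` or `"mg_cc"`.
#' @return An object of class `density_volume`.
#' @export
density_volume <- function(values, spacing, origin = c(0, 0, 0),
                           units = c("HU", "mg_cc")) {
  units <- match.arg(units)
  if (length(dim(values)) != 3)
    abort_bad("`values` must be a 3D array", "config")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    abort_bad("`spacing` must be 3 positive voxel sizes in mm", "config")
  if (any(!is.finite(values)))
    abort_bad("voxel values must be finite", "config")
  structure(
    list(values = values, spacing = spacing,
         origin = as.numeric(origin), units = units),
    class = "density_volume"
  )
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_volume> %d x %d x %d voxels, spacing %s mm, units %s\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x "), x$units))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.density_volume <- function(x) dim(x$values)

#' Read / write a density volume as NIfTI
#'
#' Thin wrappers over [RNifti::readNifti()] / [RNifti::writeNifti()]. Units
#' are not stored in NIfTI; supply them on read.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param units value units of the stored image.
#' @return `read_volume()` returns a `density_volume`; `write_volume()`
#'   returns `path` invisibly.
#' @export
read_volume <- function(path, units = c("HU", "mg_cc")) {
  units <- match.arg(units)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  density_volume(array(as.numeric(img), dim(img)[1:3]), spacing = sp,
                 units = units)
}

#' @rdname read_volume
#' @param v a `density_volume`.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "density_volume"))
  img <- RNifti::asNifti(v$values, reference = NULL)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Describe a density-calibration rod phantom
#'
#' Declares the geometry of a tissue-characterization phantom: cylindrical
#' rod inserts at known physical positions with known equivalent densities.
#' Rod axes are taken parallel to the image z-axis.
#'
#' @param centers_mm numeric matrix, one row per rod, columns x/y (mm),
#'   in-plane rod center positions.
#' @param radius_mm rod radius in mm (scalar or per rod).
#' @param densities_mg_cc known rod densities, mg/cc.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(centers_mm, radius_mm, densities_mg_cc) {
  centers_mm <- as.matrix(centers_mm)
  n <- nrow(centers_mm)
  if (n < 2 || length(unique(densities_mg_cc)) < 2)
    abort_bad("need at least 2 rods with distinct known densities", "config")
  radius_mm <- rep_len(radius_mm, n)
  structure(list(centers_mm = centers_mm, radius_mm = radius_mm,
                 densities_mg_cc = as.numeric(densities_mg_cc)),
            class = "phantom_spec")
}

# boolean rod region on the grid of `v`, eroded by `erode_mm` to avoid
# partial-volume rims
rod_region <- function(v, center, radius, erode_mm) {
  d <- dim(v$values)
  x <- axis_coords(d[1], v$spacing[1])
  y <- axis_coords(d[2], v$spacing[2])
  r2 <- outer((x - center[1])^2, (y - center[2])^2, "+")
  inplane <- r2 <= max(radius - erode_mm, v$spacing[1] / 2)^2
  array(rep(inplane, d[3]), d)
}

#' Fit the HU-to-density calibration line from a rod phantom scan
#'
#' Summarizes each rod by its mean HU over a one-voxel-eroded rod region and
#' fits ordinary least squares of known density (mg/cc) on mean HU.
#'
#' @param phantom_volume a `density_volume` in HU covering the phantom.
#' @param spec a [phantom_spec()].
#' @return A `calibration_line` with fields `slope` (mg/cc per HU),
#'   `intercept` (mg/cc), `r` (Pearson correlation), `n_rods`, and the
#'   per-rod summary table.
#' @export
fit_density_calibration <- function(phantom_volume, spec) {
  stopifnot(inherits(phantom_volume, "density_volume"),
            inherits(spec, "phantom_spec"))
  if (phantom_volume$units != "HU")
    abort_bad("calibration is fitted on an HU volume", "unit")
  erode <- min(phantom_volume$spacing)
  hu <- vapply(seq_len(nrow(spec$centers_mm)), function(i) {
    reg <- rod_region(phantom_volume, spec$centers_mm[i, ],
                      spec$radius_mm[i], erode)
    if (!any(reg)) abort_bad("rod region lies outside the volume", "config")
    mean(phantom_volume$values[reg])
  }, numeric(1))
  if (var(hu) == 0)
    abort_bad("zero HU variance across rods: degenerate fit", "degenerate")
  fit <- lm(d ~ hu, data = data.frame(hu = hu, d = spec$densities_mg_cc))
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r = cor(hu, spec$densities_mg_cc), n_rods = length(hu),
         rods = tibble::tibble(mean_hu = hu,
                               density_mg_cc = spec$densities_mg_cc)),
    class = "calibration_line"
  )
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf(
    "<calibration_line> density = %.4f + %.4f * HU  (r = %.4f, %d rods)\n",
    x$intercept, x$slope, x$r, x$n_rods))
  invisible(x)
}

#' Apply a calibration line to an HU volume
#'
#' Voxelwise affine map `density = intercept + slope * HU`; geometry is
#' unchanged and the result is flagged as mg/cc. Out-of-range densities are
#' kept as-is; downstream membership mapping clamps instead.
#'
#' @param v a `density_volume` in HU.
#' @param c a `calibration_line` (or any list with `slope` and `intercept`).
#' @return A `density_volume` in mg/cc.
#' @export
apply_calibration <- function(v, c) {
  stopifnot(inherits(v, "density_volume"))
  if (v$units != "HU")
    abort_bad("volume is already calibrated (units mg_cc)", "unit")
  density_volume(c$intercept + c$slope * v$values, v$spacing, v$origin,
                 units = "mg_cc")
}

# Lanczos-windowed sinc weights for resampling one axis.
# Rows: output sample positions (grid units of the input); cols: input index.
lanczos_weights <- function(pos, n_in, a = 4) {
  W <- matrix(0, length(pos), n_in)
  for (j in seq_along(pos)) {
    i0 <- floor(pos[j])
    idx <- (i0 - a + 1):(i0 + a)
    idx <- idx[idx >= 0 & idx <= n_in - 1]
    u <- pos[j] - idx
    w <- ifelse(abs(u) < 1e-12, 1,
                ifelse(abs(u) >= a, 0,
                       a * sin(pi * u) * sin(pi * u / a) / (pi^2 * u^2)))
    W[j, idx + 1] <- w / sum(w)
  }
  W
}

#' Resample a volume to isotropic voxels with a windowed-sinc kernel
#'
#' Separable Lanczos (a = 4) windowed-sinc interpolation onto an isotropic
#' grid of the requested spacing, preserving the physical extent to within
#' one voxel. Kernel rows are renormalized so constants are reproduced
#' exactly.
#'
#' @param v a `density_volume`.
#' @param target_spacing_mm desired isotropic voxel size in mm.
#' @param a Lanczos window radius in input voxels.
#' @return A resampled `density_volume` with isotropic spacing.
#' @export
resample_isotropic <- function(v, target_spacing_mm, a = 4) {
  stopifnot(inherits(v, "density_volume"))
  t <- as.numeric(target_spacing_mm)
  if (!is.finite(t) || t <= 0)
    abort_bad("target spacing must be positive", "config")
  d <- dim(v$values)
  out <- v$values
  for (ax in 1:3) {
    h <- v$spacing[ax]
    if (abs(h - t) < 1e-12) next
    n_in <- dim(out)[ax]
    extent <- (n_in - 1) * h
    n_out <- floor(extent / t + 1e-9) + 1L
    pos <- (seq_len(n_out) - 1) * t / h   # output centers in input grid units
    W <- lanczos_weights(pos, n_in, a)
    out <- apply_axis(out, ax, W)
  }
  density_volume(out, rep(t, 3), v$origin, units = v$units)
}

# multiply weight matrix W (n_out x n_in) along axis `ax` of 3D array
apply_axis <- function(arr, ax, W) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  m <- matrix(aperm(arr, perm), d[ax], prod(d[-ax]))
  res <- W %*% m
  d2 <- c(nrow(W), d[-ax])
  aperm(array(res, d2), order(perm))
}
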