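#' Region-of-interest mask
#'
#' A boolean voxel grid aligned to a [density_volume()], tagged with its
#' provenance: the percent-site band along the tibial length and/or the
#' percent-peel range that produced it.
#'
#' @param mask logical 3D array.
#' @param spacing voxel size, mm.
#' @param kind `"axial_band"`, `"sphere"`, or `"support"`.
#' @param site_range_pct,peel_range_pct optional provenance tags.
#' @return A `roi_mask`.
#' @export
roi_mask <- function(mask, spacing, kind = "support",
                     site_range_pct = NULL, peel_range_pct = NULL) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  spacing <- rep_len(as.numeric(spacing), 3)
  structure(list(mask = mask, spacing = spacing, kind = kind,
                 site_range_pct = site_range_pct,
                 peel_range_pct = peel_range_pct),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s: %d voxels (%.2f mm^3)\n", x$kind,
              sum(x$mask), sum(x$mask) * prod(x$spacing)))
  invisible(x)
}

roi_volume_mm3 <- function(roi) sum(roi$mask) * prod(roi$spacing)

#' Filled-in bone volume
#'
#' Segments the largest bone in a calibrated volume as a single connected
#' solid: density thresholding, multiscale morphological closing (one pass
#' per radius, smallest first), largest 26-connected component, and filling
#' of internal cavities (background regions not connected to the volume
#' border), so cortex and marrow cavity form one solid region.
#'
#' @param v a `density_volume` in mg/cc.
#' @param bone_threshold density threshold (mg/cc) separating bone from
#'   marrow.
#' @param closing_radii_mm radii (mm) for the multiscale closing passes.
#' @return A `roi_mask` of the filled bone.
#' @export
fill_bone_volume <- function(v, bone_threshold = 400,
                             closing_radii_mm = c(0.3, 0.6)) {
  stopifnot(inherits(v, "density_volume"))
  if (v$units != "mg_cc")
    abort_bad("fill_bone_volume expects a calibrated (mg/cc) volume", "unit")
  m <- v$values >= bone_threshold
  if (!any(m))
    abort_bad("no voxels above the bone threshold", "segmentation_failure")
  for (r in sort(closing_radii_mm)) m <- morph_close(m, r, v$spacing)
  m <- largest_component(m, 26L)
  # fill internal cavities: background 6-components not reaching the lateral
  # border. The axial faces are cut planes -- the scan truncates the bone
  # there -- so a marrow cavity opened only through an axial face still
  # counts as interior and is filled.
  bg <- label_components(!m, 6L)
  d <- dim(m)
  border_labs <- unique(c(bg$labels[c(1, d[1]), , ],
                          bg$labels[, c(1, d[2]), ]))
  border_labs <- border_labs[border_labs > 0]
  cavity <- !m & !(bg$labels %in% border_labs)
  m <- m | array(cavity, d)
  roi_mask(m, v$spacing, kind = "support")
}

# labels of 2D background holes in one slice: 4-connected background
# components fully enclosed by the slice (not touching the slice border)
slice_has_hole <- function(sl) {
  d2 <- dim(sl)
  lab <- cpp_label(as.logical(!sl), as.integer(c(d2, 1L)), 6L)
  labs <- array(lab$labels, c(d2, 1))[, , 1]
  border <- unique(c(labs[c(1, d2[1]), ], labs[, c(1, d2[2])]))
  any(setdiff(unique(labs[labs > 0]), border[border > 0]) > 0)
}

#' Locate the distal tibial end plateau
#'
#' Traces axial slices from proximal to distal and returns the slice just
#' proximal to the first slice whose filled-bone cross-section contains a
#' 2D hole (a background region enclosed by foreground; 4-connected
#' background against 8-connected foreground). Slice index increases from
#' distal to proximal.
#'
#' @param filled a `roi_mask` from [fill_bone_volume()].
#' @return Integer slice index of the end plateau.
#' @export
locate_end_plateau <- function(filled) {
  stopifnot(inherits(filled, "roi_mask"))
  nz <- dim(filled$mask)[3]
  for (k in nz:1) {
    if (slice_has_hole(filled$mask[, , k]))
      return(min(k + 1L, nz))
  }
  abort_bad("no slice with a 2D hole found: plateau not located",
            "plateau_not_found")
}

#' Anatomy frame of a scan
#'
#' Bundles the subject-specific references every ROI is defined against:
#' the end-plateau slice, the nominal tibial length used for percent
#' sites, the fitted long-axis direction, and the rigid rotation that
#' realigns the axis with the grid z-axis.
#'
#' @param plateau_slice axial index of the distal end plateau.
#' @param tibial_length_mm nominal tibial length (mm).
#' @param axis_direction unit 3-vector, distal-to-proximal.
#' @param rotation 3x3 rotation sending `axis_direction` to +z.
#' @param center_mm rotation center (mm).
#' @param spacing voxel size (mm).
#' @return An `anatomy_frame`.
#' @export
anatomy_frame <- function(plateau_slice, tibial_length_mm, axis_direction,
                          rotation = diag(3), center_mm = c(0, 0, 0),
                          spacing = c(1, 1, 1)) {
  axis_direction <- axis_direction / sqrt(sum(axis_direction^2))
  structure(list(plateau_slice = as.integer(plateau_slice),
                 tibial_length_mm = tibial_length_mm,
                 axis_direction = axis_direction, rotation = rotation,
                 center_mm = center_mm, spacing = rep_len(spacing, 3)),
            class = "anatomy_frame")
}

#' @export
print.anatomy_frame <- function(x, ...) {
  cat(sprintf(
    "<anatomy_frame> plateau slice %d, tibial length %.1f mm, axis (%.3f, %.3f, %.3f)\n",
    x$plateau_slice, x$tibial_length_mm, x$axis_direction[1],
    x$axis_direction[2], x$axis_direction[3]))
  invisible(x)
}

#' Fit the tibial axis
#'
#' Fits the mean-squared-error-optimal line (first principal direction)
#' through the voxel cloud of the 60%-peeled filled bone proximal to the
#' 8% tibial site, and derives the rigid rotation aligning that axis with
#' the grid z-axis. The direction is canonicalized distal-to-proximal
#' (positive z-component).
#'
#' @param filled a `roi_mask` of filled bone.
#' @param plateau_slice end-plateau slice index.
#' @param tibial_length_mm nominal tibial length (mm).
#' @param site_pct percent site bounding the fitting region distally.
#' @param peel_pct percent peel applied slice-wise before fitting.
#' @return An [anatomy_frame()].
#' @export
fit_tibial_axis <- function(filled, plateau_slice, tibial_length_mm,
                            site_pct = 8, peel_pct = 60) {
  stopifnot(inherits(filled, "roi_mask"))
  h <- filled$spacing
  p1 <- axis_fit_once(filled$mask, h, plateau_slice, tibial_length_mm,
                      site_pct, peel_pct)
  anatomy_frame(plateau_slice, tibial_length_mm, p1$axis,
                rotation = rotation_between(p1$axis, c(0, 0, 1)),
                center_mm = p1$center, spacing = h)
}

# single MSE line fit through the peeled proximal region: the line is fit
# (total least squares) through the per-slice centroids of the peeled
# cross-sections, weighted by slice size. Centroids of axial cross-sections
# lie on the shaft axis even where flat z-cuts truncate it obliquely, which
# keeps the fit free of end-cut bias.
axis_fit_once <- function(mask, h, plateau_slice, tibial_length_mm,
                          site_pct, peel_pct) {
  d <- dim(mask)
  z0 <- plateau_slice + ceiling(site_pct / 100 * tibial_length_mm / h[3])
  if (d[3] - z0 + 1 < 10)
    abort_bad("fewer than 10 slices proximal to the site for axis fitting",
              "axis_fit")
  sub <- mask
  sub[, , seq_len(min(z0 - 1, d[3]))] <- FALSE
  peeled <- compute_peel(roi_mask(sub, h), peel_pct)
  idx <- which(peeled$mask, arr.ind = TRUE)
  if (nrow(idx) < 30 || length(unique(idx[, 3])) < 10)
    abort_bad("degenerate voxel cloud for axis fitting", "axis_fit")
  pts <- sweep(idx - 1, 2, h, "*")
  ctr <- vapply(split(seq_len(nrow(pts)), idx[, 3]), function(i)
    c(colMeans(pts[i, , drop = FALSE]), length(i)), numeric(4))
  cent <- t(ctr[1:3, , drop = FALSE])
  w <- ctr[4, ]
  if (nrow(cent) < 10)
    abort_bad("degenerate voxel cloud for axis fitting", "axis_fit")
  mu <- colSums(cent * w) / sum(w)
  cc <- sweep(cent, 2, mu)
  S <- crossprod(cc * sqrt(w / sum(w)))
  eg <- eigen(S, symmetric = TRUE)
  if (eg$values[1] < 1e-12)
    abort_bad("degenerate voxel cloud for axis fitting", "axis_fit")
  ax <- eg$vectors[, 1]
  if (ax[3] < 0) ax <- -ax
  list(axis = ax, center = mu)
}

#' Realign a volume so the tibial axis is parallel to z
#'
#' Applies the frame's rigid rotation about its center on the same grid,
#' using Lanczos windowed-sinc interpolation (the package's standard
#' high-fidelity interpolator); thin trabeculae survive the rotation far
#' better than under trilinear resampling.
#'
#' @param v a `density_volume`.
#' @param frame an [anatomy_frame()].
#' @param fill value for voxels mapped from outside the input.
#' @param a Lanczos window radius in voxels.
#' @return A rotated `density_volume`.
#' @export
realign_volume <- function(v, frame, fill = 0, a = 4) {
  stopifnot(inherits(v, "density_volume"), inherits(frame, "anatomy_frame"))
  d <- dim(v$values)
  vals <- cpp_resample_rigid(as.numeric(v$values), as.integer(d),
                             as.numeric(v$spacing), frame$rotation,
                             as.numeric(frame$center_mm), as.integer(a),
                             fill)
  density_volume(array(vals, d), v$spacing, v$origin, units = v$units)
}

#' @rdname realign_volume
#' @param mask a `roi_mask` to rotate with the same frame (nearest
#'   equivalent: trilinear interpolation thresholded at 0.5).
#' @export
realign_mask <- function(mask, frame) {
  stopifnot(inherits(mask, "roi_mask"), inherits(frame, "anatomy_frame"))
  d <- dim(mask$mask)
  vals <- cpp_resample_rigid(as.numeric(mask$mask), as.integer(d),
                             as.numeric(mask$spacing), frame$rotation,
                             as.numeric(frame$center_mm), 1L, 0)
  roi_mask(array(vals >= 0.5, d), mask$spacing, kind = mask$kind,
           site_range_pct = mask$site_range_pct,
           peel_range_pct = mask$peel_range_pct)
}

#' Percent peel of a realigned mask
#'
#' Slice-wise 2D Euclidean distance-transform peeling: on each axial
#' slice, voxels are retained when their distance to the slice boundary is
#' at least `peel_pct`/100 of that slice's maximum inscribed distance.
#' Peel 0 is the identity; peel 100 keeps at most the per-slice distance
#' maxima.
#'
#' @param filled a `roi_mask` realigned so the axis is parallel to z.
#' @param peel_pct percent peel in `[0, 100]`.
#' @return A peeled `roi_mask`.
#' @export
compute_peel <- function(filled, peel_pct) {
  stopifnot(inherits(filled, "roi_mask"))
  if (peel_pct < 0 || peel_pct > 100)
    abort_bad("peel percent must lie in [0, 100]", "config")
  if (peel_pct == 0) return(filled)
  # slice-wise 2D EDT: an effectively infinite z spacing blocks cross-slice
  # propagation in the separable transform
  dist <- edt_mm(filled$mask, c(filled$spacing[1:2], 1e9))
  d <- dim(filled$mask)
  slice_max <- apply(dist, 3, max)
  thr <- array(rep(slice_max * peel_pct / 100, each = d[1] * d[2]), d)
  keep <- filled$mask & dist >= thr & dist > 0
  roi_mask(keep, filled$spacing, kind = filled$kind,
           site_range_pct = filled$site_range_pct,
           peel_range_pct = c(peel_pct, 100))
}

#' Axial percent-site ROI with optional peel
#'
#' Slab of axial slices between `site_pct[1]`% and `site_pct[2]`% of the
#' tibial length measured proximally from the end plateau, intersected
#' with an inner peel (`peel_pct` a single value: keep deeper than that
#' peel) or an annular peel band (`peel_pct = c(lo, hi)`: between the two
#' peels).
#'
#' @param frame an [anatomy_frame()].
#' @param filled realigned filled-bone `roi_mask`.
#' @param site_pct numeric length-2, percent-site range.
#' @param peel_pct `NULL` (no peel), one value (inner region), or two
#'   values (annulus between peels).
#' @return A `roi_mask` tagged with site and peel provenance.
#' @export
make_axial_roi <- function(frame, filled, site_pct, peel_pct = NULL) {
  stopifnot(inherits(frame, "anatomy_frame"), inherits(filled, "roi_mask"))
  if (any(site_pct < 0 | site_pct > 100) || site_pct[1] >= site_pct[2])
    abort_bad("site percent range must be increasing within [0, 100]",
              "config")
  h <- filled$spacing
  d <- dim(filled$mask)
  zlo <- frame$plateau_slice +
    ceiling(site_pct[1] / 100 * frame$tibial_length_mm / h[3])
  zhi <- frame$plateau_slice +
    floor(site_pct[2] / 100 * frame$tibial_length_mm / h[3])
  zlo <- max(1L, zlo); zhi <- min(d[3], zhi)
  if (zlo > zhi) abort_bad("site band lies outside the scan", "empty_roi")
  m <- filled$mask
  m[, , -(zlo:zhi)] <- FALSE
  band <- roi_mask(m, h, kind = "axial_band", site_range_pct = site_pct)
  out <- if (is.null(peel_pct)) {
    band
  } else if (length(peel_pct) == 1) {
    inner <- compute_peel(band, peel_pct)
    inner$peel_range_pct <- c(peel_pct, 100)
    inner
  } else {
    lo <- compute_peel(band, min(peel_pct))
    hi <- compute_peel(band, max(peel_pct))
    ann <- roi_mask(lo$mask & !hi$mask, h, kind = "axial_band",
                    site_range_pct = site_pct,
                    peel_range_pct = sort(peel_pct))
    ann
  }
  if (!any(out$mask)) abort_bad("resulting ROI is empty", "empty_roi")
  out$site_range_pct <- site_pct
  out
}

#' Randomly sampled spherical ROIs
#'
#' Draws `n` spheres of the given diameter whose voxel sets lie fully
#' inside `region`, with centers sampled uniformly over all feasible
#' center voxels. Deterministic for a fixed seed. A diameter of 7.05 mm at
#' 0.15 mm spacing spans exactly 47 voxels.
#'
#' @param region sampling `roi_mask`.
#' @param n number of spheres (0 returns an empty list).
#' @param diameter_mm sphere diameter (mm).
#' @param seed RNG seed.
#' @param allow_overlap if `FALSE`, centers are kept at least one
#'   diameter apart (bounded retries).
#' @return List of `roi_mask` spheres.
#' @export
sample_spherical_rois <- function(region, n, diameter_mm, seed = 1L,
                                  allow_overlap = TRUE) {
  stopifnot(inherits(region, "roi_mask"))
  if (n == 0) return(list())
  h <- region$spacing
  r <- diameter_mm / 2
  # the array edge counts as region boundary so spheres are never clipped
  shaved <- region$mask
  d0 <- dim(shaved)
  shaved[c(1, d0[1]), , ] <- FALSE
  shaved[, c(1, d0[2]), ] <- FALSE
  shaved[, , c(1, d0[3])] <- FALSE
  feas <- edt_mm(shaved, h) > r
  cand <- which(feas)
  if (length(cand) < 1)
    abort_bad("region cannot contain a sphere of this diameter", "sampling")
  set.seed(seed)
  d <- dim(region$mask)
  centers <- matrix(NA_real_, 0, 3)
  picks <- integer(0)
  tries <- 0
  while (length(picks) < n) {
    tries <- tries + 1
    if (tries > 200 * n)
      abort_bad("could not place the requested spheres", "sampling")
    ci <- cand[sample.int(length(cand), 1)]
    p <- (arrayInd(ci, d) - 1) * h
    if (!allow_overlap && nrow(centers) > 0 &&
        any(sqrt(rowSums(sweep(centers, 2, as.numeric(p))^2)) < diameter_mm))
      next
    centers <- rbind(centers, p)
    picks <- c(picks, ci)
  }
  lapply(seq_len(n), function(i) {
    ijk0 <- arrayInd(picks[i], d) - 1
    rng <- lapply(1:3, function(a) {
      lo <- max(0, ijk0[a] - ceiling(r / h[a]))
      hi <- min(d[a] - 1, ijk0[a] + ceiling(r / h[a]))
      lo:hi
    })
    m <- array(FALSE, d)
    grid <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    off <- sweep(grid, 2, as.numeric(ijk0), "-")
    dist <- sqrt(rowSums(sweep(off, 2, h, "*")^2))
    m[grid[dist <= r, , drop = FALSE] + 1] <- TRUE
    roi_mask(m, h, kind = "sphere")
  })
}
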