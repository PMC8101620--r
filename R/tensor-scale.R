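#' Tensor-scale analysis at skeleton voxels
#'
#' At each skeleton voxel, estimates the largest membership-bounded
#' ellipsoid centered there: rays are cast in a deterministic set of
#' near-uniform hemisphere directions (and their antipodes) to the fuzzy
#' boundary (membership 0.5 crossing, subvoxel interpolated), each
#' direction's radius is the smaller of the two one-sided distances, and
#' the best-fit ellipsoid through the ray endpoints is recovered by
#' least squares on its quadratic form. Semi-axes are sorted
#' `a1 >= a2 >= a3`; the local plate width is `2 * a2` and is capped at
#' `2 * max_scale_mm` (open plates report the cap).
#'
#' @param s a `skeleton_map`.
#' @param m the `membership_volume` the skeleton came from.
#' @param max_scale_mm ray length cap (mm).
#' @param n_directions hemisphere direction count (>= 45 recommended).
#' @param step_mm ray marching step; defaults to 0.3 voxel.
#' @param boundary membership level of the fuzzy boundary.
#' @return A `local_structure`: tibble with per-skeleton-voxel semi-axes
#'   (mm), orientation vectors of the largest and smallest axes, and
#'   `plate_width_mm`.
#' @export
tensor_scale_at <- function(s, m, max_scale_mm = 3, n_directions = 45,
                            step_mm = NULL, boundary = 0.5) {
  stopifnot(inherits(s, "skeleton_map"), inherits(m, "membership_volume"))
  h <- min(m$spacing)
  if (max_scale_mm <= h)
    abort_bad("max_scale_mm must exceed the voxel size", "config")
  step_mm <- step_mm %||% (0.3 * h)
  vox <- s$voxels
  if (nrow(vox) == 0) {
    out <- tibble::tibble(x = integer(), y = integer(), z = integer(),
                          a1 = numeric(), a2 = numeric(), a3 = numeric(),
                          plate_width_mm = numeric(), capped = logical())
    return(structure(list(table = out, dir1 = matrix(0, 0, 3),
                          dir3 = matrix(0, 0, 3), max_scale_mm = max_scale_mm),
                     class = "local_structure"))
  }
  dirs <- fibonacci_hemisphere(n_directions)
  pts <- cbind(vox$x - 1, vox$y - 1, vox$z - 1)
  rc <- cpp_cast_rays(as.numeric(m$values), as.integer(dim(m$values)),
                      as.numeric(m$spacing), pts, dirs, step_mm,
                      max_scale_mm, boundary)
  # two-sided mean: robust to the half-voxel off-centering of the digital
  # medial surface inside the structure
  r <- (rc$dpos + rc$dneg) / 2
  r <- pmax(r, 0.5 * h)      # never below half a voxel
  np <- nrow(pts)
  a <- matrix(0, np, 3)
  d1 <- matrix(0, np, 3)
  d3 <- matrix(0, np, 3)
  # least-squares quadratic form x' A x = 1 through endpoints r_k * u_k
  U2 <- cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
              2 * dirs[, 1] * dirs[, 2], 2 * dirs[, 1] * dirs[, 3],
              2 * dirs[, 2] * dirs[, 3])
  for (i in seq_len(np)) {
    ri <- r[i, ]
    # endpoint p = r u on the ellipsoid: r^2 u'Au = 1  =>  U2 co = 1/r^2
    rhs <- 1 / ri^2
    co <- tryCatch(qr.solve(U2, rhs), error = function(e) rep(NA, 6))
    if (!anyNA(co)) {
      # one-sided trimmed refit: rays grazing the fuzzy boundary at
      # shallow angles exit early (measured r too short, so 1/r^2 above
      # the fitted form); drop the most negative signed residuals and
      # refit on the consistent rays
      resid <- drop(U2 %*% co) - rhs
      keep <- resid >= quantile(resid, 0.4)
      if (sum(keep) >= 12) {
        co2 <- tryCatch(qr.solve(U2[keep, , drop = FALSE], rhs[keep]),
                        error = function(e) NULL)
        if (!is.null(co2)) co <- co2
      }
    }
    if (anyNA(co)) { a[i, ] <- NA; next }
    A <- matrix(c(co[1], co[4], co[5],
                  co[4], co[2], co[6],
                  co[5], co[6], co[3]), 3, 3)
    eg <- eigen(A, symmetric = TRUE)
    ev <- pmax(eg$values, 1 / max_scale_mm^2)   # cap semi-axes at max scale
    ax <- 1 / sqrt(ev)                          # ascending eigenvalue ->
    ord <- order(ax, decreasing = TRUE)         # descending axis
    a[i, ] <- ax[ord]
    d1[i, ] <- eg$vectors[, ord[1]]
    d3[i, ] <- eg$vectors[, ord[3]]
  }
  bad <- is.na(a[, 1])
  if (any(bad)) {
    a[bad, 1] <- apply(r[bad, , drop = FALSE], 1, max)
    a[bad, 2] <- apply(r[bad, , drop = FALSE], 1, median)
    a[bad, 3] <- apply(r[bad, , drop = FALSE], 1, min)
    d1[bad, ] <- matrix(rep(c(0, 0, 1), sum(bad)), ncol = 3, byrow = TRUE)
    d3[bad, ] <- matrix(rep(c(1, 0, 0), sum(bad)), ncol = 3, byrow = TRUE)
  }
  a <- pmin(a, max_scale_mm)
  out <- tibble::tibble(x = vox$x, y = vox$y, z = vox$z,
                        a1 = a[, 1], a2 = a[, 2], a3 = a[, 3],
                        plate_width_mm = 2 * a[, 2],
                        capped = a[, 2] >= max_scale_mm - 1e-9)
  structure(list(table = out, dir1 = d1, dir3 = d3,
                 max_scale_mm = max_scale_mm),
            class = "local_structure")
}

#' @export
print.local_structure <- function(x, ...) {
  cat(sprintf("<local_structure> %d voxels, mean plate width %.0f um (%.0f%% capped)\n",
              nrow(x$table), 1000 * mean(x$table$plate_width_mm),
              100 * mean(x$table$capped)))
  invisible(x)
}

#' Plate/rod classification of skeleton voxels
#'
#' A voxel is plate-like when its local ellipsoid is markedly wider than
#' thick: `a2 / a3 >= ratio_threshold` (default 2); otherwise rod-like.
#'
#' @param ls a `local_structure`.
#' @param ratio_threshold width-to-thickness ratio separating plates from
#'   rods.
#' @return Character vector (`"plate"`/`"rod"`) per skeleton voxel.
#' @export
classify_plate_rod <- function(ls, ratio_threshold = 2) {
  stopifnot(inherits(ls, "local_structure"))
  ifelse(ls$table$a2 / ls$table$a3 >= ratio_threshold, "plate", "rod")
}

#' Transverse/longitudinal classification of skeleton voxels
#'
#' Orientation of the local load-bearing geometry relative to the tibial
#' axis. Rule table: for rod-like voxels the dominant direction is the
#' long axis `a1`; the voxel is longitudinal when that direction is
#' within `angle_threshold_deg` of the tibial axis, transverse otherwise.
#' For plate-like voxels the plate plane carries the load; the voxel is
#' transverse when the plate normal (`a3` direction) is within
#' `angle_threshold_deg` of the tibial axis (plate lying in the axial
#' plane), longitudinal otherwise.
#'
#' @param ls a `local_structure`.
#' @param frame an [anatomy_frame()] (supplies the axis direction).
#' @param angle_threshold_deg angular cutoff, degrees.
#' @param ratio_threshold passed to [classify_plate_rod()].
#' @return Character vector (`"transverse"`/`"longitudinal"`).
#' @export
classify_orientation <- function(ls, frame, angle_threshold_deg = 45,
                                 ratio_threshold = 2) {
  stopifnot(inherits(ls, "local_structure"))
  ax <- if (inherits(frame, "anatomy_frame")) frame$axis_direction
        else frame / sqrt(sum(frame^2))
  kind <- classify_plate_rod(ls, ratio_threshold)
  cosang <- function(M) pmin(1, abs(M %*% ax))
  ang1 <- acos(cosang(ls$dir1)) * 180 / pi   # long axis vs tibial axis
  ang3 <- acos(cosang(ls$dir3)) * 180 / pi   # plate normal vs tibial axis
  out <- ifelse(kind == "rod",
                ifelse(ang1 <= angle_threshold_deg, "longitudinal",
                       "transverse"),
                ifelse(ang3 <= angle_threshold_deg, "transverse",
                       "longitudinal"))
  as.character(out)
}

#' Volumetric trabecular BMD (Tb.vBMD)
#'
#' Arithmetic mean of calibrated density over the ROI.
#'
#' @param v a `density_volume` in mg/cc.
#' @param roi a `roi_mask`.
#' @return Tb.vBMD in mg/cc.
#' @export
tb_vbmd <- function(v, roi) {
  stopifnot(inherits(v, "density_volume"), inherits(roi, "roi_mask"))
  if (v$units != "mg_cc") abort_bad("volume must be calibrated", "unit")
  if (!any(roi$mask)) abort_bad("empty ROI", "empty_roi")
  mean(v$values[roi$mask])
}

#' Transverse trabecular BMD (Tb.tBMD)
#'
#' Density contributed by transverse trabeculae: the sum of BMD over the
#' intersection of the ROI with the transverse structure support, divided
#' by the full ROI voxel count. A partial density on the Tb.vBMD scale,
#' so the transverse and longitudinal parts add up to the structural BMD
#' and `tb_tbmd <= tb_vbmd` whenever marrow density is nonnegative.
#'
#' @param v a `density_volume` in mg/cc.
#' @param roi a `roi_mask`.
#' @param transverse_support `roi_mask` of voxels assigned to transverse
#'   structure (see [propagate_orientation()]).
#' @return Tb.tBMD in mg/cc.
#' @export
tb_tbmd <- function(v, roi, transverse_support) {
  stopifnot(inherits(v, "density_volume"), inherits(roi, "roi_mask"),
            inherits(transverse_support, "roi_mask"))
  if (!any(roi$mask)) abort_bad("empty ROI", "empty_roi")
  sel <- roi$mask & transverse_support$mask
  if (!any(sel)) return(0)
  sum(v$values[sel]) / sum(roi$mask)
}

#' Propagate skeleton orientation classes back to the structure support
#'
#' Assigns every support voxel the orientation class of its (geodesically)
#' nearest skeleton voxel by iterative 26-neighbor dilation of the class
#' labels inside the support.
#'
#' @param s a `skeleton_map`.
#' @param m the `membership_volume`.
#' @param classes character class per skeleton voxel (from
#'   [classify_orientation()]).
#' @param keep class whose support is returned.
#' @param support_threshold membership level of the structure support.
#' @return A `roi_mask` of support voxels in class `keep`.
#' @export
propagate_orientation <- function(s, m, classes, keep = "transverse",
                                  support_threshold = 0.5) {
  stopifnot(inherits(s, "skeleton_map"), inherits(m, "membership_volume"))
  d <- dim(m$values)
  support <- m$values >= support_threshold
  lab <- array(0L, d)
  lin <- which(s$mask)
  lab[lin] <- ifelse(classes == keep, 1L, 2L)
  if (!any(lab > 0)) return(roi_mask(array(FALSE, d), m$spacing))
  # geodesic label dilation within the support
  repeat {
    todo <- support & lab == 0L
    if (!any(todo)) break
    grew <- FALSE
    for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
      src <- shift_array(lab, off)
      fill <- todo & lab == 0L & src > 0L
      if (any(fill)) { lab[fill] <- src[fill]; grew <- TRUE }
    }
    if (!grew) break  # disconnected support fragments without skeleton
  }
  roi_mask(lab == 1L & support, m$spacing, kind = "support")
}

# shift array contents by an integer offset, zero-filled
shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(0L, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    if (off[k] >= 0) {
      dst[[k]] <- (1 + off[k]):d[k]; src[[k]] <- 1:(d[k] - off[k])
    } else {
      dst[[k]] <- 1:(d[k] + off[k]); src[[k]] <- (1 - off[k]):d[k]
    }
    if (d[k] <= abs(off[k])) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Mean trabecular plate width (Tb.PW)
#'
#' Mean of the tensor-scale plate width over skeleton voxels inside the
#' ROI, reported in micrometers. By default all skeleton voxels are
#' averaged; `plates_only = TRUE` restricts to plate-classified voxels.
#'
#' @param ls a `local_structure`.
#' @param roi a `roi_mask`.
#' @param plates_only average plate-classified voxels only.
#' @param ratio_threshold plate/rod cutoff used when `plates_only`.
#' @return Tb.PW in micrometers.
#' @export
tb_pw <- function(ls, roi, plates_only = FALSE, ratio_threshold = 2) {
  stopifnot(inherits(ls, "local_structure"), inherits(roi, "roi_mask"))
  tab <- ls$table
  inside <- roi$mask[cbind(tab$x, tab$y, tab$z)]
  if (plates_only)
    inside <- inside & classify_plate_rod(ls, ratio_threshold) == "plate"
  if (!any(inside)) abort_bad("no skeleton voxels in ROI", "empty_roi")
  1000 * mean(tab$plate_width_mm[inside])
}
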