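#' Fuzzy bone membership
#'
#' Maps calibrated density to a fuzzy bone membership in `[0, 1]` by a
#' clamped linear ramp: 0 at or below `marrow_ref`, 1 at or above
#' `bone_ref`. At clinical CT resolution individual trabeculae are thinner
#' than a voxel, so their partial-volume densities fall between the two
#' references; the ramp preserves that graded occupancy instead of
#' binarizing it.
#'
#' @param v a `density_volume` in mg/cc.
#' @param marrow_ref density mapped to membership 0 (mg/cc).
#' @param bone_ref density mapped to membership 1 (mg/cc).
#' @return A `membership_volume` (values, spacing, provenance refs).
#' @export
bone_membership <- function(v, marrow_ref = 0, bone_ref = 800) {
  stopifnot(inherits(v, "density_volume"))
  if (bone_ref <= marrow_ref)
    abort_bad("bone_ref must exceed marrow_ref", "config")
  vals <- pmin(1, pmax(0, (v$values - marrow_ref) / (bone_ref - marrow_ref)))
  structure(list(values = array(vals, dim(v$values)), spacing = v$spacing,
                 marrow_ref = marrow_ref, bone_ref = bone_ref),
            class = "membership_volume")
}

#' @export
print.membership_volume <- function(x, ...) {
  cat(sprintf("<membership_volume> %s voxels, support (>=0.5): %d\n",
              paste(dim(x$values), collapse = " x "),
              sum(x$values >= 0.5)))
  invisible(x)
}

#' Fuzzy skeletonization of the trabecular network
#'
#' Computes the fuzzy distance transform (FDT) of the bone membership over
#' its support and erodes the support in increasing FDT order, deleting
#' only simple voxels (the (26,6) topology-preserving test) and retaining
#' fuzzy-medial anchors (voxels with no strictly larger FDT neighbor).
#' Ties in the erosion order are broken by linear voxel index, making the
#' result deterministic. The output is a thin set of medial surfaces and
#' curves; each skeleton voxel carries its membership and FDT value (the
#' local half-thickness).
#'
#' @param m a `membership_volume`.
#' @param support_threshold membership level defining the support that is
#'   thinned (the structure whose topology is preserved).
#' @return A `skeleton_map`: fields `mask` (logical array), `voxels`
#'   (tibble of coordinates, membership, FDT; columns for width and
#'   classes are filled by later stages), `spacing`.
#' @export
fuzzy_skeletonize <- function(m, support_threshold = 0.5) {
  stopifnot(inherits(m, "membership_volume"))
  d <- dim(m$values)
  support <- m$values >= support_threshold
  if (!any(support)) {
    return(structure(list(mask = array(FALSE, d),
                          voxels = tibble::tibble(x = integer(), y = integer(),
                                                  z = integer(),
                                                  membership = numeric(),
                                                  fdt = numeric()),
                          spacing = m$spacing, fdt = array(0, d)),
                     class = "skeleton_map"))
  }
  fdt <- cpp_fdt(as.numeric(m$values), as.logical(support), as.integer(d),
                 as.numeric(m$spacing))
  sk <- array(cpp_fuzzy_thin(as.logical(support), fdt, as.integer(d),
                             as.numeric(m$spacing)), d)
  idx <- which(sk, arr.ind = TRUE)
  lin <- which(sk)
  structure(list(mask = sk,
                 voxels = tibble::tibble(x = idx[, 1], y = idx[, 2],
                                         z = idx[, 3],
                                         membership = m$values[lin],
                                         fdt = fdt[lin]),
                 spacing = m$spacing, fdt = array(fdt, d)),
            class = "skeleton_map")
}

#' @export
print.skeleton_map <- function(x, ...) {
  cat(sprintf("<skeleton_map> %d skeleton voxels\n", nrow(x$voxels)))
  invisible(x)
}

#' Trabecular network area density (Tb.NA)
#'
#' Number of skeleton voxels inside the ROI, expressed as medial-surface
#' area per unit ROI volume: count times the voxel face area (mm^2)
#' divided by the ROI volume (mm^3).
#'
#' @param s a `skeleton_map`.
#' @param roi a `roi_mask` on the same grid.
#' @return Tb.NA in mm^2/mm^3.
#' @export
network_area_density <- function(s, roi) {
  stopifnot(inherits(s, "skeleton_map"), inherits(roi, "roi_mask"))
  if (!any(roi$mask)) abort_bad("empty ROI", "empty_roi")
  if (!all(dim(s$mask) == dim(roi$mask)))
    abort_bad("skeleton and ROI grids differ", "config")
  face_area <- s$spacing[1] * s$spacing[2]
  sum(s$mask & roi$mask) * face_area / roi_volume_mm3(roi)
}
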