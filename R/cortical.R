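#' Cortical bone segmentation at a percent-site band
#'
#' Within an axial band (typically the 14--16% site), the cortical shell
#' is the connected high-density layer between the periosteal surface
#' (the filled-bone boundary) and the endosteal surface. The density
#' threshold selects candidate cortex, the largest connected candidate
#' forms the shell, slice-wise morphological closing regularizes the
#' endosteal boundary and recovers enclosed low-density voxels, and those
#' enclosed voxels (not connected to marrow or background) form the pore
#' mask. Pore components below `min_pore_voxels` are discarded as noise.
#'
#' @param v a `density_volume` in mg/cc.
#' @param filled filled-bone `roi_mask` (defines the periosteal support).
#' @param band axial-band `roi_mask` at the cortical site.
#' @param cortex_threshold density (mg/cc) separating cortex from marrow
#'   and pore space.
#' @param closing_radius_mm slice-wise closing radius used to bridge the
#'   endosteal boundary across pores.
#' @param min_pore_voxels smallest retained pore component.
#' @param max_gap_fraction maximum tolerated fraction of band slices with
#'   no shell before segmentation fails.
#' @return list(cortex = `roi_mask`, pores = `roi_mask`).
#' @export
segment_cortex <- function(v, filled, band, cortex_threshold = 600,
                           closing_radius_mm = 0.6, min_pore_voxels = 2,
                           max_gap_fraction = 0.25) {
  stopifnot(inherits(v, "density_volume"), inherits(filled, "roi_mask"),
            inherits(band, "roi_mask"))
  if (v$units != "mg_cc") abort_bad("volume must be calibrated", "unit")
  h <- v$spacing
  cand <- v$values >= cortex_threshold & filled$mask & band$mask
  if (!any(cand))
    abort_bad("no density contrast above the cortex threshold",
              "segmentation_failure")
  shell <- largest_component(cand, 26L)
  zs <- sort(unique(which(band$mask, arr.ind = TRUE)[, 3]))
  missing <- vapply(zs, function(k) !any(shell[, , k]), logical(1))
  if (mean(missing) > max_gap_fraction)
    abort_bad("cortical shell discontinuous over too many slices",
              "segmentation_failure")
  # slice-wise closing: huge z spacing restricts the Euclidean ball to 2D
  sp2d <- c(h[1:2], 1e9)
  dil <- edt_mm(!shell, sp2d) <= closing_radius_mm
  closed <- dil & edt_mm(dil, sp2d) > closing_radius_mm
  closed <- closed & band$mask & filled$mask
  pores0 <- closed & !shell
  # keep enclosed components: not 6-adjacent to any voxel outside `closed`
  pores <- array(FALSE, dim(closed))
  if (any(pores0)) {
    lab <- label_components(pores0, 6L)
    outside <- !closed & band$mask
    # grow outside by one voxel to detect adjacency
    touch <- array(FALSE, dim(closed))
    for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1)))
      touch <- touch | shift_array(outside + 0L, off) > 0L
    bad <- unique(lab$labels[pores0 & touch])
    keep <- setdiff(seq_along(lab$sizes), bad)
    keep <- keep[lab$sizes[keep] >= min_pore_voxels]
    pores <- array(lab$labels %in% keep, dim(closed)) & pores0
  }
  cortex <- shell & !pores
  list(cortex = roi_mask(cortex, h, kind = "support"),
       pores = roi_mask(pores, h, kind = "support"))
}

#' Cortical thickness (Cb.Th)
#'
#' Local wall thickness of the cortical shell: on each axial slice the 2D
#' Euclidean distance transform of the wall (cortex plus enclosed pores)
#' is ridge-filtered (pixels whose distance is not exceeded by any
#' 8-neighbor beyond a half-voxel tolerance form the medial surface), and
#' Cb.Th is the mean of twice the medial distance, in mm.
#'
#' @param cortex cortical `roi_mask` (from [segment_cortex()]).
#' @param pores optional pore `roi_mask`, included in the wall for
#'   thickness purposes.
#' @return Cb.Th in mm.
#' @export
cortical_thickness <- function(cortex, pores = NULL) {
  stopifnot(inherits(cortex, "roi_mask"))
  wall <- cortex$mask
  if (!is.null(pores)) wall <- wall | pores$mask
  if (!any(wall)) abort_bad("empty cortical shell", "empty_roi")
  h <- cortex$spacing
  dist <- edt_mm(wall, c(h[1:2], 1e9))
  # 2D ridge: local maxima of the slice-wise EDT over the 8-neighborhood
  nmax <- array(0, dim(dist))
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    nmax <- pmax(nmax, shift_array(dist, c(dx, dy, 0)))
  }
  ridge <- wall & dist > 0 & dist >= nmax - 0.5 * min(h[1:2])
  mean(2 * dist[ridge])
}

#' Cortical porosity (Cb.Poro)
#'
#' Pore volume fraction of the cortical wall: pore voxels divided by
#' cortex-plus-pore voxels.
#'
#' @param cortex,pores `roi_mask`s from [segment_cortex()].
#' @return Porosity fraction in `[0, 1]`.
#' @export
cortical_porosity <- function(cortex, pores) {
  stopifnot(inherits(cortex, "roi_mask"), inherits(pores, "roi_mask"))
  nc <- sum(cortex$mask)
  if (nc == 0) abort_bad("empty cortex", "empty_roi")
  np <- sum(pores$mask)
  np / (np + nc)
}
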