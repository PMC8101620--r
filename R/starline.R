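#' Star-line sampling configuration
#'
#' Controls the star-line estimator of trabecular thickness and
#' separation: the number of (deterministic, near-uniform) hemisphere
#' directions, the ray marching step, and the membership cutoff that
#' separates the bone and marrow phases.
#'
#' @param n_directions hemisphere direction count (>= 13).
#' @param sample_step_mm marching step, at most half the voxel size of the
#'   volume it is used on.
#' @param bone_threshold membership cutoff between bone and marrow.
#' @return A `starline_config`.
#' @export
starline_config <- function(n_directions = 49, sample_step_mm = 0.05,
                            bone_threshold = 0.5) {
  if (n_directions < 13)
    abort_bad("at least 13 star-line directions are required", "config")
  structure(list(n_directions = n_directions,
                 sample_step_mm = sample_step_mm,
                 bone_threshold = bone_threshold),
            class = "starline_config")
}

# star-line statistic over one phase: for every phase voxel in the ROI,
# the minimum over directions of the phase-intercept chord through it;
# returns mean chord (mm) and whether the cap was hit
starline_mean_chord <- function(phase_field, spacing, roi, cfg) {
  d <- dim(phase_field)
  if (cfg$sample_step_mm > min(spacing) / 2 + 1e-12)
    abort_bad("sample step must not exceed half a voxel", "config")
  sel <- roi$mask & phase_field >= cfg$bone_threshold
  if (!any(sel)) abort_bad("phase is empty inside the ROI", "empty_roi")
  idx <- which(sel, arr.ind = TRUE)
  ridx <- which(roi$mask, arr.ind = TRUE)
  span <- apply(ridx, 2, function(v) diff(range(v)))
  cap <- sqrt(sum((span * spacing)^2))   # ROI bounding-box diagonal
  dirs <- fibonacci_hemisphere(cfg$n_directions)
  rc <- cpp_cast_rays(as.numeric(phase_field), as.integer(d),
                      as.numeric(spacing), idx - 1, dirs,
                      cfg$sample_step_mm, cap, cfg$bone_threshold)
  chords <- pmin(rc$dpos + rc$dneg, cap)
  per_vox <- apply(chords, 1, min)
  list(mean_mm = mean(per_vox), capped = any(per_vox >= cap - 1e-9),
       cap_mm = cap)
}

#' Trabecular thickness by star lines (Tb.Th)
#'
#' For every bone voxel in the ROI, star lines are cast through it in a
#' near-uniform direction set; the bone-intercept length of the segment
#' containing the voxel is measured in each direction, and the voxel's
#' local thickness is the minimum over directions. Tb.Th is the mean over
#' voxels, in micrometers. Chords are capped at the ROI bounding-box
#' diagonal; a hit cap is reported via the `"capped"` attribute.
#'
#' @param m a `membership_volume`.
#' @param roi a `roi_mask`.
#' @param cfg a [starline_config()].
#' @return Tb.Th in micrometers (attribute `capped` flags degenerate
#'   solid ROIs).
#' @export
tb_th <- function(m, roi, cfg = starline_config()) {
  stopifnot(inherits(m, "membership_volume"), inherits(roi, "roi_mask"))
  res <- starline_mean_chord(m$values, m$spacing, roi, cfg)
  structure(1000 * res$mean_mm, capped = res$capped)
}

#' Trabecular separation by star lines (Tb.Sp)
#'
#' The same star-line statistic applied to the marrow phase
#' (membership below the cutoff): mean over marrow voxels in the ROI of
#' the minimum marrow-intercept chord, in micrometers.
#'
#' @inheritParams tb_th
#' @return Tb.Sp in micrometers (attribute `capped` as in [tb_th()]).
#' @export
tb_sp <- function(m, roi, cfg = starline_config()) {
  stopifnot(inherits(m, "membership_volume"), inherits(roi, "roi_mask"))
  marrow <- 1 - m$values
  cfg2 <- cfg
  cfg2$bone_threshold <- 1 - cfg$bone_threshold
  res <- starline_mean_chord(marrow, m$spacing, roi, cfg2)
  structure(1000 * res$mean_mm, capped = res$capped)
}
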