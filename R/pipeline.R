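#' Pipeline configuration
#'
#' Collects every tunable parameter of the volume-to-measures pipeline
#' with the standard analysis defaults: trabecular measures at the 4--6%
#' distal site over the inner (60% peel) and outer (30--60% peel annulus)
#' regions, cortical measures at the 14--16% site.
#'
#' @param tb_site,cb_site percent-site bands.
#' @param inner_peel inner-region peel percent.
#' @param outer_peel annulus peel band.
#' @param tibial_length_mm nominal tibial length; if `NULL`, estimated as
#'   `0.22 * stature_mm`.
#' @param stature_mm subject stature used for the tibial-length fallback.
#' @param bone_threshold,closing_radii_mm filled-bone parameters (mg/cc,
#'   mm).
#' @param marrow_ref,bone_ref fuzzy-membership density references
#'   (mg/cc).
#' @param support_threshold membership level of the structure support.
#' @param cortex_threshold,cortex_closing_mm cortical segmentation
#'   parameters.
#' @param max_scale_mm,n_directions tensor-scale parameters.
#' @param ratio_threshold plate/rod width-to-thickness cutoff.
#' @param angle_threshold_deg transverse/longitudinal angular cutoff.
#' @param starline a [starline_config()].
#' @param realign_tol_deg axis misalignment above which the volume is
#'   rigidly realigned.
#' @param calibration optional `calibration_line` applied to HU input.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tb_site = c(4, 6), cb_site = c(14, 16),
                            inner_peel = 60, outer_peel = c(30, 60),
                            tibial_length_mm = NULL, stature_mm = 1700,
                            bone_threshold = 400,
                            closing_radii_mm = c(0.3, 0.6),
                            marrow_ref = 0, bone_ref = 800,
                            support_threshold = 0.5,
                            cortex_threshold = 600,
                            cortex_closing_mm = 0.6,
                            max_scale_mm = 3, n_directions = 45,
                            ratio_threshold = 2,
                            angle_threshold_deg = 45,
                            starline = starline_config(),
                            realign_tol_deg = 0.2,
                            calibration = NULL) {
  for (rng in list(tb_site, cb_site, outer_peel))
    if (any(rng < 0 | rng > 100) || rng[1] >= rng[2])
      abort_bad("percent ranges must be increasing within [0, 100]",
                "config")
  if (inner_peel < 0 || inner_peel > 100)
    abort_bad("inner peel must lie in [0, 100]", "config")
  cfg <- list(tb_site = tb_site, cb_site = cb_site,
              inner_peel = inner_peel, outer_peel = outer_peel,
              tibial_length_mm = tibial_length_mm %||% (0.22 * stature_mm),
              bone_threshold = bone_threshold,
              closing_radii_mm = closing_radii_mm,
              marrow_ref = marrow_ref, bone_ref = bone_ref,
              support_threshold = support_threshold,
              cortex_threshold = cortex_threshold,
              cortex_closing_mm = cortex_closing_mm,
              max_scale_mm = max_scale_mm, n_directions = n_directions,
              ratio_threshold = ratio_threshold,
              angle_threshold_deg = angle_threshold_deg,
              starline = starline, realign_tol_deg = realign_tol_deg,
              calibration = calibration)
  structure(cfg, class = "pipeline_config")
}

#' Run the full volume-to-measures pipeline
#'
#' One subject, one run: optional HU calibration, filled-bone
#' segmentation, end-plateau detection, tibial-axis fit with rigid
#' realignment when the axis is tilted, percent-site/percent-peel ROI
#' generation, fuzzy skeletonization, tensor-scale, star-line, digital
#' topology and cortical analysis -- returning the full measure panel
#' (eight trabecular measures over the inner and outer ROIs, two
#' cortical measures) plus a provenance log of every parameter.
#' Deterministic given volume and configuration.
#'
#' @param v a `density_volume` (HU with `config$calibration`, or mg/cc).
#' @param config a [pipeline_config()].
#' @return A `pipeline_result`: `metrics` (long tibble: roi, measure,
#'   value), `frame` (the anatomy frame), `provenance` (parameter list).
#' @export
run_pipeline <- function(v, config = pipeline_config()) {
  stopifnot(inherits(v, "density_volume"),
            inherits(config, "pipeline_config"))
  if (v$units == "HU") {
    if (is.null(config$calibration))
      abort_bad("HU input requires config$calibration", "config")
    v <- apply_calibration(v, config$calibration)
  }
  filled <- fill_bone_volume(v, config$bone_threshold,
                             config$closing_radii_mm)
  plateau <- locate_end_plateau(filled)
  frame <- fit_tibial_axis(filled, plateau, config$tibial_length_mm)
  tilt <- acos(min(1, abs(frame$axis_direction[3]))) * 180 / pi
  if (tilt > config$realign_tol_deg) {
    v <- realign_volume(v, frame, fill = 0)
    # rotate the filled mask with the volume: re-filling the realigned
    # volume would let the (now oblique) proximal cut open the marrow
    # cavity and defeat the cavity fill
    filled <- realign_mask(filled, frame)
    plateau <- locate_end_plateau(filled)
    frame <- fit_tibial_axis(filled, plateau, config$tibial_length_mm)
  }

  roi_inner <- make_axial_roi(frame, filled, config$tb_site,
                              config$inner_peel)
  roi_outer <- make_axial_roi(frame, filled, config$tb_site,
                              config$outer_peel)
  mem <- bone_membership(v, config$marrow_ref, config$bone_ref)
  # trabecular-only membership: cortical wall masked out beyond the 30%
  # peel so skeleton and phases describe the trabecular network
  band <- make_axial_roi(frame, filled, config$tb_site, NULL)
  trab_region <- compute_peel(band, min(config$outer_peel))
  mem_tb <- mem
  mem_tb$values <- mem$values * (trab_region$mask + 0)
  skel <- fuzzy_skeletonize(mem_tb, config$support_threshold)
  ls <- tensor_scale_at(skel, mem_tb, config$max_scale_mm,
                        config$n_directions)
  orient <- classify_orientation(ls, frame, config$angle_threshold_deg,
                                 config$ratio_threshold)
  trans_sup <- propagate_orientation(skel, mem_tb, orient,
                                     support_threshold =
                                       config$support_threshold)
  skel <- dta_classify(skel)

  # marrow phase restricted to the trabecular compartment: outside the
  # compartment the masked membership is zero, which must read as "not
  # marrow" so separation chords terminate at the compartment boundary
  mem_sp <- mem_tb
  mem_sp$values <- 1 - (1 - mem$values) * (trab_region$mask + 0)

  tb_rois <- list(inner = roi_inner, outer = roi_outer)
  rows <- purrr::map_dfr(names(tb_rois), function(nm) {
    roi <- tb_rois[[nm]]
    mem_roi <- mem_tb
    mem_roi$values <- mem_tb$values * (roi$mask + 0)
    vals <- c(
      tb_vbmd = tb_vbmd(v, roi),
      tb_tbmd = tb_tbmd(v, roi, trans_sup),
      tb_na = network_area_density(skel, roi),
      tb_pw = tb_pw(ls, roi),
      tb_th = as.numeric(tb_th(mem_tb, roi, config$starline)),
      tb_sp = as.numeric(tb_sp(mem_sp, roi, config$starline)),
      ei = erosion_index(topo_census(skel, roi)),
      smi = smi(mem_roi))
    tibble::tibble(roi = nm, measure = names(vals), value = unname(vals))
  })

  cb_band <- make_axial_roi(frame, filled, config$cb_site, NULL)
  seg <- segment_cortex(v, filled, cb_band, config$cortex_threshold,
                        config$cortex_closing_mm)
  rows <- dplyr::bind_rows(rows, tibble::tibble(
    roi = "cortical",
    measure = c("cb_poro", "cb_th"),
    value = c(cortical_porosity(seg$cortex, seg$pores),
              cortical_thickness(seg$cortex, seg$pores))))

  structure(list(metrics = rows, frame = frame,
                 provenance = c(unclass(config),
                                list(plateau_slice = frame$plateau_slice,
                                     axis_direction = frame$axis_direction,
                                     realigned = tilt >
                                       config$realign_tol_deg))),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(tidyr::pivot_wider(x$metrics, names_from = "measure",
                           values_from = "value"))
  invisible(x)
}
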