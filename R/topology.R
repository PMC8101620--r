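#' Digital topological classification of a thin skeleton
#'
#' Labels every skeleton voxel by its local topological numbers on the
#' 3x3x3 neighborhood: `xi`, the number of 26-connected object components
#' among the neighbors, and `eta`, the number of 6-connected background
#' components in the 18-neighborhood adjacent to the center. The primary
#' rule table is
#'
#' * no neighbors: `isolated`
#' * one neighbor: `curve_edge`
#' * `eta == 2, xi == 1`: `surface_interior`
#' * `eta >= 3`: `junction_ss` (surface-surface junction)
#' * `eta == 2, xi >= 2`: `junction_sc` (surface-curve junction)
#' * `eta == 1, xi == 2`: `curve_interior`
#' * `eta == 1, xi > 2`: `junction_cc` (curve-curve junction)
#'
#' Remaining border voxels (`eta == 1, xi == 1`) are resolved in a second
#' pass: adjacent to a surface class they become `surface_edge`; with two
#' or more neighbors but no surface contact they are `profile`
#' (residual edge-to-edge voxels); otherwise `curve_edge`.
#'
#' @param s a `skeleton_map` (thin; a voxel with a full 3x3x3 object
#'   neighborhood violates the contract and raises an error).
#' @return The `skeleton_map` with a `topo_class` column added to
#'   `$voxels`.
#' @export
dta_classify <- function(s) {
  stopifnot(inherits(s, "skeleton_map"))
  d <- dim(s$mask)
  if (nrow(s$voxels) == 0) {
    s$voxels$topo_class <- character(0)
    return(s)
  }
  tn <- cpp_topo_numbers(as.logical(s$mask), as.integer(d))
  lin <- which(s$mask)
  nnbr <- tn$nnbr[lin]; xi <- tn$xi[lin]; eta <- tn$eta_all[lin]
  if (any(nnbr == 26))
    abort_bad("skeleton is not thin: voxel with full 3x3x3 neighborhood",
              "contract")
  cls <- rep(NA_character_, length(lin))
  cls[nnbr == 0] <- "isolated"
  cls[is.na(cls) & nnbr == 1] <- "curve_edge"
  cls[is.na(cls) & eta >= 3] <- "junction_ss"
  cls[is.na(cls) & eta == 2 & xi == 1] <- "surface_interior"
  cls[is.na(cls) & eta == 2 & xi >= 2] <- "junction_sc"
  cls[is.na(cls) & eta == 1 & xi == 2] <- "curve_interior"
  cls[is.na(cls) & eta == 1 & xi > 2] <- "junction_cc"
  # second pass: resolve remaining border voxels (eta == 1, xi == 1).
  # Iterated to a fixpoint so staircase chains of an oblique digital
  # surface absorb into surface_edge instead of stranding as profile.
  border <- which(is.na(cls))
  if (length(border)) {
    surfaceish <- array(FALSE, d)
    surfaceish[lin[cls %in% c("surface_interior", "junction_ss",
                              "junction_sc")]] <- TRUE
    idx <- arrayInd(lin[border], d)
    pending <- rep(TRUE, length(border))
    repeat {
      touches <- vapply(which(pending), function(k) {
        i <- idx[k, ]
        any(surfaceish[max(1, i[1] - 1):min(d[1], i[1] + 1),
                       max(1, i[2] - 1):min(d[2], i[2] + 1),
                       max(1, i[3] - 1):min(d[3], i[3] + 1)])
      }, logical(1))
      hit <- which(pending)[touches]
      if (length(hit) == 0) break
      cls[border[hit]] <- "surface_edge"
      surfaceish[lin[border[hit]]] <- TRUE
      pending[hit] <- FALSE
      if (!any(pending)) break
    }
    rest <- border[pending]
    cls[rest] <- ifelse(nnbr[rest] >= 2, "profile", "curve_edge")
  }
  s$voxels$topo_class <- cls
  s
}

#' Topological census over an ROI
#'
#' Counts skeleton voxels of each topological class inside the ROI.
#'
#' @param s a classified `skeleton_map` (see [dta_classify()]).
#' @param roi optional `roi_mask`; default counts the whole skeleton.
#' @return A tibble of class counts.
#' @export
topo_census <- function(s, roi = NULL) {
  stopifnot(inherits(s, "skeleton_map"))
  if (is.null(s$voxels$topo_class))
    abort_bad("run dta_classify() first", "config")
  tab <- s$voxels
  if (!is.null(roi)) tab <- tab[roi$mask[cbind(tab$x, tab$y, tab$z)], ]
  lev <- c("surface_interior", "surface_edge", "junction_ss", "junction_sc",
           "curve_interior", "curve_edge", "junction_cc", "profile",
           "isolated")
  cnt <- table(factor(tab$topo_class, levels = lev))
  tibble::tibble(topo_class = lev, count = as.integer(cnt))
}

#' Erosion index (EI)
#'
#' Ratio of curve-like to surface-like topological classes of the
#' trabecular skeleton; erosion of plates into rods raises it. The
#' default composition is numerator `curve_interior + curve_edge +
#' junction_cc + profile + isolated`, denominator `surface_interior +
#' surface_edge + junction_ss + junction_sc`; both are configurable.
#'
#' @param census a census tibble from [topo_census()].
#' @param numerator,denominator class name sets.
#' @return EI (unitless). A zero denominator returns `Inf` with a
#'   warning.
#' @export
erosion_index <- function(census,
                          numerator = c("curve_interior", "curve_edge",
                                        "junction_cc", "profile",
                                        "isolated"),
                          denominator = c("surface_interior",
                                          "surface_edge", "junction_ss",
                                          "junction_sc")) {
  num <- sum(census$count[census$topo_class %in% numerator])
  den <- sum(census$count[census$topo_class %in% denominator])
  if (den == 0) {
    rlang::warn("no surface-class voxels: erosion index is infinite")
    return(Inf)
  }
  num / den
}

#' Structure model index (SMI)
#'
#' Simulated-thickening estimate of how plate-like versus rod-like a
#' structure is: with `V` the structure volume, `S` its surface area and
#' `S'` the derivative of surface area under a uniform outward offset of
#' the surface, `SMI = 6 V S' / S^2` (0 for ideal plates, 3 for
#' cylinders, 4 for spheres). The offset family is realized through the
#' signed Euclidean distance field of the thresholded structure: the
#' volume `V(r)` enclosed by the offset surface at distance `r` is
#' counted for a ladder of offsets, a quadratic is fitted to `V(r)`, and
#' `S = V'(0)`, `S' = V''(0)` are read off the fit.
#'
#' @param m a `membership_volume` (structure = membership >= `level`).
#' @param dr_mm offset ladder step (mm); default a quarter voxel.
#' @param level membership threshold defining the structure.
#' @param n_steps half-width of the offset ladder, in steps.
#' @return SMI (unitless).
#' @export
smi <- function(m, dr_mm = NULL, level = 0.5, n_steps = 16) {
  stopifnot(inherits(m, "membership_volume"))
  mask <- m$values >= level
  if (!any(mask)) abort_bad("empty structure", "empty_roi")
  h <- m$spacing
  dr <- dr_mm %||% (min(h) / 4)
  phi <- signed_distance(m$values, level, h)
  voxvol <- prod(h)
  rs <- seq(-n_steps, n_steps) * dr
  # subvoxel volume of the offset body: each voxel contributes the fraction
  # of its (unit-gradient) distance interval below the offset, which turns
  # the voxel-count staircase into a piecewise-linear estimate
  hmin <- min(h)
  V <- vapply(rs, function(r)
    sum(pmin(1, pmax(0, (r - phi) / hmin + 0.5))) * voxvol, numeric(1))
  fit <- lm(V ~ r + I(r^2), data = data.frame(r = rs, V = V))
  co <- coef(fit)
  V0 <- unname(co[1]); S <- unname(co[2]); Sp <- 2 * unname(co[3])
  if (S <= 0) abort_bad("degenerate surface-area estimate", "degenerate")
  6 * V0 * Sp / S^2
}

# subvoxel-accurate signed distance to the `level` set of a fuzzy field.
# Wherever a face-neighbor pair straddles the level, the crossing position
# along that axis is located by linear interpolation of the field; each
# straddling voxel combines its per-axis crossing distances t_a in
# Eikonal-consistent form d = 1 / sqrt(sum 1/t_a^2) and is used as a seed
# for chamfer Dijkstra propagation on its side of the surface. Comparisons
# stay strictly in-bounds (the array edge is a cut, not a boundary).
# Negative inside (f >= level), positive outside.
signed_distance <- function(f, level, h) {
  d <- dim(f)
  mask <- f >= level
  acc <- array(0, d)       # sum of 1 / t_a^2 per voxel
  add_axis <- function(acc, axis) {
    ha <- h[axis]
    # slices of the leading/trailing faces along `axis`
    lead <- switch(axis,
                   list(-d[1], TRUE, TRUE), list(TRUE, -d[2], TRUE),
                   list(TRUE, TRUE, -d[3]))
    trail <- switch(axis,
                    list(-1, TRUE, TRUE), list(TRUE, -1, TRUE),
                    list(TRUE, TRUE, -1))
    fa <- do.call(`[`, c(list(f), lead, list(drop = FALSE)))
    fb <- do.call(`[`, c(list(f), trail, list(drop = FALSE)))
    cross <- (fa >= level) != (fb >= level)
    if (!any(cross)) return(acc)
    t_a <- abs(fa - level) / pmax(abs(fa - fb), 1e-12) * ha
    t_b <- ha - t_a
    t_a <- pmax(t_a, ha / 100); t_b <- pmax(t_b, ha / 100)
    inv_a <- array(0, dim(fa)); inv_b <- array(0, dim(fb))
    inv_a[cross] <- 1 / t_a[cross]^2
    inv_b[cross] <- 1 / t_b[cross]^2
    accA <- do.call(`[`, c(list(acc), lead, list(drop = FALSE))) + inv_a
    acc <- do.call(`[<-`, c(list(acc), lead, list(accA)))
    accB <- do.call(`[`, c(list(acc), trail, list(drop = FALSE))) + inv_b
    do.call(`[<-`, c(list(acc), trail, list(accB)))
  }
  for (axis in 1:3) acc <- add_axis(acc, axis)
  crosses <- acc > 0
  seed_d <- array(Inf, d)
  seed_d[crosses] <- 1 / sqrt(acc[crosses])
  run_side <- function(side_mask) {
    seeds <- which(crosses & side_mask) - 1L
    if (length(seeds) == 0) return(array(Inf, d))
    array(cpp_geodesic_dist(as.logical(side_mask), as.integer(d),
                            as.numeric(h), as.integer(seeds),
                            as.numeric(seed_d)[seeds + 1L]), d)
  }
  d_in <- run_side(mask)
  d_out <- run_side(!mask)
  phi <- ifelse(mask, -d_in, d_out)
  # voxels unreachable on their side (isolated pockets): half-voxel offset
  hmax <- max(h)
  phi[!is.finite(phi) & mask] <- -hmax / 2
  phi[!is.finite(phi) & !mask] <- hmax / 2
  phi
}
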