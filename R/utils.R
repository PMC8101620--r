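# shared internal helpers

abort_bad <- function(msg, class) {
  rlang::abort(msg, class = paste0("bonemicro_", class))
}

# physical coordinates (mm) of voxel centers along one axis, origin at the
# center of voxel 1
axis_coords <- function(n, h) (seq_len(n) - 1) * h

# vectorized trilinear interpolation of a 3D array at physical points
# (rows of `pts`, mm, voxel 1 center at 0); out-of-bounds -> fill
interp_trilinear <- function(arr, pts, spacing, fill = 0) {
  d <- dim(arr)
  g <- sweep(pts, 2, spacing, "/")
  i0 <- floor(g)
  f <- g - i0
  ok <- i0[, 1] >= 0 & i0[, 2] >= 0 & i0[, 3] >= 0 &
    i0[, 1] <= d[1] - 2 & i0[, 2] <= d[2] - 2 & i0[, 3] <= d[3] - 2
  out <- rep(fill, nrow(pts))
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE] + 1L
  fx <- f[ok, 1]; fy <- f[ok, 2]; fz <- f[ok, 3]
  at <- function(a, b, c) arr[cbind(i0[, 1] + a, i0[, 2] + b, i0[, 3] + c)]
  v <-
    at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    at(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    at(1, 1, 0) * fx * fy * (1 - fz) +
    at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    at(1, 0, 1) * fx * (1 - fy) * fz +
    at(0, 1, 1) * (1 - fx) * fy * fz +
    at(1, 1, 1) * fx * fy * fz
  out[ok] <- v
  out
}

# deterministic near-uniform directions on the upper hemisphere
# (spherical Fibonacci lattice)
fibonacci_hemisphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- i / n                       # cos(theta) in (0, 1): upper hemisphere
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# rotation matrix sending unit vector `from` onto unit vector `to`
rotation_between <- function(from, to) {
  from <- from / sqrt(sum(from^2))
  to <- to / sqrt(sum(to^2))
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  c_ <- sum(from * to)
  if (abs(c_ + 1) < 1e-12) {
    # antipodal: rotate pi about any axis orthogonal to `from`
    ax <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ax - sum(ax * from) * from
    v <- v / sqrt(sum(v^2))
    return(2 * tcrossprod(v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# Euclidean distance (mm) to the nearest FALSE voxel, array in / array out
edt_mm <- function(mask, spacing) {
  d <- dim(mask)
  array(sqrt(cpp_edt_sq(as.logical(mask), as.integer(d),
                        as.numeric(spacing))), d)
}

# connected components; returns list(labels = array, sizes)
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  res <- cpp_label(as.logical(mask), as.integer(d), as.integer(connectivity))
  list(labels = array(res$labels, d), sizes = res$sizes)
}

largest_component <- function(mask, connectivity = 26L) {
  lab <- label_components(mask, connectivity)
  if (length(lab$sizes) == 0) return(mask & FALSE)
  lab$labels == which.max(lab$sizes)
}

# binary closing by a Euclidean ball of radius r (mm) via distance
# transforms: dilate (background within r of the mask joins), then erode
# (keep voxels deeper than r inside the dilated set)
morph_close <- function(mask, r_mm, spacing) {
  if (r_mm <= 0) return(mask)
  dil <- edt_mm(!mask, spacing) <= r_mm
  dil & edt_mm(dil, spacing) > r_mm
}
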