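# Internal geometry and misc helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v^2))

normalize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalise a zero-length vector", call. = FALSE)
  v / n
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Angle between two vectors in degrees
#'
#' Numerically safe arccos of the dot product of the normalised vectors,
#' clamped to \[0, 180\].
#'
#' @param a,b numeric 3-vectors (any nonzero length).
#' @return angle in degrees, in \[0, 180\].
#' @export
angle_between <- function(a, b) {
  ct <- sum(normalize(a) * normalize(b))
  rad2deg(acos(min(1, max(-1, ct))))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Axis coordinate vectors (mm, voxel centres) of a gridded volume.
voxel_axes <- function(x) {
  d <- dim(x$labels %||% x$sigma)
  lapply(1:3, function(a) x$origin_mm[a] + (seq_len(d[a]) - 1) * x$voxel_size_mm)
}

# Linear indices of voxels whose centres lie within `radius` of `center`
# (closed ball, voxel-centre containment). Restricted to the grid; optionally
# to a set of label codes.
sphere_indices <- function(vol, center_mm, radius_mm, codes = NULL) {
  d <- dim(vol$labels)
  h <- vol$voxel_size_mm
  ax <- voxel_axes(vol)
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, as.integer(ceiling((center_mm[a] - radius_mm - vol$origin_mm[a]) / h)) + 1L)
    hi <- min(d[a], as.integer(floor((center_mm[a] + radius_mm - vol$origin_mm[a]) / h)) + 1L)
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(lengths(rng) == 0)) return(integer(0))
  xs <- ax[[1]][rng[[1]]] - center_mm[1]
  ys <- ax[[2]][rng[[2]]] - center_mm[2]
  zs <- ax[[3]][rng[[3]]] - center_mm[3]
  d2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  keep <- d2 <= radius_mm^2 + 1e-9
  if (!any(keep)) return(integer(0))
  ii <- rep(rng[[1]], times = length(rng[[2]]) * length(rng[[3]]))
  jj <- rep(rep(rng[[2]], each = length(rng[[1]])), times = length(rng[[3]]))
  kk <- rep(rng[[3]], each = length(rng[[1]]) * length(rng[[2]]))
  lin <- (ii + (jj - 1L) * d[1] + (kk - 1L) * d[1] * d[2])[keep]
  if (!is.null(codes)) lin <- lin[vol$labels[lin] %in% codes]
  lin
}

# Number of voxel centres inside a ball of `radius` on an unbounded lattice
# aligned with the grid (denominator of the lesion volume fraction: the
# "maximum potential volume" is not clipped by the grid bounds).
sphere_lattice_count <- function(vol, center_mm, radius_mm) {
  h <- vol$voxel_size_mm
  off <- lapply(1:3, function(a) {
    # lattice coordinates along axis a, extended beyond the grid if needed
    k <- seq(floor((center_mm[a] - radius_mm - vol$origin_mm[a]) / h),
             ceiling((center_mm[a] + radius_mm - vol$origin_mm[a]) / h))
    vol$origin_mm[a] + k * h - center_mm[a]
  })
  d2 <- outer(outer(off[[1]]^2, off[[2]]^2, "+"), off[[3]]^2, "+")
  sum(d2 <= radius_mm^2 + 1e-9)
}

# Nearest voxel (i, j, k) of a world point; NA if outside the grid.
point_to_ijk <- function(vol, p) {
  d <- dim(vol$labels %||% vol$sigma)
  ijk <- as.integer(round((p - vol$origin_mm) / vol$voxel_size_mm)) + 1L
  if (any(ijk < 1L) || any(ijk > d)) return(rep(NA_integer_, 3))
  ijk
}

point_to_linear <- function(vol, p) {
  d <- dim(vol$labels %||% vol$sigma)
  ijk <- point_to_ijk(vol, p)
  if (anyNA(ijk)) return(NA_integer_)
  ijk[1] + (ijk[2] - 1L) * d[1] + (ijk[3] - 1L) * d[1] * d[2]
}
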