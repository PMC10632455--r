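# Factorial generation of spherical lesion states relative to a cortical ROI:
# 14 directions x 3 edge-to-edge distances x 3 radii x 5 conductivities.

.LESION_DIRECTIONS <- c("R", "L", "A", "P", "S", "I",
                        "RAS", "RAI", "RPS", "RPI", "LAS", "LAI", "LPS", "LPI")

#' The 14 lesion direction labels
#'
#' Six cardinal directions (right, left, anterior, posterior, superior,
#' inferior) plus the eight intercardinal diagonals.
#'
#' @return character vector of length 14.
#' @export
lesion_directions <- function() .LESION_DIRECTIONS

#' Unit vector of a lesion direction label
#'
#' Cardinal labels map to signed RAS unit axes (R = +x, A = +y, S = +z);
#' intercardinal labels map to the normalised sum of their three signed axes,
#' e.g. RAS = (1,1,1)/sqrt(3).
#'
#' @param label one of [lesion_directions()].
#' @return unit 3-vector.
#' @export
direction_vector <- function(label) {
  if (!(label %in% .LESION_DIRECTIONS))
    stop("parameter error: unknown direction label: ", label, call. = FALSE)
  axes <- list(R = c(1, 0, 0), L = c(-1, 0, 0),
               A = c(0, 1, 0), P = c(0, -1, 0),
               S = c(0, 0, 1), I = c(0, 0, -1))
  parts <- strsplit(label, "")[[1]]
  normalize(Reduce(`+`, axes[parts]))
}

#' Default factorial grids for lesion states
#'
#' Edge-to-edge ROI-lesion distances 1/5/10 mm, radii 4/12/24 mm and
#' conductivities 0.2/0.6/1.0/1.4/1.8 S/m, spanning roughly grey-matter
#' conductivity up to above that of CSF.
#'
#' @return list with `directions`, `gap_mm`, `radius_mm`,
#'   `conductivity_S_per_m`.
#' @export
default_lesion_grid <- function() {
  list(directions = .LESION_DIRECTIONS,
       gap_mm = c(1, 5, 10),
       radius_mm = c(4, 12, 24),
       conductivity_S_per_m = c(0.2, 0.6, 1.0, 1.4, 1.8))
}

#' Lesion centre for a given ROI, direction and edge-to-edge distance
#'
#' The centre is displaced from the ROI centre along the direction vector by
#' ROI radius + gap + lesion radius, so the shortest Euclidean edge-to-edge
#' distance between the two spheres equals the gap exactly.
#'
#' @param roi a `spherical_roi`.
#' @param direction_label one of [lesion_directions()].
#' @param gap_mm edge-to-edge distance in mm.
#' @param radius_mm lesion radius in mm.
#' @return centre as a 3-vector (mm).
#' @export
place_lesion <- function(roi, direction_label, gap_mm, radius_mm) {
  if (gap_mm <= 0 || radius_mm <= 0)
    stop("parameter error: gap and radius must be positive", call. = FALSE)
  roi$center_mm + direction_vector(direction_label) *
    (roi$radius_mm + gap_mm + radius_mm)
}

#' Rasterise a spherical lesion constrained to grey and white matter
#'
#' Voxel membership is by voxel-centre containment. The volume fraction is
#' the number of in-brain voxels divided by the voxel count of the
#' unconstrained sphere on the same (unbounded) lattice, i.e. the fraction of
#' the maximum potential lesion volume realised inside grey + white matter.
#'
#' @param phantom a `label_volume`.
#' @param center_mm lesion centre (mm).
#' @param radius_mm lesion radius (mm); must be at least half a voxel.
#' @return list with `mask` (linear voxel indices), `volume_fraction`.
#' @export
rasterize_lesion <- function(phantom, center_mm, radius_mm) {
  if (radius_mm < phantom$voxel_size_mm / 2)
    stop("degenerate lesion: radius smaller than half a voxel", call. = FALSE)
  codes <- c(label_code(phantom, "gm"), label_code(phantom, "wm"))
  mask <- sphere_indices(phantom, center_mm, radius_mm, codes)
  full <- sphere_lattice_count(phantom, center_mm, radius_mm)
  list(mask = mask,
       volume_fraction = if (full > 0) length(mask) / full else 0)
}

#' Validate a rasterised lesion state
#'
#' A state is excluded if the lesion centre falls outside the brain (grey +
#' white matter) or if less than 20% of the maximum potential lesion volume
#' lies within the brain. The 20% threshold is inclusive ("at least 20%").
#'
#' @param phantom a `label_volume`.
#' @param center_mm lesion centre (mm).
#' @param volume_fraction realised fraction from [rasterize_lesion()].
#' @param min_volume_fraction exclusion threshold (default 0.20).
#' @return list with `valid` flag and `exclusion_reason` (one of "none",
#'   "centre_outside_brain", "volume_below_threshold").
#' @export
validate_lesion <- function(phantom, center_mm, volume_fraction,
                            min_volume_fraction = 0.20) {
  lin <- point_to_linear(phantom, center_mm)
  in_brain <- !is.na(lin) && brain_mask(phantom)[lin]
  if (!in_brain)
    return(list(valid = FALSE, exclusion_reason = "centre_outside_brain"))
  if (volume_fraction < min_volume_fraction)
    return(list(valid = FALSE, exclusion_reason = "volume_below_threshold"))
  list(valid = TRUE, exclusion_reason = "none")
}

#' Enumerate the full factorial of lesion states for one ROI
#'
#' Iterates direction, then distance, then radius, then conductivity (the
#' documented deterministic order), rasterising and validating each geometry
#' once; the conductivity variants of a geometry share the identical mask.
#' With the default grids this yields 14 x 3 x 3 x 5 = 630 states per ROI.
#'
#' @param phantom a `label_volume`.
#' @param roi a `spherical_roi`.
#' @param grid factorial grids as from [default_lesion_grid()].
#' @return a `lesion_states` object: data frame `states` (one row per state:
#'   spec fields, centre, volume fraction, validity, geometry id) plus a list
#'   `masks` of shared voxel masks keyed by geometry id.
#' @export
enumerate_states <- function(phantom, roi, grid = default_lesion_grid()) {
  if (!all(lengths(grid) > 0)) stop("grids must be nonempty", call. = FALSE)
  geoms <- expand.grid(radius_mm = grid$radius_mm, gap_mm = grid$gap_mm,
                       direction = grid$directions,
                       stringsAsFactors = FALSE)[, c("direction", "gap_mm", "radius_mm")]
  # expand.grid varies its first factor fastest; reorder columns and rows so
  # direction is the slowest loop, then gap, then radius
  geoms <- geoms[order(match(geoms$direction, grid$directions),
                       geoms$gap_mm, geoms$radius_mm), ]
  masks <- vector("list", nrow(geoms))
  rows <- vector("list", nrow(geoms))
  for (g in seq_len(nrow(geoms))) {
    dir <- geoms$direction[g]; gap <- geoms$gap_mm[g]; rad <- geoms$radius_mm[g]
    ctr <- place_lesion(roi, dir, gap, rad)
    ras <- rasterize_lesion(phantom, ctr, rad)
    val <- validate_lesion(phantom, ctr, ras$volume_fraction)
    masks[[g]] <- ras$mask
    rows[[g]] <- data.frame(
      direction = dir, gap_mm = gap, radius_mm = rad,
      conductivity_S_per_m = grid$conductivity_S_per_m,
      center_x = ctr[1], center_y = ctr[2], center_z = ctr[3],
      volume_fraction = ras$volume_fraction,
      valid = val$valid, exclusion_reason = val$exclusion_reason,
      geom_id = g, stringsAsFactors = FALSE)
  }
  states <- do.call(rbind, rows)
  rownames(states) <- NULL
  structure(list(states = states, masks = masks, roi = roi),
            class = "lesion_states")
}

#' @export
print.lesion_states <- function(x, ...) {
  s <- x$states
  cat("<lesion_states> ", nrow(s), " states (",
      sum(s$valid), " valid, ", sum(!s$valid), " excluded)\n", sep = "")
  if (any(!s$valid)) print(table(s$exclusion_reason[!s$valid]))
  invisible(x)
}

#' Export a lesion-state table to CSV
#'
#' One row per state with the specification fields, centre coordinates,
#' volume fraction, validity flag and exclusion reason.
#'
#' @param x a `lesion_states` object.
#' @param path output file path.
#' @export
write_lesion_states <- function(x, path) {
  utils::write.csv(x$states[, setdiff(names(x$states), "geom_id")],
                   path, row.names = FALSE)
  invisible(path)
}
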