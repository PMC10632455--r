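# Individualising tDCS on the phantom: exhaustive bipolar montage search under
# a magnitude or radial-inward objective, and stimulator-output adjustment.

#' Deterministic candidate electrode positions on the scalp
#'
#' Quasi-uniform Fibonacci-spiral sampling of the scalp cap above a latitude
#' cutoff, standing in for a high-density electrode coordinate system on
#' phantoms without fiducials. The sequence is deterministic and indexed in a
#' fixed order.
#'
#' @param n number of positions (at least 8).
#' @param phantom a `label_volume` (for the scalp radius).
#' @param lat_cutoff_deg lowest latitude of the cap in degrees (default -30;
#'   90 is the vertex, 0 the equator).
#' @return matrix `n x 3` of scalp positions in mm, with attributes
#'   `theta_deg` and `phi_deg`.
#' @export
candidate_positions <- function(n, phantom, lat_cutoff_deg = -30) {
  if (n < 8) stop("parameter error: need at least 8 candidates", call. = FALSE)
  r <- scalp_radius(phantom)
  z_min <- sin(deg2rad(lat_cutoff_deg))
  k <- seq_len(n)
  z <- 1 - (k - 0.5) / n * (1 - z_min)
  golden <- pi * (3 - sqrt(5))
  phi <- (k - 1) * golden
  s <- sqrt(pmax(1 - z^2, 0))
  pos <- r * cbind(s * cos(phi), s * sin(phi), z)
  structure(pos,
            theta_deg = rad2deg(acos(pmin(1, pmax(-1, z)))),
            phi_deg = rad2deg(atan2(sin(phi), cos(phi))))
}

#' Mean radial-inward E-field component over the ROI grey matter
#'
#' Signed mean over the ROI grey-matter voxels of the dot product between the
#' E-field vector and the inward cortical normal. On the spherical phantom
#' the inward normal at a voxel is minus its radial unit vector; for
#' user-supplied volumes explicit normals can be passed.
#'
#' @param solution a solved `field_solution`.
#' @param roi a `spherical_roi`.
#' @param normals optional function mapping an `n x 3` matrix of voxel
#'   positions (mm) to inward unit normals (same shape).
#' @return mean inward component in V/m (positive = net inward current).
#' @export
objective_radial_inward <- function(solution, roi, normals = NULL) {
  vox <- roi_gm_indices(solution, roi)
  if (!length(vox))
    stop("geometry error: ROI contains no grey-matter voxels", call. = FALSE)
  d <- dim(solution$labels)
  ijk <- arrayInd(vox, d)
  xyz <- sweep((ijk - 1) * solution$voxel_size_mm, 2, -solution$origin_mm)
  nrm <- if (is.null(normals)) -xyz / sqrt(rowSums(xyz^2)) else normals(xyz)
  ev <- cbind(solution$efield$x[vox], solution$efield$y[vox],
              solution$efield$z[vox])
  mean(rowSums(ev * nrm))
}

#' Mean E-field magnitude over the ROI grey matter
#'
#' @inheritParams objective_radial_inward
#' @return mean magnitude in V/m.
#' @export
objective_magnitude <- function(solution, roi) {
  vox <- roi_gm_indices(solution, roi)
  if (!length(vox))
    stop("geometry error: ROI contains no grey-matter voxels", call. = FALSE)
  mean(solution$magnitude[vox])
}

#' Exhaustive bipolar montage search
#'
#' Evaluates every ordered anode/cathode pair from the candidate set at a
#' fixed stimulator output, solving the field for each, and returns the pair
#' maximising the objective. Ties are broken by the lowest (anode index,
#' cathode index); pairs whose discs cannot be placed or whose solve fails are
#' skipped and counted.
#'
#' @param phantom a `label_volume` without electrodes.
#' @param candidates candidate position matrix from [candidate_positions()].
#' @param roi a `spherical_roi`.
#' @param objective `"magnitude"` or `"radial_inward"`.
#' @param current_mA stimulator output (default 1).
#' @param table conductivity table.
#' @param disc_radius_mm,thickness_mm electrode geometry.
#' @param tolerance,maxit solver settings.
#' @param leaderboard if `TRUE`, keep the per-pair objective table.
#' @return a `montage_result`: anode/cathode indices and positions, objective
#'   name and value, ROI mean magnitude of the winning solve, number of pairs
#'   evaluated and skipped, and optionally the leaderboard.
#' @export
optimise_montage <- function(phantom, candidates, roi,
                             objective = c("magnitude", "radial_inward"),
                             current_mA = 1,
                             table = default_conductivities(),
                             disc_radius_mm = 17, thickness_mm = 2,
                             tolerance = 1e-8, maxit = NULL,
                             leaderboard = TRUE) {
  objective <- match.arg(objective)
  n <- nrow(candidates)
  if (n < 2) stop("parameter error: need at least 2 candidates", call. = FALSE)
  pairs <- expand.grid(cathode = seq_len(n), anode = seq_len(n))[, c("anode", "cathode")]
  pairs <- pairs[pairs$anode != pairs$cathode, ]
  pairs <- pairs[order(pairs$anode, pairs$cathode), ]
  best <- NULL
  rows <- vector("list", nrow(pairs))
  evaluated <- 0L; skipped <- 0L
  first_solution <- TRUE
  for (p in seq_len(nrow(pairs))) {
    ia <- pairs$anode[p]; ic <- pairs$cathode[p]
    val <- tryCatch({
      montage <- list(
        electrode_at_point(candidates[ia, ], current_mA,
                           disc_radius_mm, thickness_mm),
        electrode_at_point(candidates[ic, ], -current_mA,
                           disc_radius_mm, thickness_mm))
      lv <- place_electrodes(phantom, montage)
      cond <- assign_conductivity(lv, table)
      sol <- solve_tdcs(cond, tolerance = tolerance, maxit = maxit,
                        check_connected = first_solution)
      first_solution <- FALSE
      obj <- switch(objective,
                    magnitude = objective_magnitude(sol, roi),
                    radial_inward = objective_radial_inward(sol, roi))
      list(obj = obj, roi_mean = objective_magnitude(sol, roi))
    }, error = function(e) e)
    if (inherits(val, "error")) {
      skipped <- skipped + 1L
      rows[[p]] <- data.frame(anode = ia, cathode = ic, objective = NA_real_,
                              roi_mean_mag = NA_real_)
      next
    }
    evaluated <- evaluated + 1L
    rows[[p]] <- data.frame(anode = ia, cathode = ic, objective = val$obj,
                            roi_mean_mag = val$roi_mean)
    if (is.null(best) || val$obj > best$objective_value)
      best <- list(anode = ia, cathode = ic, objective_value = val$obj,
                   roi_mean_mag = val$roi_mean)
  }
  if (is.null(best))
    stop("optimisation failed: no candidate pair could be evaluated", call. = FALSE)
  if (skipped > 0)
    warning(skipped, " candidate pair(s) skipped", call. = FALSE)
  structure(list(anode_index = best$anode, cathode_index = best$cathode,
                 anode_position = candidates[best$anode, ],
                 cathode_position = candidates[best$cathode, ],
                 objective_name = objective,
                 objective_value = best$objective_value,
                 roi_mean_mag = best$roi_mean_mag,
                 evaluated_count = evaluated, skipped_count = skipped,
                 leaderboard = if (leaderboard) do.call(rbind, rows)),
            class = "montage_result")
}

#' @export
print.montage_result <- function(x, ...) {
  cat(sprintf("<montage_result> %s objective %.4g V/m; anode #%d, cathode #%d (%d pairs evaluated, %d skipped)\n",
              x$objective_name, x$objective_value, x$anode_index,
              x$cathode_index, x$evaluated_count, x$skipped_count))
  invisible(x)
}

#' Individualise the stimulator output
#'
#' individualised dose = (target E-field magnitude / actual E-field
#' magnitude) x fixed dose. By solver linearity, re-solving at the
#' individualised dose delivers the target ROI magnitude. The dose is capped
#' at a configurable safety limit.
#'
#' @param target_mag,actual_mag ROI mean E-field magnitudes in V/m.
#' @param fixed_dose_mA the fixed reference dose (default 1 mA).
#' @param safety_cap_mA per-electrode current cap (default 4 mA).
#' @return a `dose_adjustment` with `individualised_dose_mA` and a `capped`
#'   flag.
#' @export
individualise_dose <- function(target_mag, actual_mag, fixed_dose_mA = 1,
                               safety_cap_mA = 4) {
  if (any(c(target_mag, actual_mag, fixed_dose_mA) <= 0))
    stop("parameter error: all dose inputs must be positive", call. = FALSE)
  dose <- (target_mag / actual_mag) * fixed_dose_mA
  capped <- dose > safety_cap_mA
  structure(list(target_mag = target_mag, actual_mag = actual_mag,
                 fixed_dose_mA = fixed_dose_mA,
                 individualised_dose_mA = if (capped) safety_cap_mA else dose,
                 uncapped_dose_mA = dose, capped = capped),
            class = "dose_adjustment")
}

#' @export
print.dose_adjustment <- function(x, ...) {
  cat(sprintf("<dose_adjustment> %.3g mA (target %.4g / actual %.4g V/m at %.3g mA)%s\n",
              x$individualised_dose_mA, x$target_mag, x$actual_mag,
              x$fixed_dose_mA, if (x$capped) " [capped]" else ""))
  invisible(x)
}
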