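# Orchestration of the factorial lesion experiment: baseline + lesioned
# solves, the per-state results table, trend models and summaries.

#' Default bipolar montage for a target direction
#'
#' Places the anode and cathode on a great circle through the target scalp
#' direction, by default 40 degrees to one side and 80 degrees to the other.
#' On a smooth spherical phantom an anode directly over the target yields an
#' almost purely radial field; clinical montages on real heads produce a
#' largely tangential field at the target, and this straddling, asymmetric
#' placement emulates that, giving the lesion-angle variable coverage over
#' most of 0--180 degrees.
#'
#' @param roi_direction unit 3-vector of the target scalp direction.
#' @param anode_offset_deg,cathode_offset_deg great-circle offsets from the
#'   target (defaults 40 and 80 degrees, opposite sides).
#' @param current_mA stimulator output (default 1).
#' @param tangent_hint vector whose tangential component sets the montage
#'   axis (default (1,1,0)).
#' @param disc_radius_mm,thickness_mm electrode geometry.
#' @return list of two [electrode()] descriptions (anode first).
#' @export
montage_for_roi <- function(roi_direction, anode_offset_deg = 40,
                            cathode_offset_deg = 80, current_mA = 1,
                            tangent_hint = c(1, 1, 0),
                            disc_radius_mm = 17, thickness_mm = 2) {
  u <- normalize(roi_direction)
  t_raw <- tangent_hint - sum(tangent_hint * u) * u
  if (vnorm(t_raw) < 1e-6) {
    tangent_hint <- c(1, 0, 0)
    t_raw <- tangent_hint - sum(tangent_hint * u) * u
    if (vnorm(t_raw) < 1e-6) {
      tangent_hint <- c(0, 1, 0)
      t_raw <- tangent_hint - sum(tangent_hint * u) * u
    }
  }
  th <- normalize(t_raw)
  tilt <- function(deg) normalize(cos(deg2rad(abs(deg))) * u +
                                    sign(deg) * sin(deg2rad(abs(deg))) * th)
  a_dir <- tilt(-anode_offset_deg)
  c_dir <- tilt(cathode_offset_deg)
  list(electrode_at_point(a_dir, current_mA,
                          disc_radius_mm = disc_radius_mm,
                          thickness_mm = thickness_mm),
       electrode_at_point(c_dir, -current_mA,
                          disc_radius_mm = disc_radius_mm,
                          thickness_mm = thickness_mm))
}

#' Configuration of a factorial lesion experiment
#'
#' Bundles phantom parameters, one or more named ROI target directions with
#' their montages, lesion grids and solver settings. The defaults reproduce
#' the package's reference study: a 92/86/80/78/70 mm five-shell phantom at
#' 2 mm voxels, an "M1-like" vertex target (plus a "BA44-like" left-frontal
#' target available for two-ROI runs), 1 mA bipolar stimulation and the
#' 14 x 3 x 3 x 5 lesion grid.
#'
#' @param shell_radii_mm,voxel_size_mm phantom geometry.
#' @param rois named list of unit target directions.
#' @param montages named list (same names) of electrode lists; defaults to
#'   [montage_for_roi()] of each target.
#' @param lesion_grid factorial grids (see [default_lesion_grid()]).
#' @param roi_radius_mm ROI radius (default 12).
#' @param conductivities tissue conductivity table; the lesion entry is
#'   overridden per state by the factorial grid.
#' @param tolerance,sigma_cap solver settings.
#' @param output_dir optional directory for resumable runs.
#' @param seed seed for any sampled auxiliary grids.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(shell_radii_mm = c(92, 86, 80, 78, 70),
                              voxel_size_mm = 2,
                              rois = list("M1-like" = c(0, 0, 1)),
                              montages = NULL,
                              lesion_grid = default_lesion_grid(),
                              roi_radius_mm = 12,
                              conductivities = default_conductivities(),
                              tolerance = 1e-8,
                              sigma_cap = 1e4,
                              output_dir = NULL,
                              seed = 1L) {
  if (is.null(montages))
    montages <- lapply(rois, montage_for_roi)
  if (!identical(sort(names(rois)), sort(names(montages))))
    stop("configuration error: rois and montages must share names", call. = FALSE)
  if (!all(lengths(lesion_grid) > 0))
    stop("configuration error: lesion grids must be nonempty", call. = FALSE)
  structure(list(shell_radii_mm = shell_radii_mm,
                 voxel_size_mm = voxel_size_mm,
                 rois = rois, montages = montages,
                 lesion_grid = lesion_grid, roi_radius_mm = roi_radius_mm,
                 conductivities = conductivities,
                 tolerance = tolerance, sigma_cap = sigma_cap,
                 output_dir = output_dir, seed = seed),
            class = "experiment_config")
}

state_key <- function(roi, direction, gap, radius, conductivity) {
  sprintf("%s|%s|%g|%g|%g", roi, direction, gap, radius, conductivity)
}

.result_columns <- c("roi", "direction", "gap_mm", "radius_mm",
                     "conductivity_S_per_m", "center_x", "center_y",
                     "center_z", "volume_fraction", "valid",
                     "exclusion_reason", "baseline_mean_mag", "diff_mean",
                     "diff_p16", "diff_p84", "pct_diff", "abs_pct_diff",
                     "angle_deg", "solver_iterations", "solver_residual")

#' Run the full factorial lesion experiment
#'
#' For each ROI/montage the non-lesioned baseline is solved once, then every
#' valid lesion state is solved and summarised; invalid states are emitted
#' with their exclusion reason and no field values. With an `output_dir` the
#' run is resumable: rows already present in `results.csv` (keyed by ROI and
#' lesion specification) are not re-solved, and per-row results are appended
#' as they complete. Solver failures are recorded per row and the run
#' continues.
#'
#' @param config an [experiment_config()].
#' @param progress print per-state progress lines.
#' @return the results data frame (one row per state), with attributes
#'   `n_solves` (solves performed in this call) and `baselines` (per-ROI
#'   baseline statistics, for fresh runs).
#' @export
run_factorial <- function(config = experiment_config(), progress = FALSE) {
  outdir <- config$output_dir
  res_path <- if (!is.null(outdir)) file.path(outdir, "results.csv")
  done <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (file.exists(res_path)) {
      done <- utils::read.csv(res_path, stringsAsFactors = FALSE)
      done <- done[, intersect(.result_columns, names(done)), drop = FALSE]
    }
  }
  done_keys <- if (!is.null(done))
    with(done, state_key(roi, direction, gap_mm, radius_mm, conductivity_S_per_m))
  else character(0)

  n_solves <- 0L
  baselines <- list()
  out_rows <- list()
  phantom0 <- build_phantom(config$shell_radii_mm, config$voxel_size_mm)

  for (rn in names(config$rois)) {
    roi <- define_roi(phantom0, normalize(config$rois[[rn]]),
                      radius_mm = config$roi_radius_mm)
    states <- enumerate_states(phantom0, roi, config$lesion_grid)
    st <- states$states
    keys <- state_key(rn, st$direction, st$gap_mm, st$radius_mm,
                      st$conductivity_S_per_m)
    todo <- which(!(keys %in% done_keys))
    if (!length(todo)) next

    ph_mont <- place_electrodes(phantom0, config$montages[[rn]])
    base_cond <- assign_conductivity(ph_mont, config$conductivities)
    base_sys <- assemble_system(base_cond, check_connected = TRUE,
                                sigma_cap = config$sigma_cap)
    base_sol <- compute_efield(solve_potential(base_sys, config$tolerance))
    n_solves <- n_solves + 1L
    base_stats <- roi_stats(base_sol, roi)
    baselines[[rn]] <- base_stats

    for (i in todo) {
      row <- st[i, ]
      out <- data.frame(roi = rn, row[c("direction", "gap_mm", "radius_mm",
                                        "conductivity_S_per_m", "center_x",
                                        "center_y", "center_z",
                                        "volume_fraction", "valid",
                                        "exclusion_reason")],
                        baseline_mean_mag = base_stats$mean_mag,
                        diff_mean = NA_real_, diff_p16 = NA_real_,
                        diff_p84 = NA_real_, pct_diff = NA_real_,
                        abs_pct_diff = NA_real_, angle_deg = NA_real_,
                        solver_iterations = NA_integer_,
                        solver_residual = NA_real_,
                        stringsAsFactors = FALSE)
      if (row$valid) {
        solve_err <- NULL
        eff <- tryCatch({
          lesioned <- apply_lesion(ph_mont, states$masks[[row$geom_id]])
          tab_l <- config$conductivities
          tab_l["lesion"] <- row$conductivity_S_per_m
          cond <- assign_conductivity(lesioned, tab_l)
          sys <- assemble_system(cond, check_connected = FALSE,
                                 sigma_cap = config$sigma_cap)
          sol <- compute_efield(solve_potential(sys, config$tolerance))
          n_solves <- n_solves + 1L
          e <- lesion_effect(sol, base_sol, roi,
                             c(row$center_x, row$center_y, row$center_z),
                             baseline_stats = base_stats)
          e$solver_iterations <- sol$iterations
          e$solver_residual <- sol$residual
          e
        }, error = function(err) {
          solve_err <<- conditionMessage(err)
          NULL
        })
        if (is.null(eff) && !is.null(solve_err))
          out$exclusion_reason <- paste0("solver_failure: ", solve_err)
        if (!is.null(eff)) {
          out$diff_mean <- eff$diff_mean; out$diff_p16 <- eff$diff_p16
          out$diff_p84 <- eff$diff_p84; out$pct_diff <- eff$pct_diff
          out$abs_pct_diff <- eff$abs_pct_diff; out$angle_deg <- eff$angle_deg
          out$solver_iterations <- eff$solver_iterations
          out$solver_residual <- eff$solver_residual
        }
      }
      if (progress)
        message(sprintf("[%s] %s gap %g r %g sigma %g: %s", rn, row$direction,
                        row$gap_mm, row$radius_mm, row$conductivity_S_per_m,
                        if (row$valid) sprintf("pct %.2f", out$pct_diff)
                        else row$exclusion_reason))
      out_rows[[length(out_rows) + 1L]] <- out
      if (!is.null(outdir)) {
        new_file <- !file.exists(res_path)
        utils::write.table(out, res_path, sep = ",", row.names = FALSE,
                           col.names = new_file, append = !new_file)
      }
    }
  }
  new_rows <- if (length(out_rows)) do.call(rbind, out_rows)
  result <- rbind(done, new_rows)
  rownames(result) <- NULL
  attr(result, "n_solves") <- n_solves
  attr(result, "baselines") <- baselines
  result
}

#' Fit trend models to a factorial results table
#'
#' Ordinary least squares standing in for the mixed-effects analysis of the
#' factorial design (the phantom has no subject-level random effect; tables
#' from multiple phantoms carry a `roi`/phantom column so mixed models can be
#' fitted externally). For `abs_pct_diff` the model has the main effects of
#' distance, size and conductivity; for `pct_diff` it adds the lesion angle
#' and its interactions with each of the three.
#'
#' @param table results table (from [run_factorial()] or
#'   [make_planted_table()]); invalid and non-finite rows are dropped.
#' @param response `"abs_pct_diff"` or `"pct_diff"`.
#' @param min_rows minimum number of usable rows (default 30).
#' @return a `trend_fit` wrapping the `lm` fit, with `coef`, `print` and
#'   `summary` methods; coefficients carry standard errors and 95% confidence
#'   intervals.
#' @export
fit_trends <- function(table, response = c("abs_pct_diff", "pct_diff"),
                       min_rows = 30) {
  response <- match.arg(response)
  keep <- (table$valid %||% TRUE) & is.finite(table[[response]])
  dat <- table[keep, , drop = FALSE]
  if (nrow(dat) < min_rows)
    stop("need at least ", min_rows, " valid rows; got ", nrow(dat),
         call. = FALSE)
  fm <- if (response == "abs_pct_diff")
    abs_pct_diff ~ gap_mm + radius_mm + conductivity_S_per_m
  else
    pct_diff ~ angle_deg + gap_mm + radius_mm + conductivity_S_per_m +
      angle_deg:gap_mm + angle_deg:radius_mm + angle_deg:conductivity_S_per_m
  X <- stats::model.matrix(fm, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("configuration error: rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(fm, data = dat)
  # a noiseless planted table is a legal input: silence the perfect-fit note
  structure(list(fit = fit, response = response,
                 coefficients = stats::coef(fit),
                 se = suppressWarnings(sqrt(diag(stats::vcov(fit)))),
                 confint = suppressWarnings(stats::confint(fit)),
                 n = nrow(dat),
                 sigma = stats::sigma(fit),
                 r_squared = suppressWarnings(summary(fit)$r.squared)),
            class = "trend_fit")
}

#' @export
coef.trend_fit <- function(object, ...) object$coefficients

#' @export
print.trend_fit <- function(x, ...) {
  cat("<trend_fit> response:", x$response, " (n =", x$n,
      ", R^2 =", round(x$r_squared, 3), ")\n")
  tab <- cbind(estimate = x$coefficients, se = x$se, x$confint)
  print(round(tab, 5))
  invisible(x)
}

#' @export
summary.trend_fit <- function(object, ...) summary(object$fit, ...)

#' Summarise a factorial results table
#'
#' Per-factor means of the absolute percentage difference, per-direction
#' signed means, and exclusion accounting.
#'
#' @param table results table from [run_factorial()].
#' @return an `experiment_summary` list: `by_radius`, `by_gap`,
#'   `by_conductivity`, `by_direction` (each a data frame of level means),
#'   `exclusions` (counts by reason), `n_total`, `n_valid`, `n_solved`.
#' @export
summarise_experiment <- function(table) {
  if (!nrow(table)) stop("empty results table", call. = FALSE)
  val <- table[table$valid & is.finite(table$abs_pct_diff), , drop = FALSE]
  lev_means <- function(var, resp) {
    if (!nrow(val)) return(data.frame())
    ag <- stats::aggregate(val[[resp]], by = list(level = val[[var]]), FUN = mean)
    names(ag)[2] <- paste0("mean_", resp)
    ag
  }
  by_dir <- if (nrow(val)) {
    ag <- stats::aggregate(cbind(pct_diff, abs_pct_diff) ~ direction,
                           data = val, FUN = mean)
    ag[order(match(ag$direction, lesion_directions())), ]
  } else data.frame()
  excl <- table$exclusion_reason[!table$valid]
  structure(list(by_radius = lev_means("radius_mm", "abs_pct_diff"),
                 by_gap = lev_means("gap_mm", "abs_pct_diff"),
                 by_conductivity = lev_means("conductivity_S_per_m",
                                             "abs_pct_diff"),
                 by_direction = by_dir,
                 exclusions = if (length(excl)) table(excl) else table(character(0)),
                 n_total = nrow(table),
                 n_valid = sum(table$valid),
                 n_solved = sum(table$valid & is.finite(table$pct_diff))),
            class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat("<experiment_summary>", x$n_total, "states:", x$n_valid, "valid,",
      x$n_solved, "solved\n")
  if (length(x$exclusions)) { cat("exclusions:\n"); print(x$exclusions) }
  if (nrow(x$by_radius)) {
    cat("mean |pct diff| by radius (mm):\n"); print(x$by_radius)
    cat("by distance (mm):\n"); print(x$by_gap)
    cat("by conductivity (S/m):\n"); print(x$by_conductivity)
  }
  invisible(x)
}
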