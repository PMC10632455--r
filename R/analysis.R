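# Outcome measures: difference images, ROI grey-matter field statistics, mean
# current direction, lesion-direction angle and percentage differences.

#' Voxelwise difference of two magnitude images
#'
#' Lesioned minus non-lesioned, so voxels where the lesioned field is larger
#' are positive.
#'
#' @param lesioned_mag,nonlesioned_mag magnitude arrays on the same grid.
#' @return difference array.
#' @export
difference_image <- function(lesioned_mag, nonlesioned_mag) {
  if (!identical(dim(lesioned_mag), dim(nonlesioned_mag)))
    stop("shape error: magnitude images have different geometry", call. = FALSE)
  lesioned_mag - nonlesioned_mag
}

#' ROI grey-matter field statistics
#'
#' Mean, 16th and 84th percentile of the E-field magnitude over the
#' grey-matter voxels whose centres lie within the ROI sphere, plus the mean
#' current direction (normalised mean of the raw E-vectors over the same
#' voxels, so coherent strong current dominates). Percentiles use linear
#' interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param solution a `field_solution` with E-field computed (or any object
#'   carrying `magnitude`, `efield` and `labels` on one grid).
#' @param roi a `spherical_roi`.
#' @return a `roi_field_stats`: `mean_mag`, `p16_mag`, `p84_mag`,
#'   `mean_direction` (unit 3-vector), `n_voxels`.
#' @export
roi_stats <- function(solution, roi) {
  vox <- roi_gm_indices(solution, roi)
  if (!length(vox))
    stop("geometry error: ROI contains no grey-matter voxels", call. = FALSE)
  mag <- solution$magnitude[vox]
  ev <- cbind(solution$efield$x[vox], solution$efield$y[vox],
              solution$efield$z[vox])
  q <- stats::quantile(mag, c(0.16, 0.84), names = FALSE, type = 7)
  structure(list(mean_mag = mean(mag), p16_mag = q[1], p84_mag = q[2],
                 mean_direction = normalize(colMeans(ev)),
                 n_voxels = length(vox)),
            class = "roi_field_stats")
}

#' @export
print.roi_field_stats <- function(x, ...) {
  cat(sprintf("<roi_field_stats> mean %.4g V/m (p16 %.4g, p84 %.4g) over %d voxels; direction (%.2f, %.2f, %.2f)\n",
              x$mean_mag, x$p16_mag, x$p84_mag, x$n_voxels,
              x$mean_direction[1], x$mean_direction[2], x$mean_direction[3]))
  invisible(x)
}

#' Angle between lesion direction and mean current direction
#'
#' Arccos of the dot product between the normalised ROI-centre-to-lesion-centre
#' vector and the mean E-field direction, in degrees (0--180). A small angle
#' means the lesion lies in the path of current flow; the mean direction is
#' taken from the non-lesioned baseline.
#'
#' @param roi a `spherical_roi`.
#' @param lesion_center_mm lesion centre (mm); must differ from the ROI centre.
#' @param mean_direction unit 3-vector (baseline ROI mean E-field direction).
#' @return angle in degrees.
#' @export
lesion_angle <- function(roi, lesion_center_mm, mean_direction) {
  sep <- lesion_center_mm - roi$center_mm
  if (vnorm(sep) < .Machine$double.eps)
    stop("parameter error: lesion centre coincides with ROI centre", call. = FALSE)
  angle_between(sep, mean_direction)
}

#' Percentage difference in ROI mean magnitude
#'
#' `100 * (lesioned - nonlesioned) / nonlesioned`, using the non-lesioned ROI
#' mean magnitude as the denominator.
#'
#' @param lesioned_stats,nonlesioned_stats `roi_field_stats`.
#' @return list with `pct_diff` and `abs_pct_diff`.
#' @export
percent_difference <- function(lesioned_stats, nonlesioned_stats) {
  base <- nonlesioned_stats$mean_mag
  if (!is.finite(base) || base <= 0)
    stop("division error: non-lesioned baseline mean magnitude must be positive",
         call. = FALSE)
  pct <- 100 * (lesioned_stats$mean_mag - base) / base
  list(pct_diff = pct, abs_pct_diff = abs(pct))
}

#' Lesioned-versus-baseline effect summary for one lesion state
#'
#' Computes the voxelwise difference image, its mean and 16th/84th percentiles
#' over the ROI grey matter, the percentage difference of the ROI means, and
#' the lesion angle relative to the baseline mean current direction.
#'
#' @param lesioned,baseline solved `field_solution`s on the same grid.
#' @param roi a `spherical_roi`.
#' @param lesion_center_mm lesion centre (mm).
#' @param baseline_stats optional precomputed [roi_stats()] of the baseline.
#' @return a one-row data frame with `diff_mean`, `diff_p16`, `diff_p84`,
#'   `pct_diff`, `abs_pct_diff`, `angle_deg`, `baseline_mean_mag`.
#' @export
lesion_effect <- function(lesioned, baseline, roi, lesion_center_mm,
                          baseline_stats = NULL) {
  baseline_stats <- baseline_stats %||% roi_stats(baseline, roi)
  les_stats <- roi_stats(lesioned, roi)
  dimg <- difference_image(lesioned$magnitude, baseline$magnitude)
  vox <- roi_gm_indices(baseline, roi)
  dvals <- dimg[vox]
  q <- stats::quantile(dvals, c(0.16, 0.84), names = FALSE, type = 7)
  pct <- percent_difference(les_stats, baseline_stats)
  data.frame(diff_mean = mean(dvals), diff_p16 = q[1], diff_p84 = q[2],
             pct_diff = pct$pct_diff, abs_pct_diff = pct$abs_pct_diff,
             angle_deg = lesion_angle(roi, lesion_center_mm,
                                      baseline_stats$mean_direction),
             baseline_mean_mag = baseline_stats$mean_mag)
}
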