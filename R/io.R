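# NIfTI and YAML interfaces: label/conductivity/field volumes as NIfTI-1,
# experiment configuration as YAML.

lf_affine <- function(vol) {
  h <- vol$voxel_size_mm
  rbind(cbind(diag(h, 3), vol$origin_mm), c(0, 0, 0, 1))
}

#' Write a label volume as NIfTI-1
#'
#' Labels are written as int16 with an affine encoding the voxel size and
#' origin (RAS millimetres).
#'
#' @param vol a `label_volume`.
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_label_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$labels, datatype = "int16")
  img <- RNifti::`sform<-`(img, structure(lf_affine(vol), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label volume from NIfTI-1
#'
#' @param path input path.
#' @param label_table code-to-tissue mapping (defaults to the package's
#'   convention: air 0, skin 1, skull 2, csf 3, gm 4, wm 5, lesion 6, gel 7,
#'   electrode 8).
#' @return a `label_volume`.
#' @export
read_label_volume <- function(path, label_table = LABEL_CODES) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  h <- sqrt(sum(xf[1:3, 1]^2))   # voxel size from the affine, not pixdim
  labels <- array(as.integer(img), dim = dim(img))
  unknown <- setdiff(unique(as.vector(labels)), unname(label_table))
  if (length(unknown))
    stop("label codes not in label_table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  new_label_volume(labels, h, origin_mm = unname(xf[1:3, 4]),
                   label_table = label_table)
}

#' Write a scalar or field volume as NIfTI-1
#'
#' Scalar grids (potential, magnitude, conductivity, difference images) are
#' written as float32; a `field_solution`'s E-field is written as a 4-D
#' volume with the three vector components in the fourth dimension.
#'
#' @param x numeric array, `conductivity_volume` or `field_solution`.
#' @param path output path.
#' @param what for a `field_solution`: `"magnitude"`, `"potential"` or
#'   `"efield"`.
#' @param geometry a volume supplying voxel size/origin when `x` is a bare
#'   array.
#' @export
write_field_volume <- function(x, path, what = "magnitude", geometry = NULL) {
  if (inherits(x, "conductivity_volume")) {
    arr <- x$sigma; geom <- x
  } else if (inherits(x, "field_solution")) {
    geom <- x
    arr <- switch(what,
                  magnitude = x$magnitude,
                  potential = x$potential,
                  efield = {
                    a <- array(NA_real_, dim = c(dim(x$potential), 3))
                    a[, , , 1] <- x$efield$x
                    a[, , , 2] <- x$efield$y
                    a[, , , 3] <- x$efield$z
                    a
                  },
                  stop("unknown component: ", what, call. = FALSE))
  } else {
    if (is.null(geometry))
      stop("supply `geometry` when writing a bare array", call. = FALSE)
    arr <- x; geom <- geometry
  }
  img <- RNifti::asNifti(arr, datatype = "float")
  img <- RNifti::`sform<-`(img, structure(lf_affine(geom), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an experiment configuration from YAML
#'
#' Recognised keys: `shell_radii_mm`, `voxel_size_mm`, `roi_radius_mm`,
#' `tolerance`, `sigma_cap`, `output_dir`, `seed`, `rois` (name -> unit
#' direction), `montages` (name -> list of `{theta_deg, phi_deg, current_mA,
#' disc_radius_mm, thickness_mm}`), `conductivities` (tissue -> S/m overrides
#' of the default table), and `lesion_grid` (`directions`, `gap_mm`,
#' `radius_mm`, `conductivity_S_per_m`). Missing keys fall back to the
#' [experiment_config()] defaults.
#'
#' @param path YAML file path.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("shell_radii_mm", "voxel_size_mm", "roi_radius_mm",
              "tolerance", "sigma_cap", "output_dir", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$rois))
    args$rois <- lapply(y$rois, function(v) normalize(as.numeric(v)))
  if (!is.null(y$montages))
    args$montages <- lapply(y$montages, function(m)
      lapply(m, function(e)
        electrode(theta_deg = e$theta_deg, phi_deg = e$phi_deg,
                  current_mA = e$current_mA,
                  disc_radius_mm = e$disc_radius_mm %||% 17,
                  thickness_mm = e$thickness_mm %||% 2)))
  if (!is.null(y$conductivities)) {
    tab <- default_conductivities()
    for (k in names(y$conductivities)) tab[k] <- y$conductivities[[k]]
    args$conductivities <- tab
  }
  if (!is.null(y$lesion_grid)) {
    g <- default_lesion_grid()
    for (k in names(y$lesion_grid)) g[[k]] <- y$lesion_grid[[k]]
    args$lesion_grid <- g
  }
  do.call(experiment_config, args)
}
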