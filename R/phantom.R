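# Multi-shell spherical head phantoms: tissue label volumes, conductivity
# assignment, ROIs and electrode placement.

# Tissue label codes. Air is 0 so that `labels > 0` is the conductive domain.
LABEL_CODES <- c(air = 0L, skin = 1L, skull = 2L, csf = 3L, gm = 4L,
                 wm = 5L, lesion = 6L, gel = 7L, electrode = 8L)

#' Default tissue conductivity table (S/m)
#'
#' Conductivities of the seven head tissues plus electrode gel and electrode
#' conductor: white matter 0.126, grey matter 0.276, CSF 1.65, skull (bone)
#' 0.465, skin 0.126, air 2.5e-14, gel 0.3, electrode 5.9e7 S/m. Lesion
#' conductivity is the quantity varied across simulations and is supplied by
#' the caller.
#'
#' @param lesion lesion conductivity in S/m (default 1.0, the midpoint of the
#'   0.2--1.8 S/m range explored by the factorial experiment).
#' @return named numeric vector, one entry per tissue name.
#' @export
default_conductivities <- function(lesion = 1.0) {
  c(air = 2.5e-14, skin = 0.126, skull = 0.465, csf = 1.65,
    gm = 0.276, wm = 0.126, lesion = lesion, gel = 0.3, electrode = 5.9e7)
}

new_label_volume <- function(labels, voxel_size_mm, origin_mm,
                             label_table = LABEL_CODES, shell_radii_mm = NULL,
                             electrodes = NULL) {
  structure(list(labels = labels,
                 voxel_size_mm = voxel_size_mm,
                 origin_mm = origin_mm,
                 label_table = label_table,
                 shell_radii_mm = shell_radii_mm,
                 electrodes = electrodes),
            class = "label_volume")
}

label_code <- function(vol, tissue) {
  code <- vol$label_table[[tissue]]
  if (is.null(code)) stop("unknown tissue name: ", tissue, call. = FALSE)
  code
}

#' Build a multi-shell spherical head phantom
#'
#' Voxelises five concentric spheres (skin, skull, CSF, grey matter, white
#' matter) on an isotropic grid centred at the head centre, labelling each
#' voxel by the innermost shell containing its centre; everything outside the
#' skin sphere is air. The phantom stands in for a segmented structural MRI.
#'
#' Coordinates are RAS millimetres (+x right, +y anterior, +z superior) with
#' the head centre at the origin; voxel (1,1,1) has its centre at `origin_mm`.
#'
#' @param shell_radii_mm five strictly descending positive radii for
#'   skin/skull/CSF/grey-matter/white-matter outer surfaces. Defaults to
#'   92/86/80/78/70 mm, typical adult head values.
#' @param voxel_size_mm isotropic voxel edge length in mm (default 2).
#' @param pad_voxels layers of air padding beyond the skin radius (default 2).
#' @return a `label_volume`: list with integer array `labels`, `voxel_size_mm`,
#'   `origin_mm`, `label_table`, and `shell_radii_mm`.
#' @examples
#' ph <- build_phantom(c(46, 43, 40, 39, 35), voxel_size_mm = 2)
#' table(ph$labels)
#' @export
build_phantom <- function(shell_radii_mm = c(92, 86, 80, 78, 70),
                          voxel_size_mm = 2, pad_voxels = 2L) {
  r <- as.numeric(shell_radii_mm)
  if (length(r) != 5 || any(r <= 0) || any(diff(r) >= 0))
    stop("shell_radii_mm must be 5 strictly descending positive radii ",
         "(skin, skull, csf, gm, wm)", call. = FALSE)
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be positive", call. = FALSE)
  h <- voxel_size_mm
  half <- as.integer(ceiling(r[1] / h)) + as.integer(pad_voxels)
  n <- 2L * half + 1L
  origin <- rep(-half * h, 3)
  ax <- origin[1] + (seq_len(n) - 1) * h
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  labels <- array(LABEL_CODES[["air"]], dim = c(n, n, n))
  shells <- c("skin", "skull", "csf", "gm", "wm")
  for (s in seq_along(shells))          # outer to inner; inner overwrites
    labels[d2 <= r[s]^2] <- LABEL_CODES[[shells[s]]]
  storage.mode(labels) <- "integer"
  new_label_volume(labels, h, origin, shell_radii_mm = r)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat("<label_volume> ", paste(d, collapse = " x "),
      " voxels @ ", x$voxel_size_mm, " mm\n", sep = "")
  tab <- table(factor(x$labels, levels = x$label_table,
                      labels = names(x$label_table)))
  print(tab[tab > 0])
  invisible(x)
}

# Logical array: grey or white matter.
brain_mask <- function(vol) {
  vol$labels == label_code(vol, "gm") | vol$labels == label_code(vol, "wm")
}

#' Define a spherical cortical region of interest
#'
#' Places a spherical ROI (default 12 mm radius, the size used for the M1 and
#' BA44 targets) with its centre at the grey-matter shell mid-thickness along
#' a unit direction from the head centre, or at an explicit `center_mm`.
#'
#' @param phantom a `label_volume` built by [build_phantom()] (required for
#'   the default mid-grey-matter placement).
#' @param direction_unit unit 3-vector from head centre towards the target.
#' @param radius_mm ROI radius in mm (default 12).
#' @param center_mm optional explicit centre, overriding the shell placement.
#' @return a `spherical_roi`: list with `center_mm`, `radius_mm`,
#'   `direction_unit`.
#' @export
define_roi <- function(phantom, direction_unit, radius_mm = 12,
                       center_mm = NULL) {
  if (radius_mm <= 0) stop("radius_mm must be positive", call. = FALSE)
  if (is.null(center_mm)) {
    if (abs(vnorm(direction_unit) - 1) > 1e-6)
      stop("direction_unit must have unit norm", call. = FALSE)
    if (is.null(phantom$shell_radii_mm))
      stop("phantom has no shell radii; supply center_mm explicitly",
           call. = FALSE)
    r <- phantom$shell_radii_mm
    center_mm <- direction_unit * (r[4] + r[5]) / 2
  }
  lin <- point_to_linear(phantom, center_mm)
  bm <- brain_mask(phantom)
  if (is.na(lin) || !bm[lin])
    stop("geometry error: ROI centre does not lie inside the brain mask",
         call. = FALSE)
  if (length(sphere_indices(phantom, center_mm, radius_mm,
                            label_code(phantom, "gm"))) == 0L)
    stop("geometry error: ROI contains no grey-matter voxels", call. = FALSE)
  structure(list(center_mm = as.numeric(center_mm), radius_mm = radius_mm,
                 direction_unit = if (missing(direction_unit)) NULL
                                  else as.numeric(direction_unit)),
            class = "spherical_roi")
}

# Linear indices of grey-matter voxels whose centres fall inside the ROI.
roi_gm_indices <- function(vol, roi) {
  sphere_indices(vol, roi$center_mm, roi$radius_mm, label_code(vol, "gm"))
}

#' Assign tissue conductivities to a label volume
#'
#' Voxelwise lookup of the conductivity table: `sigma(voxel)` equals the table
#' value for the voxel's tissue label. No other transformation is applied.
#'
#' @param phantom a `label_volume`.
#' @param table named conductivity vector covering every tissue present
#'   (see [default_conductivities()]).
#' @return a `conductivity_volume` carrying `sigma` plus the source labels and
#'   geometry metadata.
#' @export
assign_conductivity <- function(phantom, table = default_conductivities()) {
  codes_present <- sort(unique(as.vector(phantom$labels)))
  names_present <- names(phantom$label_table)[match(codes_present, phantom$label_table)]
  missing <- setdiff(names_present, names(table))
  if (length(missing))
    stop("configuration error: no conductivity for label(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  lut <- rep(NA_real_, max(phantom$label_table) + 1L)
  lut[phantom$label_table + 1L] <- table[names(phantom$label_table)]
  sigma <- array(lut[phantom$labels + 1L], dim = dim(phantom$labels))
  structure(list(sigma = sigma,
                 labels = phantom$labels,
                 voxel_size_mm = phantom$voxel_size_mm,
                 origin_mm = phantom$origin_mm,
                 label_table = phantom$label_table,
                 shell_radii_mm = phantom$shell_radii_mm,
                 electrodes = phantom$electrodes,
                 table = table),
            class = "conductivity_volume")
}

#' @export
print.conductivity_volume <- function(x, ...) {
  cat("<conductivity_volume> ", paste(dim(x$sigma), collapse = " x "),
      " voxels @ ", x$voxel_size_mm, " mm; sigma range ",
      format(min(x$sigma)), "-", format(max(x$sigma)), " S/m\n", sep = "")
  invisible(x)
}

#' Describe a disc electrode on the phantom scalp
#'
#' Position is given in scalp spherical coordinates: `theta_deg` is the polar
#' angle from +z (vertex) and `phi_deg` the azimuth from +x towards +y. The
#' default disc geometry (17 mm radius, 2 mm depth) matches standard round
#' tDCS electrodes.
#'
#' @param theta_deg,phi_deg scalp spherical coordinates in degrees.
#' @param current_mA signed electrode current: anode > 0, cathode < 0.
#' @param disc_radius_mm disc radius (default 17).
#' @param thickness_mm conductor thickness (default 2).
#' @return an `electrode` description.
#' @export
electrode <- function(theta_deg, phi_deg, current_mA,
                      disc_radius_mm = 17, thickness_mm = 2) {
  if (disc_radius_mm <= 0 || thickness_mm <= 0)
    stop("disc radius and thickness must be positive", call. = FALSE)
  th <- deg2rad(theta_deg); ph <- deg2rad(phi_deg)
  structure(list(theta_deg = theta_deg, phi_deg = phi_deg,
                 direction = c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)),
                 current_mA = current_mA,
                 disc_radius_mm = disc_radius_mm,
                 thickness_mm = thickness_mm),
            class = "electrode")
}

# Electrode whose disc axis passes through an arbitrary scalp point.
electrode_at_point <- function(point_mm, current_mA, disc_radius_mm = 17,
                               thickness_mm = 2) {
  u <- normalize(point_mm)
  electrode(theta_deg = rad2deg(acos(min(1, max(-1, u[3])))),
            phi_deg = rad2deg(atan2(u[2], u[1])),
            current_mA = current_mA,
            disc_radius_mm = disc_radius_mm, thickness_mm = thickness_mm)
}

scalp_radius <- function(vol) {
  if (!is.null(vol$shell_radii_mm)) return(vol$shell_radii_mm[1])
  skin <- which(vol$labels == label_code(vol, "skin"))
  if (!length(skin)) stop("volume has no skin voxels", call. = FALSE)
  d <- dim(vol$labels)
  ijk <- arrayInd(skin, d)
  xyz <- sweep((ijk - 1) * vol$voxel_size_mm, 2, -vol$origin_mm)
  max(sqrt(rowSums(xyz^2)))
}

#' Place a bipolar (or multi-electrode) montage on the scalp
#'
#' Rasterises each disc electrode outward from the scalp surface: one voxel
#' layer of conductive gel sits directly on the skin, followed by electrode
#' conductor up to the requested thickness. Only air voxels are overwritten,
#' so the head tissues are untouched. Montage currents must sum to zero and
#' at least two electrodes are required (bipolar minimum).
#'
#' @param phantom a `label_volume`.
#' @param montage list of [electrode()] descriptions.
#' @return a new `label_volume` with gel/electrode labels added and an
#'   `electrodes` field recording, per electrode, its injection voxels and
#'   current.
#' @export
place_electrodes <- function(phantom, montage) {
  if (length(montage) < 2)
    stop("placement error: a montage needs at least 2 electrodes", call. = FALSE)
  cur <- vapply(montage, function(e) e$current_mA, numeric(1))
  if (abs(sum(cur)) > 1e-9 * max(abs(cur)))
    stop("parameter error: montage currents must sum to zero", call. = FALSE)

  lv <- phantom
  d <- dim(lv$labels)
  h <- lv$voxel_size_mm
  r_skin <- scalp_radius(lv)
  gel_mm <- h                                   # one voxel layer of gel
  air <- label_code(lv, "air")
  claimed <- integer(0)
  placed <- vector("list", length(montage))

  for (k in seq_along(montage)) {
    e <- montage[[k]]
    surf <- e$direction * r_skin
    reach <- e$disc_radius_mm + gel_mm + e$thickness_mm + 2 * h
    box <- sphere_indices(lv, surf, reach)
    if (!length(box))
      stop("placement error: electrode ", k, " lies outside the grid", call. = FALSE)
    ijk <- arrayInd(box, d)
    xyz <- sweep((ijk - 1) * h, 2, -lv$origin_mm)
    rad <- sqrt(rowSums(xyz^2))
    t_ax <- xyz %*% e$direction
    perp2 <- pmax(rad^2 - t_ax^2, 0)
    # test against the original labels so overlapping discs are detected
    # rather than silently claiming each other's voxels
    on_disc <- t_ax > 0 & perp2 <= e$disc_radius_mm^2 & phantom$labels[box] == air
    gel_sel <- on_disc & rad > r_skin & rad <= r_skin + gel_mm
    ele_sel <- on_disc & rad > r_skin + gel_mm &
      rad <= r_skin + gel_mm + e$thickness_mm
    gel_idx <- box[gel_sel]
    ele_idx <- box[ele_sel]
    if (!length(gel_idx) || !length(ele_idx))
      stop("placement error: electrode ", k,
           " produced an empty gel or conductor patch", call. = FALSE)
    both <- c(gel_idx, ele_idx)
    if (any(both %in% claimed))
      stop("placement error: overlapping electrode discs", call. = FALSE)
    claimed <- c(claimed, both)
    lv$labels[gel_idx] <- label_code(lv, "gel")
    lv$labels[ele_idx] <- label_code(lv, "electrode")
    placed[[k]] <- list(center_mm = surf, direction = e$direction,
                        current_mA = e$current_mA,
                        theta_deg = e$theta_deg, phi_deg = e$phi_deg,
                        disc_radius_mm = e$disc_radius_mm,
                        voxels = ele_idx, gel_voxels = gel_idx)
  }
  lv$electrodes <- placed
  lv
}

#' Stamp a lesion mask into a label volume
#'
#' Overwrites the masked voxels (a subset of grey/white matter) with the
#' lesion label.
#'
#' @param phantom a `label_volume`.
#' @param mask integer vector of linear voxel indices.
#' @return a new `label_volume`.
#' @export
apply_lesion <- function(phantom, mask) {
  lv <- phantom
  if (length(mask)) lv$labels[mask] <- label_code(lv, "lesion")
  lv
}
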