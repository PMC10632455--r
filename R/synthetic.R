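# Synthetic fixtures with closed-form ground truth: layered slab conductors
# (series-resistance oracle for the solver), analytic field volumes, and
# planted-effect regression tables.

#' Layered slab conductor with plate electrodes and closed-form solution
#'
#' Stacks uniform conductivity layers along z between full-face plate
#' electrodes. With total current I through cross-section A the current
#' density J = I/A is uniform and the field in layer i is E_i = J / sigma_i
#' (series-resistor closed form); lateral boundaries are zero-flux so the
#' problem is exactly one-dimensional.
#'
#' @param thickness_mm layer thicknesses in mm (positive).
#' @param sigma layer conductivities in S/m.
#' @param current_mA total plate current (default 1).
#' @param nx,ny cross-section in voxels (default 8 x 8).
#' @param voxel_size_mm voxel edge (default 2).
#' @return a `slab_fixture`: `volume` (label volume), `cond` (conductivity
#'   volume with plate electrodes attached), `E_layers` (closed-form V/m per
#'   layer), `J_A_per_m2`, `area_mm2`, and `layer_of_k` mapping each z-slice
#'   to its layer (0 = electrode plate).
#' @export
make_slab_fixture <- function(thickness_mm = c(10, 10, 10),
                              sigma = c(0.1, 1.0, 0.5),
                              current_mA = 1, nx = 8, ny = 8,
                              voxel_size_mm = 2) {
  if (length(thickness_mm) != length(sigma))
    stop("parameter error: one conductivity per layer", call. = FALSE)
  if (any(thickness_mm <= 0))
    stop("parameter error: zero-thickness layer", call. = FALSE)
  if (any(sigma <= 0) || current_mA <= 0)
    stop("parameter error: inputs must be positive", call. = FALSE)
  h <- voxel_size_mm
  nz_layers <- as.integer(round(thickness_mm / h))
  if (any(abs(nz_layers * h - thickness_mm) > 1e-9))
    stop("parameter error: layer thicknesses must be voxel multiples", call. = FALSE)
  nz <- sum(nz_layers) + 2L                       # one plate at each end
  labels <- array(0L, dim = c(nx, ny, nz))
  layer_of_k <- integer(nz)
  codes <- 10L + seq_along(sigma)
  k <- 1L
  labels[, , k] <- LABEL_CODES[["electrode"]]; layer_of_k[k] <- 0L
  for (l in seq_along(sigma)) {
    ks <- k + seq_len(nz_layers[l])
    labels[, , ks] <- codes[l]
    layer_of_k[ks] <- l
    k <- k + nz_layers[l]
  }
  labels[, , nz] <- LABEL_CODES[["electrode"]]; layer_of_k[nz] <- 0L

  label_table <- c(stats::setNames(codes, paste0("layer", seq_along(sigma))),
                   electrode = LABEL_CODES[["electrode"]],
                   air = LABEL_CODES[["air"]])
  origin <- c(-(nx - 1) / 2 * h, -(ny - 1) / 2 * h, 0)
  vol <- new_label_volume(labels, h, origin, label_table = label_table)

  d <- dim(labels)
  plate <- function(kz) which(array(slice.index(labels, 3) == kz, dim = d))
  vol$electrodes <- list(
    list(center_mm = c(0, 0, 0), direction = c(0, 0, -1),
         current_mA = current_mA, voxels = plate(1L)),
    list(center_mm = c(0, 0, (nz - 1) * h), direction = c(0, 0, 1),
         current_mA = -current_mA, voxels = plate(nz)))

  table <- c(stats::setNames(sigma, paste0("layer", seq_along(sigma))),
             electrode = 5.9e7, air = 2.5e-14)
  cond <- assign_conductivity(vol, table)

  area_m2 <- (nx * h / 1000) * (ny * h / 1000)
  J <- (current_mA / 1000) / area_m2
  structure(list(volume = vol, cond = cond,
                 E_layers = J / sigma, J_A_per_m2 = J,
                 area_mm2 = nx * ny * h^2,
                 layer_of_k = layer_of_k, sigma = sigma),
            class = "slab_fixture")
}

#' Planted-effect results table for trend-fit testing
#'
#' Samples lesion-state predictors over the default factorial grids (angle
#' uniform on 0--180 degrees) and generates the response from a linear model
#' with the given coefficients plus Gaussian noise. Regeneration with the same
#' seed is bit-identical; the planted coefficients travel with the table.
#'
#' @param coefficients named vector with entries `intercept`, `angle_deg`,
#'   `gap_mm`, `radius_mm`, `conductivity_S_per_m` (missing entries are 0).
#' @param noise_sd response noise standard deviation.
#' @param n_rows number of rows (at least 30; default 630).
#' @param seed RNG seed.
#' @return data frame with predictors, `pct_diff`, `abs_pct_diff` and
#'   attributes `planted` and `seed`.
#' @export
make_planted_table <- function(coefficients = c(angle_deg = -0.06),
                               noise_sd = 1, n_rows = 630, seed = 1) {
  if (n_rows < 30) stop("parameter error: n_rows must be >= 30", call. = FALSE)
  full <- c(intercept = 0, angle_deg = 0, gap_mm = 0, radius_mm = 0,
            conductivity_S_per_m = 0)
  full[names(coefficients)] <- coefficients
  grid <- default_lesion_grid()
  tab <- with_seed(seed, {
    df <- data.frame(
      angle_deg = stats::runif(n_rows, 0, 180),
      gap_mm = sample(grid$gap_mm, n_rows, replace = TRUE),
      radius_mm = sample(grid$radius_mm, n_rows, replace = TRUE),
      conductivity_S_per_m = sample(grid$conductivity_S_per_m, n_rows,
                                    replace = TRUE))
    eta <- full["intercept"] + full["angle_deg"] * df$angle_deg +
      full["gap_mm"] * df$gap_mm + full["radius_mm"] * df$radius_mm +
      full["conductivity_S_per_m"] * df$conductivity_S_per_m
    df$pct_diff <- eta + if (noise_sd > 0) stats::rnorm(n_rows, 0, noise_sd) else 0
    df
  })
  tab$abs_pct_diff <- abs(tab$pct_diff)
  tab$valid <- TRUE
  attr(tab, "planted") <- full
  attr(tab, "seed") <- seed
  tab
}

#' Analytic field volumes with exactly known ROI statistics
#'
#' Builds a `field_solution`-shaped object on a phantom grid without running a
#' solve: `"uniform"` is a constant E-field of the given amplitude along +z
#' (linear potential), `"linear"` a potential linear in x+y+z (constant
#' diagonal field), and `"radial"` a radially inward field of constant
#' magnitude.
#'
#' @param profile `"uniform"`, `"linear"` or `"radial"`.
#' @param amplitude field amplitude in V/m (default 0.2).
#' @param phantom a `label_volume`; default is a small five-shell phantom.
#' @return a `field_solution` with analytic `potential`, `efield` and
#'   `magnitude` (defined on non-air voxels).
#' @export
make_field_fixture <- function(profile = c("uniform", "linear", "radial"),
                               amplitude = 0.2, phantom = NULL) {
  profile <- match.arg(profile)
  phantom <- phantom %||% build_phantom(c(46, 43, 40, 39, 35), 2)
  d <- dim(phantom$labels)
  ax <- voxel_axes(phantom)
  X <- array(rep(ax[[1]], times = d[2] * d[3]), dim = d) / 1000
  Y <- array(rep(rep(ax[[2]], each = d[1]), times = d[3]), dim = d) / 1000
  Z <- array(rep(ax[[3]], each = d[1] * d[2]), dim = d) / 1000
  mask <- phantom$labels != label_code(phantom, "air")
  zero <- array(0, dim = d)
  if (profile == "uniform") {
    V <- -amplitude * Z
    E <- list(x = zero, y = zero, z = zero + amplitude)
  } else if (profile == "linear") {
    V <- -amplitude * (X + Y + Z)
    E <- list(x = zero + amplitude, y = zero + amplitude, z = zero + amplitude)
  } else {
    R <- sqrt(X^2 + Y^2 + Z^2)
    V <- amplitude * R                           # E = -grad V = -amp * r_hat
    Rs <- pmax(R, .Machine$double.eps)
    E <- list(x = -amplitude * X / Rs, y = -amplitude * Y / Rs,
              z = -amplitude * Z / Rs)
  }
  na_out <- function(a) { a[!mask] <- NA_real_; a }
  E <- lapply(E, na_out)
  structure(list(potential = na_out(V), efield = E,
                 magnitude = na_out(sqrt(E$x^2 + E$y^2 + E$z^2)),
                 injected_current_mA = NA_real_, residual = 0,
                 iterations = 0L, converged = TRUE,
                 voxel_size_mm = phantom$voxel_size_mm,
                 origin_mm = phantom$origin_mm,
                 labels = phantom$labels, sigma = NULL,
                 label_table = phantom$label_table,
                 shell_radii_mm = phantom$shell_radii_mm,
                 electrodes = NULL, sigma_cap = Inf,
                 profile = profile, amplitude = amplitude),
            class = "field_solution")
}
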