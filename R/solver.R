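# Finite-volume solver for the quasi-static volume conduction problem
# div(sigma grad V) = 0 with electrode current injection on the voxel grid.
# One unknown per conductive (non-air) voxel; face conductances use the
# harmonic mean of the adjacent voxel conductivities; the outer boundary is
# zero-flux; the gauge is fixed at the cathode-centre voxel.

# Face list of the conductive domain along one axis: full-grid linear indices
# `a` and `b = a + stride` of adjacent conductive voxels plus the face
# conductance in siemens. Voxels are cubes of edge h, so the geometric factor
# area/spacing equals h (in metres).
face_conductances <- function(sigma, mask, axis, h_m, sigma_cap) {
  d <- dim(sigma)
  n_ax <- d[axis]
  if (n_ax < 2) return(list(a = integer(0), b = integer(0), g = numeric(0)))
  idx1 <- switch(axis,
                 mask[-n_ax, , , drop = FALSE] & mask[-1, , , drop = FALSE],
                 mask[, -n_ax, , drop = FALSE] & mask[, -1, , drop = FALSE],
                 mask[, , -n_ax, drop = FALSE] & mask[, , -1, drop = FALSE])
  sub <- which(idx1)
  if (!length(sub)) return(list(a = integer(0), b = integer(0), g = numeric(0)))
  stride <- c(1L, d[1], d[1] * d[2])[axis]
  # map sub-array linear index (one axis shortened) to full-array index
  if (axis == 1L) {
    ix <- (sub - 1L) %% (d[1] - 1L) + 1L
    rest <- (sub - 1L) %/% (d[1] - 1L)
    a <- ix + rest * d[1]
  } else if (axis == 2L) {
    ix <- (sub - 1L) %% d[1] + 1L
    iy <- ((sub - 1L) %/% d[1]) %% (d[2] - 1L) + 1L
    iz <- (sub - 1L) %/% (d[1] * (d[2] - 1L))
    a <- ix + (iy - 1L) * d[1] + iz * d[1] * d[2]
  } else {
    a <- sub
  }
  b <- a + stride
  s1 <- pmin(sigma[a], sigma_cap)
  s2 <- pmin(sigma[b], sigma_cap)
  list(a = a, b = b, g = h_m * 2 * s1 * s2 / (s1 + s2))
}

#' Assemble the finite-volume linear system
#'
#' Discretises the conductive (non-air) domain with one unknown per voxel.
#' Face conductances are the harmonic mean of the adjacent voxel
#' conductivities times the geometric factor (face area / spacing = voxel
#' edge, in metres). The injected current of each electrode is distributed
#' uniformly over its conductor voxels; row sums are zero away from source
#' voxels (current conservation); the gauge is fixed by pinning the
#' cathode-centre voxel to 0 V.
#'
#' @param cond a `conductivity_volume` (with electrodes placed, unless only
#'   the matrix structure is needed).
#' @param check_connected verify that the conductive domain is a single
#'   connected component (topology error otherwise). Skippable for repeated
#'   solves on the same domain.
#' @param sigma_cap assembly-time conductivity cap in S/m (default 1e4). The
#'   electrode conductor's nominal 5.9e7 S/m is far beyond what conditioning
#'   tolerates and far beyond what the physics needs: at 1e4 S/m the pad is
#'   still more than four orders of magnitude more conductive than gel and
#'   behaves as an equipotential.
#' @return an `fv_system`: sparse matrix `A`, right-hand side `b` (amperes),
#'   voxel-to-unknown index map, reference unknown, and geometry metadata.
#' @export
assemble_system <- function(cond, check_connected = TRUE, sigma_cap = 1e4) {
  d <- dim(cond$sigma)
  mask <- cond$labels != label_code(cond, "air")
  nu <- sum(mask)
  if (nu == 0L)
    stop("topology error: conductive domain is empty (all-air volume)",
         call. = FALSE)
  if (any(cond$sigma[mask] <= 0))
    stop("parameter error: non-positive conductivity in conductive domain",
         call. = FALSE)
  h_m <- cond$voxel_size_mm / 1000
  idx <- array(0L, dim = d)
  idx[mask] <- seq_len(nu)

  faces <- lapply(1:3, function(ax)
    face_conductances(cond$sigma, mask, ax, h_m, sigma_cap))
  a <- unlist(lapply(faces, `[[`, "a"))
  b_ <- unlist(lapply(faces, `[[`, "b"))
  g <- unlist(lapply(faces, `[[`, "g"))
  if (!length(a))
    stop("topology error: conductive domain has no internal faces", call. = FALSE)
  ia <- idx[a]; ib <- idx[b_]

  if (check_connected) {
    gr <- igraph::graph_from_edgelist(cbind(ia, ib), directed = FALSE)
    if (igraph::vcount(gr) < nu || igraph::components(gr)$no > 1L)
      stop("topology error: conductive domain is disconnected", call. = FALSE)
  }

  A <- Matrix::sparseMatrix(i = c(ia, ib, ia, ib),
                            j = c(ib, ia, ia, ib),
                            x = c(-g, -g, g, g),
                            dims = c(nu, nu))

  rhs <- numeric(nu)
  ref <- 1L
  if (!is.null(cond$electrodes)) {
    cur <- vapply(cond$electrodes, function(e) e$current_mA, numeric(1))
    if (abs(sum(cur)) > 1e-9 * max(abs(cur), 1))
      stop("parameter error: electrode currents must sum to zero", call. = FALSE)
    for (e in cond$electrodes) {
      v <- idx[e$voxels]
      if (any(v == 0L))
        stop("topology error: electrode voxel outside conductive domain",
             call. = FALSE)
      rhs[v] <- rhs[v] + (e$current_mA / 1000) / length(v)
    }
    # gauge: pin the voxel of the (first, most negative) cathode nearest its
    # disc axis mid-conductor point
    kc <- which.min(cur)
    ec <- cond$electrodes[[kc]]
    ijk <- arrayInd(ec$voxels, d)
    xyz <- sweep((ijk - 1) * cond$voxel_size_mm, 2, -cond$origin_mm)
    ref <- idx[ec$voxels[which.min(colSums((t(xyz) - ec$center_mm)^2))]]
  }
  structure(list(A = A, b = rhs, index = idx, mask = mask, ref = ref,
                 voxel_size_mm = cond$voxel_size_mm,
                 origin_mm = cond$origin_mm,
                 labels = cond$labels, sigma = cond$sigma,
                 label_table = cond$label_table,
                 shell_radii_mm = cond$shell_radii_mm,
                 electrodes = cond$electrodes,
                 sigma_cap = sigma_cap),
            class = "fv_system")
}

default_maxit <- function(n) as.integer(ceiling(10 * n^(1 / 3) * 100))

#' Solve for the electric potential
#'
#' Jacobi-preconditioned conjugate gradient on the gauge-reduced symmetric
#' positive-definite system, with a fixed zero initial guess so repeated
#' solves are bit-identical.
#'
#' @param system an `fv_system` from [assemble_system()].
#' @param tolerance relative residual tolerance (default 1e-8).
#' @param maxit iteration cap; defaults to `10 * n^(1/3) * 100`.
#' @param on_fail `"error"` (default) to stop on non-convergence, `"warn"` to
#'   return the unconverged solution flagged with its residual.
#' @return a `field_solution` with the potential filled (volts; `NA` at air
#'   voxels), solver residual and iteration count.
#' @export
solve_potential <- function(system, tolerance = 1e-8, maxit = NULL,
                            on_fail = c("error", "warn")) {
  on_fail <- match.arg(on_fail)
  nu <- length(system$b)
  if (abs(sum(system$b)) > 1e-12 * max(abs(system$b), 1e-300))
    stop("parameter error: injected currents do not sum to zero", call. = FALSE)
  maxit <- maxit %||% default_maxit(nu)
  keep <- setdiff(seq_len(nu), system$ref)
  Ar <- methods::as(system$A[keep, keep, drop = FALSE], "generalMatrix")
  Ar <- methods::as(Ar, "CsparseMatrix")
  res <- .pcg_jacobi(Ar, system$b[keep], tolerance, as.integer(maxit))
  if (!res$converged) {
    msg <- sprintf("solver did not converge: relative residual %.3g after %d iterations",
                   res$relres, res$iterations)
    if (on_fail == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  v <- numeric(nu)
  v[keep] <- res$x
  V <- array(NA_real_, dim = dim(system$labels))
  V[system$mask] <- v
  pos <- vapply(system$electrodes %||% list(),
                function(e) max(e$current_mA, 0), numeric(1))
  structure(list(potential = V, efield = NULL, magnitude = NULL,
                 injected_current_mA = sum(pos),
                 residual = res$relres, iterations = res$iterations,
                 converged = res$converged,
                 voxel_size_mm = system$voxel_size_mm,
                 origin_mm = system$origin_mm,
                 labels = system$labels, sigma = system$sigma,
                 label_table = system$label_table,
                 shell_radii_mm = system$shell_radii_mm,
                 electrodes = system$electrodes,
                 sigma_cap = system$sigma_cap),
            class = "field_solution")
}

# Shift an array by one voxel along an axis, filling with NA.
shift_array <- function(x, axis, by) {
  d <- dim(x)
  out <- array(NA_real_, dim = d)
  src <- dst <- lapply(d, seq_len)
  if (by > 0) { dst[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1) }
  else        { dst[[axis]] <- 1:(d[axis] - 1); src[[axis]] <- 2:d[axis] }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

#' Derive the vector E-field and its magnitude from the potential
#'
#' E = -grad V by central differences in the interior and one-sided
#' differences at tissue-air boundaries; units V/m given volts and the voxel
#' size converted to metres.
#'
#' @param solution a `field_solution` with the potential filled.
#' @return the solution with `efield` (list of three arrays, V/m) and
#'   `magnitude` filled.
#' @export
compute_efield <- function(solution) {
  V <- solution$potential
  if (is.null(V)) stop("potential not solved yet", call. = FALSE)
  h_m <- solution$voxel_size_mm / 1000
  comp <- vector("list", 3)
  for (ax in 1:3) {
    Vp <- shift_array(V, ax, -1)   # value at i+1
    Vm <- shift_array(V, ax, +1)   # value at i-1
    central <- (Vp - Vm) / (2 * h_m)
    fwd <- (Vp - V) / h_m
    bwd <- (V - Vm) / h_m
    gradV <- central
    use_f <- is.na(gradV) & !is.na(fwd)
    gradV[use_f] <- fwd[use_f]
    use_b <- is.na(gradV) & !is.na(bwd)
    gradV[use_b] <- bwd[use_b]
    gradV[is.na(gradV) & !is.na(V)] <- 0
    comp[[ax]] <- -gradV
  }
  solution$efield <- list(x = comp[[1]], y = comp[[2]], z = comp[[3]])
  solution$magnitude <- sqrt(comp[[1]]^2 + comp[[2]]^2 + comp[[3]]^2)
  solution
}

#' @export
print.field_solution <- function(x, ...) {
  cat("<field_solution> ", paste(dim(x$potential), collapse = " x "),
      " voxels; ", x$injected_current_mA, " mA injected; ",
      x$iterations, " iterations, residual ", format(x$residual, digits = 3),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' Check current conservation through a closed surface
#'
#' Sums the normal current through the boundary of a voxel region that must
#' enclose exactly one electrode entirely, and compares it with that
#' electrode's injected current.
#'
#' @param solution a solved `field_solution`.
#' @param region logical array (same grid): the enclosed voxel set whose
#'   boundary is the separating surface.
#' @return relative conservation error, `abs(flux/injected - 1)`; the summed
#'   flux in amperes is attached as attribute `"flux_A"`.
#' @export
check_current_conservation <- function(solution, region) {
  if (!identical(dim(region), dim(solution$potential)))
    stop("geometry error: region grid mismatch", call. = FALSE)
  inside <- vapply(solution$electrodes, function(e) {
    fr <- mean(region[e$voxels])
    if (fr > 0 && fr < 1)
      stop("geometry error: surface is not closed around an electrode ",
           "(electrode straddles the region boundary)", call. = FALSE)
    fr == 1
  }, logical(1))
  if (sum(inside) != 1L)
    stop("geometry error: region must enclose exactly one electrode",
         call. = FALSE)
  injected_A <- solution$electrodes[[which(inside)]]$current_mA / 1000

  V <- solution$potential
  mask <- !is.na(V)
  h_m <- solution$voxel_size_mm / 1000
  flux <- 0
  for (ax in 1:3) {
    fc <- face_conductances(solution$sigma, mask, ax, h_m, solution$sigma_cap)
    out_ab <- region[fc$a] & !region[fc$b]   # outward a -> b
    out_ba <- region[fc$b] & !region[fc$a]   # outward b -> a
    flux <- flux +
      sum(fc$g[out_ab] * (V[fc$a[out_ab]] - V[fc$b[out_ab]])) +
      sum(fc$g[out_ba] * (V[fc$b[out_ba]] - V[fc$a[out_ba]]))
  }
  structure(abs(flux / injected_A - 1), flux_A = flux)
}

#' Assemble, solve and differentiate in one call
#'
#' Convenience wrapper: [assemble_system()], [solve_potential()],
#' [compute_efield()].
#'
#' @inheritParams assemble_system
#' @inheritParams solve_potential
#' @return a `field_solution` with potential, E-field and magnitude filled.
#' @export
solve_tdcs <- function(cond, tolerance = 1e-8, maxit = NULL,
                       check_connected = TRUE, sigma_cap = 1e4,
                       on_fail = c("error", "warn")) {
  sys <- assemble_system(cond, check_connected = check_connected,
                         sigma_cap = sigma_cap)
  sol <- solve_potential(sys, tolerance = tolerance, maxit = maxit,
                         on_fail = on_fail)
  compute_efield(sol)
}
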