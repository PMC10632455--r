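# Shared fixtures: down-scaled phantoms keep solve times small while
# preserving the five-shell structure; oracles are independent re-computations
# (brute-force voxel scans, closed forms, dense solves).

LABEL_CODES_test <- function() lesionfield:::LABEL_CODES
normalize_test <- function(v) v / sqrt(sum(v^2))

# ~7k unknowns at 2 mm: sub-second solves.
tiny_phantom <- function() build_phantom(c(24, 22, 20, 19, 16), voxel_size_mm = 2)

tiny_roi <- function(ph = tiny_phantom()) define_roi(ph, c(0, 0, 1), radius_mm = 6)

tiny_montage <- function(current_mA = 1)
  montage_for_roi(c(0, 0, 1), current_mA = current_mA,
                  disc_radius_mm = 6, thickness_mm = 2)

tiny_solution <- function(current_mA = 1, lesion_mask = NULL,
                          lesion_sigma = 1.0, tolerance = 1e-10) {
  ph <- tiny_phantom()
  lv <- place_electrodes(ph, tiny_montage(current_mA))
  if (!is.null(lesion_mask)) lv <- apply_lesion(lv, lesion_mask)
  solve_tdcs(assign_conductivity(lv, default_conductivities(lesion = lesion_sigma)),
             tolerance = tolerance)
}

# ~51k unknowns at 2 mm: a few seconds per solve.
small_phantom <- function() build_phantom(c(46, 43, 40, 39, 35), voxel_size_mm = 2)

# Independent sort-based percentile oracle: linear interpolation between order
# statistics at h = (n - 1) p + 1.
percentile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  k <- floor(h)
  if (k >= n) return(s[n])
  s[k] + (h - k) * (s[k + 1] - s[k])
}

# Brute-force voxel scan: linear indices of voxels with centre within radius,
# optionally restricted to label codes. Independent of sphere_indices().
brute_sphere <- function(vol, center, radius, codes = NULL) {
  d <- dim(vol$labels)
  ax <- lapply(1:3, function(a) vol$origin_mm[a] + (seq_len(d[a]) - 1) * vol$voxel_size_mm)
  hit <- integer(0)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) {
    dz2 <- (ax[[3]][k] - center[3])^2
    dy2 <- (ax[[2]][j] - center[2])^2
    if (dy2 + dz2 > radius^2) next
    dx2 <- (ax[[1]] - center[1])^2
    i <- which(dx2 + dy2 + dz2 <= radius^2 + 1e-9)
    if (length(i)) hit <- c(hit, i + (j - 1) * d[1] + (k - 1) * d[1] * d[2])
  }
  if (!is.null(codes)) hit <- hit[vol$labels[hit] %in% codes]
  as.integer(sort(hit))
}
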