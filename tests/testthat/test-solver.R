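test_that("face conductances are harmonic means of adjacent conductivities", {
  # 2-voxel domain with sigma1, sigma2
  labels <- array(c(4L, 5L), dim = c(2, 1, 1))  # gm | wm
  lv <- lesionfield:::new_label_volume(labels, 2, c(0, 0, 0))
  cond <- assign_conductivity(lv, c(gm = 0.3, wm = 0.1))
  sys <- assemble_system(cond, check_connected = FALSE)
  h_m <- 0.002
  g <- h_m * 2 * 0.3 * 0.1 / (0.3 + 0.1)
  A <- as.matrix(sys$A)
  expect_equal(A[1, 2], -g)
  expect_equal(A[2, 1], -g)
  expect_equal(A[1, 1], g)
  # conservation structure: row sums vanish
  expect_lt(max(abs(rowSums(A))), 1e-15)
})

test_that("assembly rejects empty or disconnected domains", {
  labels <- array(0L, dim = c(4, 4, 4))
  lv <- lesionfield:::new_label_volume(labels, 2, c(0, 0, 0))
  cond <- assign_conductivity(lv, c(air = 2.5e-14))
  expect_error(assemble_system(cond), "topology error")
  # two islands of tissue
  labels2 <- array(0L, dim = c(5, 1, 1))
  labels2[c(1, 2, 4, 5)] <- 4L
  lv2 <- lesionfield:::new_label_volume(labels2, 2, c(0, 0, 0))
  cond2 <- assign_conductivity(lv2, c(air = 2.5e-14, gm = 0.276))
  expect_error(assemble_system(cond2), "disconnected|no internal faces")
})

test_that("system row sums are zero away from sources on a real phantom", {
  lv <- place_electrodes(tiny_phantom(), tiny_montage())
  sys <- assemble_system(assign_conductivity(lv, default_conductivities()))
  rs <- Matrix::rowSums(sys$A)
  expect_lt(max(abs(rs)) / max(Matrix::diag(sys$A)), 1e-12)
})

test_that("a three-layer slab reproduces the series-resistor closed form", {
  sl <- make_slab_fixture(c(10, 10, 10), c(0.1, 1.0, 0.5), current_mA = 1,
                          nx = 8, ny = 8, voxel_size_mm = 2)
  sol <- solve_tdcs(sl$cond, tolerance = 1e-10)
  mid_k <- vapply(1:3, function(l) {
    ks <- which(sl$layer_of_k == l)
    ks[ceiling(length(ks) / 2)]
  }, integer(1))
  e_meas <- vapply(mid_k, function(k) mean(sol$magnitude[, , k]), numeric(1))
  expect_equal(e_meas / sl$E_layers, rep(1, 3), tolerance = 0.01)
  # 10 : 1 : 2 magnitude ratio
  expect_equal(e_meas / e_meas[2], c(10, 1, 2), tolerance = 0.01)
})

test_that("a homogeneous slab carries E = I / (A sigma)", {
  sl <- make_slab_fixture(20, 0.3, current_mA = 2, nx = 6, ny = 6,
                          voxel_size_mm = 2)
  sol <- solve_tdcs(sl$cond, tolerance = 1e-10)
  k <- which(sl$layer_of_k == 1)[5]
  expect_equal(mean(sol$magnitude[, , k]), sl$J_A_per_m2 / 0.3,
               tolerance = 0.005)
})

test_that("current is conserved through a separating surface", {
  sl <- make_slab_fixture(c(10, 10, 10), c(0.1, 1.0, 0.5), current_mA = 1,
                          nx = 8, ny = 8, voxel_size_mm = 2)
  sol <- solve_tdcs(sl$cond, tolerance = 1e-10)
  region <- array(FALSE, dim = dim(sol$potential))
  region[, , 1:8] <- TRUE              # encloses the bottom plate (anode)
  err <- check_current_conservation(sol, region)
  expect_lt(as.numeric(err), 0.01)
  # doubling the injected current doubles the flux, not the relative error
  sl2 <- make_slab_fixture(c(10, 10, 10), c(0.1, 1.0, 0.5), current_mA = 2,
                           nx = 8, ny = 8, voxel_size_mm = 2)
  sol2 <- solve_tdcs(sl2$cond, tolerance = 1e-10)
  err2 <- check_current_conservation(sol2, region)
  expect_equal(attr(err2, "flux_A"), 2 * attr(err, "flux_A"), tolerance = 1e-6)
  expect_lt(as.numeric(err2), 0.01)
  # unconverged solve is flagged and violates conservation
  sys <- assemble_system(sl$cond, check_connected = FALSE)
  expect_warning(bad <- solve_potential(sys, 1e-10, maxit = 1, on_fail = "warn"),
                 "did not converge")
  expect_false(bad$converged)
  bad <- compute_efield(bad)
  expect_gt(as.numeric(check_current_conservation(bad, region)), 0.01)
  # surface must enclose exactly one electrode
  whole <- array(TRUE, dim = dim(sol$potential))
  expect_error(check_current_conservation(sol, whole), "exactly one")
  cut <- region; cut[1, 1, 1] <- FALSE  # slices through the anode plate
  expect_error(check_current_conservation(sol, cut), "not closed")
})

test_that("solutions are linear in the applied current and odd under polarity swap", {
  s1 <- tiny_solution(current_mA = 1)
  s2 <- tiny_solution(current_mA = 2)
  m <- !is.na(s1$potential)
  scale <- max(abs(s1$potential[m]))
  expect_lt(max(abs(s2$potential[m] - 2 * s1$potential[m])) / scale, 1e-6)
  expect_lt(max(abs(s2$magnitude[m] - 2 * s1$magnitude[m])) /
              max(s1$magnitude[m]), 1e-6)

  ph <- tiny_phantom()
  # anode/cathode swap = negating every electrode current
  mont_neg <- lapply(tiny_montage(), function(e) { e$current_mA <- -e$current_mA; e })
  s_neg <- solve_tdcs(assign_conductivity(place_electrodes(ph, mont_neg),
                                          default_conductivities()),
                      tolerance = 1e-10)
  # the gauge is pinned at the cathode centre, which moves with the swap, so
  # the negated potential agrees up to that additive constant
  offset <- mean(s_neg$potential[m] + s1$potential[m])
  expect_lt(max(abs(s_neg$potential[m] + s1$potential[m] - offset)) / scale, 1e-6)
  expect_lt(max(abs(s_neg$efield$x[m] + s1$efield$x[m])) /
              max(s1$magnitude[m]), 1e-6)
  expect_lt(max(abs(s_neg$efield$z[m] + s1$efield$z[m])) /
              max(s1$magnitude[m]), 1e-6)
  expect_lt(max(abs(s_neg$magnitude[m] - s1$magnitude[m])) /
              max(s1$magnitude[m]), 1e-6)
})

test_that("repeated solves with identical inputs are bit-identical", {
  a <- tiny_solution()
  b <- tiny_solution()
  expect_identical(a$potential, b$potential)
  expect_identical(a$magnitude, b$magnitude)
  expect_identical(a$iterations, b$iterations)
})

test_that("the iterative solution matches a dense direct solve on a small grid", {
  ph <- build_phantom(c(16, 15, 13, 12, 10), voxel_size_mm = 2)  # 21^3 grid
  lv <- place_electrodes(ph, montage_for_roi(c(0, 0, 1), disc_radius_mm = 5))
  sys <- assemble_system(assign_conductivity(lv, default_conductivities()))
  sol <- solve_potential(sys, tolerance = 1e-12)
  keep <- setdiff(seq_along(sys$b), sys$ref)
  dense <- solve(as.matrix(sys$A[keep, keep]), sys$b[keep])
  v_iter <- sol$potential[sys$mask][keep]
  expect_lt(max(abs(v_iter - dense)) / max(abs(dense)), 1e-6)
})

test_that("the E-field of a linear potential is exact and uniform fields are flat", {
  fx <- make_field_fixture("linear", amplitude = 0.3,
                           phantom = tiny_phantom())
  sol <- compute_efield(fx)
  # voxels with an in-domain neighbour along the axis (single-voxel poles of
  # the sphere fall back to a zero component there)
  m <- !is.na(sol$potential)
  mx <- m & (!is.na(lesionfield:::shift_array(fx$potential, 1, -1)) |
               !is.na(lesionfield:::shift_array(fx$potential, 1, +1)))
  mz <- m & (!is.na(lesionfield:::shift_array(fx$potential, 3, -1)) |
               !is.na(lesionfield:::shift_array(fx$potential, 3, +1)))
  expect_equal(max(abs(sol$efield$x[mx] - 0.3)), 0, tolerance = 1e-9)
  expect_equal(max(abs(sol$efield$z[mz] - 0.3)), 0, tolerance = 1e-9)
  # uniform potential -> zero field
  fx$potential[m] <- 1.5
  sol0 <- compute_efield(fx)
  expect_equal(max(abs(sol0$magnitude[m])), 0)
})
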