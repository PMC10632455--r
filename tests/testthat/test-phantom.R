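test_that("phantom shells are nested along random rays", {
  ph <- tiny_phantom()
  rank_of <- c(air = 0, skin = 1, skull = 2, csf = 3, gm = 4, wm = 5)
  set.seed(42)
  for (ray in 1:100) {
    u <- normalize_test(stats::rnorm(3))
    r <- seq(0, 30, by = 0.9)
    pts <- outer(r, u)
    labs <- vapply(seq_len(nrow(pts)), function(i) {
      ijk <- round((pts[i, ] - ph$origin_mm) / ph$voxel_size_mm) + 1
      if (any(ijk < 1) || any(ijk > dim(ph$labels))) return(0L)
      ph$labels[ijk[1], ijk[2], ijk[3]]
    }, integer(1))
    ranks <- rank_of[match(labs, LABEL_CODES_test()[names(rank_of)])]
    expect_true(all(diff(ranks) <= 0),
                info = paste("ray", ray, "not monotone inward->outward"))
  }
})

test_that("phantom labelling matches analytic sphere geometry", {
  ph <- build_phantom(voxel_size_mm = 2)  # default 92/86/80/78/70 radii
  ctr <- round((c(0, 0, 0) - ph$origin_mm) / ph$voxel_size_mm) + 1
  expect_equal(ph$labels[ctr[1], ctr[2], ctr[3]],
               LABEL_CODES_test()[["wm"]])
  far <- round((c(0, 0, 95) - ph$origin_mm) / ph$voxel_size_mm) + 1
  expect_equal(ph$labels[far[1], far[2], far[3]],
               LABEL_CODES_test()[["air"]])
  brain_vox <- sum(ph$labels %in% LABEL_CODES_test()[c("gm", "wm")])
  brain_vol <- brain_vox * ph$voxel_size_mm^3
  expect_lt(abs(brain_vol - 4 / 3 * pi * 78^3) / (4 / 3 * pi * 78^3), 0.02)
})

test_that("phantom generation is deterministic and rejects bad radii", {
  expect_identical(tiny_phantom()$labels, tiny_phantom()$labels)
  expect_error(build_phantom(c(80, 86, 78, 70, 60)), "descending")
  expect_error(build_phantom(c(92, 86, 80, 78, -1)), "descending|positive")
})

test_that("ROI lands mid grey-matter and matches a brute-force voxel scan", {
  ph <- tiny_phantom()
  roi <- define_roi(ph, c(0, 0, 1), radius_mm = 6)
  expect_equal(roi$center_mm, c(0, 0, 17.5))  # gm shell 16-19 mm
  got <- sort(lesionfield:::roi_gm_indices(ph, roi))
  want <- brute_sphere(ph, roi$center_mm, 6, LABEL_CODES_test()[["gm"]])
  expect_identical(got, want)
  expect_gt(length(got), 0)
})

test_that("ROI placement fails outside grey matter", {
  ph <- tiny_phantom()
  # explicit centre deep in white matter: inside brain but no gm in reach
  expect_error(define_roi(ph, c(0, 0, 1), radius_mm = 2, center_mm = c(0, 0, 0)),
               "geometry error")
  # centre outside the brain mask entirely
  expect_error(define_roi(ph, c(0, 0, 1), radius_mm = 6, center_mm = c(0, 0, 23)),
               "geometry error")
  expect_error(define_roi(ph, c(0, 0, 2), radius_mm = 6), "unit norm")
})

test_that("conductivity assignment is a pure table lookup", {
  ph <- tiny_phantom()
  cond <- assign_conductivity(ph, default_conductivities(lesion = 1.4))
  gm_vox <- which(ph$labels == LABEL_CODES_test()[["gm"]])[1]
  csf_vox <- which(ph$labels == LABEL_CODES_test()[["csf"]])[1]
  expect_equal(cond$sigma[gm_vox], 0.276)
  expect_equal(cond$sigma[csf_vox], 1.65)
  wm_vox <- which(ph$labels == LABEL_CODES_test()[["wm"]])[1]
  expect_equal(cond$sigma[wm_vox], 0.126)
  # lesion voxels inherit the configured lesion conductivity
  les <- apply_lesion(ph, which(ph$labels == LABEL_CODES_test()[["wm"]])[1:10])
  cond_l <- assign_conductivity(les, default_conductivities(lesion = 1.4))
  expect_true(all(cond_l$sigma[ph$labels == LABEL_CODES_test()[["wm"]]][1:10] == 1.4))
  # exactly reproducible
  expect_identical(cond$sigma, assign_conductivity(ph, default_conductivities(lesion = 1.4))$sigma)
  # missing label -> configuration error
  tab <- default_conductivities()
  expect_error(assign_conductivity(ph, tab[names(tab) != "csf"]),
               "configuration error")
})

test_that("electrode discs rasterise as disjoint scalp patches of the right size", {
  ph <- build_phantom(voxel_size_mm = 2)
  mont <- list(electrode(0, 0, 1), electrode(180, 0, -1))  # antipodal
  lv <- place_electrodes(ph, mont)
  e1 <- lv$electrodes[[1]]; e2 <- lv$electrodes[[2]]
  expect_length(intersect(c(e1$voxels, e1$gel_voxels),
                          c(e2$voxels, e2$gel_voxels)), 0)
  # patch area from the one-layer conductor: voxel count x face area
  for (e in lv$electrodes) {
    area <- length(e$voxels) * ph$voxel_size_mm^2
    expect_lt(abs(area - pi * 17^2) / (pi * 17^2), 0.15)
  }
  # head tissues untouched
  head_codes <- LABEL_CODES_test()[c("skin", "skull", "csf", "gm", "wm")]
  expect_identical(lv$labels[lv$labels %in% head_codes],
                   ph$labels[lv$labels %in% head_codes])
})

test_that("montage validation enforces the bipolar contract", {
  ph <- tiny_phantom()
  expect_error(place_electrodes(ph, list(electrode(0, 0, 1))), "at least 2")
  expect_error(place_electrodes(ph, list(electrode(0, 0, 1),
                                         electrode(180, 0, -0.5))),
               "sum to zero")
  expect_error(place_electrodes(ph, list(electrode(0, 0, 1, disc_radius_mm = 6),
                                         electrode(5, 0, -1, disc_radius_mm = 6))),
               "overlapping")
  # (+1, -1) is accepted
  expect_s3_class(place_electrodes(ph, tiny_montage()), "label_volume")
})

test_that("conductivity and field volumes write as NIfTI", {
  ph <- tiny_phantom()
  cond <- assign_conductivity(ph, default_conductivities())
  p1 <- tempfile(fileext = ".nii.gz")
  write_field_volume(cond, p1)
  img <- RNifti::readNifti(p1)
  expect_equal(dim(img), dim(cond$sigma))
  expect_equal(max(abs(img[ph$labels == 4L] - 0.276)), 0, tolerance = 1e-6)
  fx <- make_field_fixture("uniform", 0.2, ph)
  p2 <- tempfile(fileext = ".nii.gz")
  write_field_volume(fx, p2, what = "efield")
  expect_equal(dim(RNifti::readNifti(p2)), c(dim(ph$labels), 3))
  unlink(c(p1, p2))
})

test_that("label volumes round-trip through NIfTI", {
  ph <- tiny_phantom()
  path <- tempfile(fileext = ".nii.gz")
  write_label_volume(ph, path)
  back <- read_label_volume(path)
  expect_identical(back$labels, ph$labels)
  expect_equal(back$voxel_size_mm, ph$voxel_size_mm)
  expect_equal(back$origin_mm, ph$origin_mm)
  unlink(path)
})
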