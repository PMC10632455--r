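tiny_config <- function(outdir = NULL, conds = c(0.2, 1.65))
  experiment_config(shell_radii_mm = c(24, 22, 20, 19, 16), voxel_size_mm = 2,
                    rois = list(target = c(0, 0, 1)),
                    montages = list(target = tiny_montage()),
                    lesion_grid = list(directions = c("I", "RAI", "LPI"),
                                       gap_mm = 1, radius_mm = 4,
                                       conductivity_S_per_m = conds),
                    roi_radius_mm = 6, tolerance = 1e-8, output_dir = outdir)

test_that("the factorial runner emits one row per state and is resumable", {
  outdir <- tempfile("lfrun")
  cfg <- tiny_config(outdir)
  tab <- run_factorial(cfg)
  expect_equal(nrow(tab), 3 * 1 * 1 * 2)
  expect_true(all(c("pct_diff", "angle_deg", "exclusion_reason") %in% names(tab)))
  n1 <- attr(tab, "n_solves")
  expect_gt(n1, 0)
  valid <- tab[tab$valid, ]
  expect_true(all(is.finite(valid$pct_diff)))
  # angle is constant across conductivities of one geometry
  expect_true(all(tapply(valid$angle_deg,
                         paste(valid$direction, valid$gap_mm, valid$radius_mm),
                         function(a) diff(range(a)) == 0)))

  # resume: a second run over a completed directory performs zero solves
  tab2 <- run_factorial(cfg)
  expect_equal(attr(tab2, "n_solves"), 0)
  expect_equal(nrow(tab2), nrow(tab))
  expect_equal(sort(tab2$pct_diff[tab2$valid]), sort(tab$pct_diff[tab$valid]))
  unlink(outdir, recursive = TRUE)
})

test_that("a host-conductivity lesion is a physical no-op", {
  # lesion fully inside white matter (direction I stays clear of grey
  # matter), conductivity = white matter
  cfg <- tiny_config(conds = 0.126)
  cfg$lesion_grid$directions <- "I"
  tab <- run_factorial(cfg)
  expect_true(all(tab$valid))
  expect_equal(tab$volume_fraction, 1)
  expect_true(all(abs(tab$pct_diff) < 0.1))
})

test_that("trend fits recover planted coefficients", {
  # noiseless: exact recovery
  tab0 <- make_planted_table(c(intercept = 3, angle_deg = -0.06,
                               radius_mm = 0.5), noise_sd = 0, n_rows = 200,
                             seed = 11)
  fit0 <- fit_trends(tab0, "pct_diff")
  co <- coef(fit0)
  expect_equal(unname(co["angle_deg"]), -0.06, tolerance = 1e-8)
  expect_equal(unname(co["radius_mm"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(co["angle_deg:gap_mm"]), 0, tolerance = 1e-8)

  # noisy: within 3 standard errors
  tab <- make_planted_table(c(angle_deg = -0.06), noise_sd = 1, n_rows = 630,
                            seed = 4)
  fit <- fit_trends(tab, "pct_diff")
  est <- coef(fit)["angle_deg"]; se <- fit$se["angle_deg"]
  expect_lt(abs(est - (-0.06)), 3 * se)

  # constant response: zero slopes, intercept equals the constant
  tabc <- make_planted_table(c(intercept = 7), noise_sd = 0, n_rows = 100,
                             seed = 2)
  fitc <- fit_trends(tabc, "abs_pct_diff")
  expect_equal(unname(coef(fitc)["(Intercept)"]), 7, tolerance = 1e-10)
  expect_equal(max(abs(coef(fitc)[-1])), 0, tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  tab <- make_planted_table(c(angle_deg = -0.06), noise_sd = 1, n_rows = 100,
                            seed = 5)
  tab$radius_mm <- tab$gap_mm          # duplicated predictor
  expect_error(fit_trends(tab, "abs_pct_diff"), "radius_mm")
  expect_error(fit_trends(tab[1:10, ], "abs_pct_diff"), "at least 30")
})

test_that("the experiment summary matches a hand computation on a small fixture", {
  tab <- data.frame(
    roi = "t", direction = c("R", "R", "L", "L", "S", "S"),
    gap_mm = c(1, 5, 1, 5, 1, 5), radius_mm = c(4, 4, 12, 12, 24, 24),
    conductivity_S_per_m = 1.0,
    valid = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    exclusion_reason = c("none", "none", "none", "none",
                         "centre_outside_brain", "none"),
    pct_diff = c(10, 6, -4, -2, NA, 8),
    abs_pct_diff = c(10, 6, 4, 2, NA, 8))
  s <- summarise_experiment(tab)
  expect_equal(s$n_total, 6)
  expect_equal(s$n_valid, 5)
  expect_equal(s$n_solved, 5)
  expect_equal(s$by_gap$mean_abs_pct_diff[s$by_gap$level == 1], mean(c(10, 4)))
  expect_equal(s$by_gap$mean_abs_pct_diff[s$by_gap$level == 5], mean(c(6, 2, 8)))
  expect_equal(s$by_radius$mean_abs_pct_diff[s$by_radius$level == 4],
               mean(c(10, 6)))
  expect_equal(unname(s$exclusions["centre_outside_brain"]), 1)
  d <- s$by_direction
  expect_equal(d$pct_diff[d$direction == "L"], -3)

  # one valid row: reported verbatim
  one <- tab[1, ]
  s1 <- summarise_experiment(one)
  expect_equal(s1$by_radius$mean_abs_pct_diff, 10)
})

test_that("experiment configs round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "shell_radii_mm: [24, 22, 20, 19, 16]",
    "voxel_size_mm: 2",
    "roi_radius_mm: 6",
    "rois:",
    "  target: [0, 0, 1]",
    "montages:",
    "  target:",
    "    - {theta_deg: 40, phi_deg: 225, current_mA: 1, disc_radius_mm: 6}",
    "    - {theta_deg: 80, phi_deg: 45, current_mA: -1, disc_radius_mm: 6}",
    "conductivities:",
    "  skull: 0.5",
    "lesion_grid:",
    "  directions: [I, RAI]",
    "  gap_mm: [1]",
    "  radius_mm: [4]",
    "  conductivity_S_per_m: [0.2, 1.8]"), path)
  cfg <- read_experiment_config(path)
  expect_s3_class(cfg, "experiment_config")
  expect_equal(cfg$shell_radii_mm, c(24, 22, 20, 19, 16))
  expect_equal(cfg$lesion_grid$directions, c("I", "RAI"))
  expect_equal(unname(cfg$conductivities["skull"]), 0.5)
  expect_equal(unname(cfg$conductivities["csf"]), 1.65)
  expect_length(cfg$montages$target, 2)
  tab <- run_factorial(cfg)
  expect_equal(nrow(tab), 4)
  unlink(path)
})
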