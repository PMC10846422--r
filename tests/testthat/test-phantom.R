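test_that("material fractions close to 1 in every voxel and stay in range", {
  ph <- demo_scene()
  expect_silent(validate_tissue_grid(ph))
  s <- rowSums(matrix(ph$fractions, ncol = 5))
  expect_lt(max(abs(s - 1)), 1e-9)
  expect_gte(min(ph$fractions), 0)
  expect_lte(max(ph$fractions), 1)
})

test_that("balloon geometry matches the protocol arithmetic", {
  expect_equal(round(ellipsoid_volume(c(7, 4, 3))), 44)
  # full-study grid spacing from extents / voxel counts
  sp <- c(5.8, 5.4, 3.6) / c(250, 231, 155)
  expect_equal(sp, c(0.0232, 0.023376623, 0.023225806), tolerance = 1e-6)
})

test_that("phantom regions are laid out as specified", {
  ph <- demo_scene()
  fr <- ph$fractions
  expect_true(all(fr[, , , "intralipid"][ph$labels == 1L] == 1))
  expect_true(all(fr[, , , "saline"][ph$labels == 2L] == 1))
  expect_true(all(fr[, , , "gbm"][ph$labels == 4L] == 1))  # solid sphere
  expect_gt(sum(ph$labels == 4L), 0)
  # no photosensitizer-bearing tissue inside the cavity
  expect_true(all(fr[, , , "gbm"][ph$labels %in% c(1L, 2L)] == 0))
})

test_that("rim GBM fraction decreases with depth from the cavity wall", {
  ph <- demo_scene()
  ctr <- ph$meta$balloon_center_cm
  sp <- ph$spacing
  j <- ceiling(ctr[2] / sp[2]); k <- ceiling(ctr[3] / sp[3])
  prof <- ph$fractions[, j, k, "gbm"]
  ix0 <- ceiling(ctr[1] / sp[1])
  rimward <- prof[ix0:length(prof)]
  nz <- which(rimward > 0)
  expect_gt(length(nz), 1)
  seg <- rimward[nz[1]:nz[length(nz)]]
  expect_true(all(diff(seg) <= 1e-12))
  # rim extent bounded by the configured thickness (approximate depth map)
  expect_lte(length(nz) * sp[1] * 10, ph$meta$rim_thickness_cm * 10 + 1.5)
})

test_that("degenerate and invalid phantom arguments are rejected", {
  expect_error(make_phantom(grid_shape = c(16, 16, 16),
                            extent_cm = c(2, 2, 2),
                            balloon_axes_cm = c(4, 4, 4)), "larger than")
  expect_error(make_phantom(grid_shape = c(16, 16, 16),
                            extent_cm = c(2, 2, 2),
                            balloon_axes_cm = c(1.4, 1, 1),
                            rim_thickness_mm = -1, margin_cm = 0.2), ">= 0")
  # zero rim: no GBM anywhere outside the solid sphere
  ph0 <- make_phantom(grid_shape = c(24, 24, 24), extent_cm = c(2.4, 2.4, 2.4),
                      balloon_axes_cm = c(1.8, 1.4, 1.2),
                      rim_thickness_mm = 0, sphere_radius_mm = 2,
                      saline_gap_mm = 0.5, margin_cm = 0.3)
  gbm <- ph0$fractions[, , , "gbm"]
  expect_true(all(gbm[ph0$labels != 4L] == 0))
  expect_true(any(gbm[ph0$labels == 4L] == 1))
})

test_that("phantom generation is bit-reproducible for a fixed seed", {
  a <- make_phantom(grid_shape = c(20, 20, 20), extent_cm = c(2, 2, 2),
                    balloon_axes_cm = c(1.4, 1.2, 1), rim_noise = 0.3,
                    margin_cm = 0.2, seed = 7L)
  b <- make_phantom(grid_shape = c(20, 20, 20), extent_cm = c(2, 2, 2),
                    balloon_axes_cm = c(1.4, 1.2, 1), rim_noise = 0.3,
                    margin_cm = 0.2, seed = 7L)
  expect_identical(a$fractions, b$fractions)
  c2 <- make_phantom(grid_shape = c(20, 20, 20), extent_cm = c(2, 2, 2),
                     balloon_axes_cm = c(1.4, 1.2, 1), rim_noise = 0.3,
                     margin_cm = 0.2, seed = 8L)
  expect_false(identical(a$fractions, c2$fractions))
})

test_that("optical mixing follows the fraction-weighted rule", {
  tbl <- material_table()
  # pure white matter voxel
  wm <- tbl[tbl$material == "white", ]
  expect_equal(c(wm$mua, wm$mus, wm$n, wm$g), c(0.63, 686.0, 1.38, 0.85))
  # 50/50 white/gray mixture, no PpIX
  fr <- array(0, dim = c(1, 1, 1, 5),
              dimnames = list(NULL, NULL, NULL,
                              c("white", "gray", "gbm", "intralipid", "saline")))
  fr[1, 1, 1, "white"] <- 0.5; fr[1, 1, 1, "gray"] <- 0.5
  g <- structure(list(fractions = fr,
                      labels = array(0L, dim = c(1, 1, 1)),
                      spacing = c(0.1, 0.1, 0.1), meta = list()),
                 class = "tissue_grid")
  opt <- mix_optics(g, ppix0_uM = 0)
  expect_equal(as.numeric(opt$mua), 0.81)
  expect_equal(as.numeric(opt$mus), (686 + 202) / 2)
  expect_equal(as.numeric(opt$n), 1.38)
})

test_that("PpIX absorption follows the worked-example convention", {
  expect_equal(ppix_absorption(5 * 0.2), 0.0265)
  expect_error(ppix_absorption(-1), ">= 0")
  # unit-rigorous mode converts uM to ug/ml via the molecular weight
  expect_equal(ppix_absorption(1, unit_rigorous = TRUE), 0.5627 * 0.0265)
})

test_that("absorption is affine in PpIX concentration with slope eps * F_GBM", {
  ph <- make_phantom(grid_shape = c(20, 20, 20), extent_cm = c(2, 2, 2),
                     balloon_axes_cm = c(1.4, 1.2, 1), margin_cm = 0.2)
  o0 <- mix_optics(ph, ppix0_uM = 0)
  o5 <- mix_optics(ph, ppix0_uM = 5)
  o10 <- mix_optics(ph, ppix0_uM = 10)
  slope <- (o10$mua - o0$mua) / 10
  expect_equal(slope, ppix_extinction() * ph$fractions[, , , "gbm"],
               tolerance = 1e-12)
  expect_equal(o5$mua, o0$mua + 5 * slope, tolerance = 1e-12)
  # scattering/anisotropy unaffected by concentration
  expect_identical(o5$mus, o0$mus)
  expect_identical(o5$g, o0$g)
})
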