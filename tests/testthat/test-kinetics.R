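test_that("initial oxygen follows Henry-law solubility", {
  expect_equal(initial_o2(kinetics_params()), 38.85)
  expect_equal(initial_o2(kinetics_params(p_tio2 = 0)), 0)
  expect_equal(initial_o2(kinetics_params(alpha_solubility = 1.295 / 2)),
               38.85 / 2)
  # default equilibrium concentration uses the formula value
  expect_equal(kinetics_params()$o2_init, 38.85)
  expect_equal(kinetics_params(o2_init = 38)$o2_init, 38)
})

test_that("perfusion rate follows the Krogh-fit rational polynomial", {
  expect_equal(perfusion_phi(750), 21.6 * 0.32 / 0.31)
  expect_equal(perfusion_phi(1e9) / 21.6, 0.99, tolerance = 1e-6)
  expect_equal(perfusion_phi(750, phi0 = 10), 10 * 0.32 / 0.31)
  expect_error(perfusion_phi(Inf), "finite")
  expect_error(perfusion_phi(NaN), "finite")
})

test_that("dark intervals with full oxygen are a fixed point", {
  p <- kinetics_params()
  st <- single_voxel_run(psi = 0, s0 = 5, seconds = 50, params = p)
  expect_equal(st$s0, 5, tolerance = 1e-12)
  expect_equal(st$o2, p$o2_init, tolerance = 1e-10)
  expect_equal(st$o2rx, 0, tolerance = 1e-12)
})

test_that("no photosensitizer means no singlet oxygen production", {
  st <- single_voxel_run(psi = 200, s0 = 0, seconds = 50)
  expect_equal(st$o2rx, 0, tolerance = 1e-12)
  expect_equal(st$s0, 0, tolerance = 1e-12)
})

test_that("trajectories match an independent adaptive ODE oracle", {
  p <- kinetics_params()
  for (psi in c(20, 50, 150)) {
    ours <- single_voxel_run(psi = psi, s0 = 5, seconds = 100, params = p)
    ref <- oracle_kinetics(psi, 5, times = c(0, 100), params = p)
    expect_equal(ours$s0, ref[2, "s0"], tolerance = 1e-3 * ref[2, "s0"],
                 ignore_attr = TRUE)
    expect_equal(ours$o2, ref[2, "o2"], tolerance = 1e-3 * ref[2, "o2"],
                 ignore_attr = TRUE)
    expect_equal(ours$o2rx, ref[2, "o2rx"], tolerance = 1e-3 * ref[2, "o2rx"],
                 ignore_attr = TRUE)
  }
})

test_that("photosensitizer bleaches and dose accumulates monotonically in light", {
  st <- single_voxel_run(psi = 100, s0 = 5, seconds = 200)
  expect_true(all(diff(st$series$mean_s0) <= 1e-12))
  expect_true(all(diff(st$series$max_o2rx) >= -1e-12))
  expect_lt(st$s0, 5)
  expect_gt(st$o2rx, 0)
})

test_that("oxygen recovers monotonically toward equilibrium in the dark", {
  p <- kinetics_params()
  # deplete under strong light, then switch off
  fl <- structure(list(psi = array(300, dim = c(1, 1, 1))),
                  class = "fluence_grid")
  st <- structure(list(idx = 1L, dims = c(1L, 1L, 1L), fgbm = 1,
                       fgbm_total = 1, s0 = 20, o2 = p$o2_init, o2rx = 0,
                       killed = FALSE, t = 0), class = "kinetics_state")
  sched <- tibble::tibble(light_on = c(TRUE, FALSE),
                          duration_s = c(60, 180))
  st <- kinetics_run(st, fl, sched, power_W = 1, params = p)
  dark <- st$series[!st$series$light_on, ]
  expect_true(all(diff(dark$mean_o2) >= -1e-10))
  expect_true(all(dark$mean_o2 <= p$o2_init + 1e-9))
  expect_equal(dark$mean_o2[nrow(dark)], p$o2_init, tolerance = 1e-3)
})

test_that("fixed-oxygen mode holds oxygen exactly constant", {
  p <- kinetics_params()
  st <- single_voxel_run(psi = 150, s0 = 10, seconds = 120, params = p,
                         fixed_oxygen = TRUE)
  expect_identical(st$o2, p$o2_init)
  expect_true(all(st$series$mean_o2 == p$o2_init))
})

test_that("without photobleaching and with fixed oxygen, dose is linear in fluence", {
  p <- kinetics_params(sigma = 1e-30)
  st <- single_voxel_run(psi = 80, s0 = 5, seconds = 100, params = p,
                         fixed_oxygen = TRUE)
  rate <- p$xi * 80 * 5 * p$o2_init / (p$o2_init + p$beta)
  expect_equal(st$o2rx, rate * 100, tolerance = 1e-6 * rate * 100)
  # doubling exposure time doubles the reacted dose
  st2 <- single_voxel_run(psi = 80, s0 = 5, seconds = 200, params = p,
                          fixed_oxygen = TRUE)
  expect_equal(st2$o2rx, 2 * st$o2rx, tolerance = 1e-6 * st2$o2rx)
})

test_that("kill threshold marks voxels at the boundary correctly", {
  p <- kinetics_params()
  st <- structure(list(idx = 1:3, dims = c(3L, 1L, 1L),
                       fgbm = c(1, 0.5, 0.5), fgbm_total = 2,
                       s0 = c(0, 0, 0), o2 = rep(38.85, 3),
                       o2rx = c(559.99, 560, 700), killed = rep(FALSE, 3),
                       t = 0), class = "kinetics_state")
  thr <- apply_threshold(st, p$threshold)
  expect_identical(thr$killed, c(FALSE, TRUE, TRUE))
  expect_equal(thr$pct_gbm_remaining, 50)
  # +/- 25% scaling gives the study's sensitivity bounds
  expect_equal(p$threshold * c(0.75, 1.25), c(420, 700))
  all_zero <- st; all_zero$o2rx <- rep(0, 3)
  expect_equal(apply_threshold(all_zero, p$threshold)$pct_gbm_remaining, 100)
  expect_error(apply_threshold(st, 0), "> 0")
})

test_that("resection arithmetic converts kill fractions to whole-tumor remnants", {
  expect_equal(residual_tumor_pct(39), 3.05)
  expect_equal(residual_tumor_pct(61), 1.95)
  expect_equal(residual_tumor_pct(0), 5)
})

test_that("cerebral metabolic oxygen consumption reproduces the ratio scaling", {
  expect_equal(metabolic_q0(), 26.3)
  expect_equal(metabolic_q0(1.5, 3.5, 0.2), 26.3)
})

test_that("kinetics parameter validation rejects nonphysical values", {
  expect_error(kinetics_params(xi = -1), "positive")
  expect_error(kinetics_params(bogus = 1), "unknown")
  st <- single_voxel_run(psi = 50, s0 = 5, seconds = 10)
  expect_error(kinetics_run(st, structure(list(psi = array(50, c(1, 1, 1))),
                                          class = "fluence_grid"),
                            tibble::tibble(light_on = TRUE, duration_s = 10),
                            power_W = -2), ">= 0")
})
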