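# uniform brain-like block helper
uniform_block <- function(n, T0 = 37, qdot = 0, bc = 0L, dx_m = 1e-3) {
  d <- rep(n, 3)
  new_temperature_grid(array(T0, d), array(1046, d), array(3630, d),
                       array(0.51, d), array(qdot, d), array(bc, d),
                       dx_m = dx_m)
}

test_that("a uniform insulated block without sources is a fixed point", {
  tg <- uniform_block(8)
  out <- thermal_evolve(tg, tibble::tibble(light_on = FALSE, duration_s = 20))
  expect_equal(out$T, tg$T, tolerance = 1e-12)
  expect_true(all(out$max_trace$max_T == 37))
})

test_that("the discrete maximum principle holds without sources", {
  set.seed(3)
  d <- rep(10, 3)
  T0 <- array(stats::runif(prod(d), 20, 60), d)
  tg <- new_temperature_grid(T0, array(1046, d), array(3630, d),
                             array(0.51, d), dx_m = 1e-3)
  out <- thermal_evolve(tg, tibble::tibble(light_on = FALSE,
                                           duration_s = 120))
  expect_true(all(out$T <= max(T0) + 1e-9))
  expect_true(all(out$T >= min(T0) - 1e-9))
  expect_true(all(diff(out$max_trace$max_T) <= 1e-9))
})

test_that("1-D conduction matches the analytic Fourier-mode decay", {
  # rod with both x-ends held at 0, sine initial profile:
  # T(x,t) = sin(pi x / L) exp(-alpha pi^2 t / L^2)
  n <- 40; dx <- 1e-3; L <- n * dx
  d <- c(n, 3L, 3L)
  xs <- (seq_len(n) - 0.5) * dx
  T0 <- array(rep(sin(pi * xs / L), times = 9), d)
  bc <- array(0L, d); bc[1, , ] <- 2L; bc[n, , ] <- 2L
  tg <- new_temperature_grid(T0, array(1046, d), array(3630, d),
                             array(0.51, d), bc = bc, dx_m = dx,
                             t_room = 0)
  out <- thermal_evolve(tg, tibble::tibble(light_on = FALSE,
                                           duration_s = 300))
  alpha <- 0.51 / (1046 * 3630)
  exact <- sin(pi * xs / L) * exp(-alpha * pi^2 * 300 / L^2)
  expect_lt(max(abs(out$T[, 2, 2] - exact)), 0.05)
})

test_that("a uniform volumetric source heats at qdot/(rho cp) exactly", {
  tg <- uniform_block(6, qdot = 1000)
  out <- thermal_evolve(tg, tibble::tibble(light_on = TRUE,
                                           duration_s = 100))
  expect_equal(out$T, tg$T + 1000 * 100 / (1046 * 3630), tolerance = 1e-9)
  # light off: no heating at all
  off <- thermal_evolve(uniform_block(6, qdot = 1000),
                        tibble::tibble(light_on = FALSE, duration_s = 100))
  expect_equal(off$T, tg$T, tolerance = 1e-12)
})

test_that("heat source is mua * Psi * power with unit conversion", {
  opt <- homog_optics(rep(8L, 3), rep(0.1, 3), mua = 0.8, mus = 50, g = 0.85)
  fl <- transport(opt, n_packets = 4000, seed = 12)
  q1 <- heat_source(opt, fl, power_W = 1)
  q2 <- heat_source(opt, fl, power_W = 2)
  expect_equal(q2, 2 * q1, tolerance = 1e-12)
  expect_true(all(heat_source(opt, fl, 2, light_on = FALSE) == 0))
  # energy bookkeeping: volume integral of qdot equals absorbed power
  dv_m3 <- prod(rep(0.1, 3)) * 1e-6
  expect_equal(sum(q1) * dv_m3, fl$absorbed, tolerance = 0.01 * fl$absorbed)
  bad <- homog_optics(rep(6L, 3), rep(0.1, 3), 0.8, 50, 0.85)
  expect_error(heat_source(bad, fl, 1), "match")
})

test_that("equilibration relaxes the balloon toward brain temperature", {
  ph <- demo_scene()
  fl <- demo_fluence()
  opt <- mix_optics(ph, ppix0_uM = 5)
  tg <- thermal_subgrid(ph, fl, opt, power_W = 2, size_cm = 1.2, n = 24)
  T_before <- tg$T
  cool <- which(tg$T < 30)  # intralipid/saline voxels start at 22 C
  expect_gt(length(cool), 0)
  out <- equilibrate(tg, duration_s = 120)
  expect_true(all(out$T[cool] >= T_before[cool] - 1e-9))
  expect_true(all(out$T <= max(T_before) + 1e-9))
  # brain-facing boundary never drops below body temperature
  expect_true(all(out$T[out$bc == 1L] >= 37 - 1e-9))
})

test_that("fractionated illumination produces a saw-tooth maximum trace", {
  ph <- demo_scene()
  fl <- demo_fluence()
  opt <- mix_optics(ph, ppix0_uM = 5)
  tg <- thermal_subgrid(ph, fl, opt, power_W = 2, size_cm = 1.2, n = 24)
  tg <- equilibrate(tg, duration_s = 120)
  sched <- build_schedule(protocol_spec())
  out <- thermal_evolve(tg, sched)
  tr <- out$max_trace[out$max_trace$t > 120, ]
  seg <- rle(tr$light_on)
  ends <- cumsum(seg$lengths)
  starts <- c(1, head(ends, -1) + 1)
  for (i in seq_along(seg$values)) {
    delta <- tr$max_T[ends[i]] - tr$max_T[starts[i]]
    if (seg$values[i]) expect_gt(delta, 0) else expect_lt(delta, 0)
  }
})

test_that("maximum temperature is monotone in source power", {
  ph <- demo_scene()
  fl <- demo_fluence()
  opt <- mix_optics(ph, ppix0_uM = 5)
  sched <- build_schedule(protocol_spec())
  run_p <- function(p) {
    tg <- thermal_subgrid(ph, fl, opt, power_W = p, size_cm = 1.2, n = 24)
    tg <- equilibrate(tg, duration_s = 120)
    thermal_evolve(tg, sched)$max_trace$max_T
  }
  t2 <- run_p(2); t4 <- run_p(4)
  expect_true(all(t4 >= t2 - 1e-9))
  expect_gt(max(t4), max(t2))
})
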