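test_that("free-path sampling is exponential with mean 1/mu_t", {
  n <- 1e6
  s10 <- sample_step(10, n, seed = 2)
  expect_equal(mean(s10), 0.1, tolerance = 3 / sqrt(n) / 0.1 * 0.1 + 3e-4)
  s20 <- sample_step(20, n, seed = 2)
  expect_equal(mean(s20), mean(s10) / 2, tolerance = 1e-3)
  ks <- suppressWarnings(stats::ks.test(s10, stats::pexp, rate = 10))
  expect_lt(unname(ks$statistic), 0.002)
  expect_error(sample_step(0), "mu_t")
})

test_that("Henyey-Greenstein sampling matches the analytic moments", {
  n <- 1e6
  for (g in c(0, 0.85, 0.875, 0.9)) {
    ct <- sample_hg(g, n, seed = 5)
    expect_equal(mean(ct), g, tolerance = 3 * stats::sd(ct) / sqrt(n) + 1e-4)
  }
  # second moment against numeric integration of the HG density
  g <- 0.875
  dens <- function(x) 0.5 * (1 - g^2) / (1 + g^2 - 2 * g * x)^1.5
  m2 <- stats::integrate(function(x) x^2 * dens(x), -1, 1,
                         rel.tol = 1e-10)$value
  ct <- sample_hg(g, n, seed = 9)
  expect_equal(mean(ct^2), m2, tolerance = 5e-4)
  expect_error(sample_hg(1), "inside")
})

test_that("collimated transmission through a pure absorber is Beer-Lambert", {
  dims <- c(20L, 20L, 40L); sp <- c(0.05, 0.05, 0.05)
  opt <- homog_optics(dims, sp, mua = 2, mus = 0, g = 0)
  src <- source_spec("pencil", position_cm = c(0.5, 0.5, 0.025),
                     direction = c(0, 0, 1))
  n <- 5e4
  fl <- transport(opt, src, n_packets = n, seed = 11)
  L <- 40 * 0.05 - 0.025
  p <- exp(-2 * L)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(fl$escaped - p), 3 * se)
})

test_that("launched weight is conserved by the estimator ledger", {
  opt <- homog_optics(c(16L, 16L, 16L), rep(0.1, 3), mua = 0.5, mus = 100,
                      g = 0.85, n = 1.38)
  fl <- transport(opt, n_packets = 5e3, seed = 4)
  # roulette survival boosts make the realized ledger stochastic; it closes
  # in expectation, with discrepancy well under the 1e-3 roulette budget
  expect_equal(fl$escaped + fl$absorbed + fl$roulette_killed, 1,
               tolerance = 1e-3)
  expect_lt(fl$roulette_killed, 1e-3)
  # with roulette disabled (threshold 0 never triggers) the ledger is exact
  fl2 <- transport(opt, n_packets = 1e3, seed = 4, roulette_wmin = 0)
  expect_equal(fl2$escaped + fl2$absorbed, 1, tolerance = 1e-9)
})

test_that("a point source in vacuum gives inverse-square fluence", {
  dims <- rep(33L, 3); sp <- rep(0.1, 3)
  opt <- homog_optics(dims, sp, mua = 0, mus = 0, g = 0)
  fl <- transport(opt, n_packets = 4e4, seed = 8)
  ctr <- dims * sp / 2
  xs <- (seq_len(dims[1]) - 0.5) * sp[1]
  r2 <- outer(outer((xs - ctr[1])^2, (xs - ctr[2])^2, "+"),
              (xs - ctr[3])^2, "+")
  r <- sqrt(r2)
  for (r0 in c(0.5, 0.8, 1.1)) {
    sel <- abs(r - r0) < 0.05
    got <- mean(fl$psi[sel])
    expected <- 1000 / (4 * pi * r0^2)  # mW/cm^2 per W
    expect_equal(got, expected, tolerance = 0.05 * expected, ignore_attr = TRUE)
  }
})

test_that("fluence decays monotonically with depth in homogeneous tissue", {
  dims <- rep(25L, 3); sp <- rep(0.04, 3)
  opt <- homog_optics(dims, sp, mua = 1, mus = 100, g = 0.85, n = 1.38)
  fl <- transport(opt, n_packets = 2e4, seed = 6)
  ctr <- dims * sp / 2
  xs <- (seq_len(dims[1]) - 0.5) * sp[1]
  r <- sqrt(outer(outer((xs - ctr[1])^2, (xs - ctr[2])^2, "+"),
                  (xs - ctr[3])^2, "+"))
  edges <- seq(0.06, 0.42, by = 0.06)
  shell_mean <- vapply(seq_len(length(edges) - 1), function(i)
    mean(fl$psi[r >= edges[i] & r < edges[i + 1]]), numeric(1))
  expect_true(all(diff(shell_mean) < 0))
})

test_that("voxel-wise statistical error shrinks as 1/sqrt(n_packets)", {
  opt <- homog_optics(rep(15L, 3), rep(0.1, 3), mua = 1, mus = 50, g = 0.8)
  run_sd <- function(n) {
    runs <- vapply(1:6, function(s)
      transport(opt, n_packets = n, seed = 100 + s)$psi[8, 8, 11],
      numeric(1))
    stats::sd(runs)
  }
  sds <- vapply(c(1000, 4000, 16000), run_sd, numeric(1))
  # each 4x packet increase should roughly halve the error
  expect_equal(sds[1] / sds[2], 2, tolerance = 1.2)
  expect_equal(sds[2] / sds[3], 2, tolerance = 1.2)
  expect_true(all(diff(sds) < 0))
})

test_that("transport is reproducible per seed and validates inputs", {
  opt <- homog_optics(rep(10L, 3), rep(0.1, 3), mua = 1, mus = 20, g = 0.8)
  a <- transport(opt, n_packets = 2000, seed = 5)
  b <- transport(opt, n_packets = 2000, seed = 5)
  expect_identical(a$psi, b$psi)
  c2 <- transport(opt, n_packets = 2000, seed = 6)
  expect_false(identical(a$psi, c2$psi))
  expect_error(transport(opt, n_packets = 0), "positive")
  expect_error(
    transport(opt, source = source_spec("isotropic", c(-1, 0.5, 0.5))),
    "inside")
})

test_that("cumulative dose integrates the schedule linearly", {
  opt <- homog_optics(rep(8L, 3), rep(0.1, 3), mua = 1, mus = 20, g = 0.8)
  fl <- transport(opt, n_packets = 2000, seed = 5)
  std <- build_schedule(protocol_spec())       # 8.6 min on in 5 fractions
  solid <- build_schedule(protocol_spec(fractionated = FALSE))  # 8.6 min on
  d1 <- fluence_to_dose(fl, 2, std)
  expect_equal(fluence_to_dose(fl, 4, std), 2 * d1, tolerance = 1e-12)
  # same on-time, with or without breaks: identical cumulative fluence
  expect_equal(fluence_to_dose(fl, 2, solid), d1, tolerance = 1e-12)
  none <- tibble::tibble(light_on = FALSE, duration_s = 600)
  expect_true(all(fluence_to_dose(fl, 2, none) == 0))
  expect_error(fluence_to_dose(fl, -1, std), ">= 0")
})
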