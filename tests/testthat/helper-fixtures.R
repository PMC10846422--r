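# shared, lazily built fixtures (one R session per test run, so heavy
# objects are computed once and reused across files)
.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# the standard desk-scale scene (48^3, 0.5 mm voxels)
demo_scene <- function() memo_fixture("scene", demo_phantom(seed = 1L))

# one per-watt fluence map shared by every protocol test
demo_fluence <- function() memo_fixture("fluence", {
  ph <- demo_scene()
  transport(mix_optics(ph, ppix0_uM = 0),
            source = source_spec("isotropic", ph$meta$balloon_center_cm),
            n_packets = 2e4, seed = 42)
})

# small homogeneous optics block for transport validations
homog_optics <- function(dims, spacing, mua, mus, g, n = 1.0) {
  mk <- function(v) array(v, dim = dims)
  structure(list(mua = mk(mua), mus = mk(mus), g = mk(g), n = mk(n),
                 spacing = spacing), class = "scene_optics")
}

# independent reference trajectory for the PDT rate equations (adaptive
# stiff integrator, written against the model equations directly)
oracle_kinetics <- function(psi, s0, times, params = kinetics_params(),
                            fixed_oxygen = FALSE) {
  rhs <- function(t, y, p) {
    common <- p$xi * psi * y[1] * y[2] / (y[2] + p$beta)
    phi <- perfusion_phi(t, p$phi0)
    list(c(-p$sigma * (y[1] + p$rho_lc) * common,
           if (fixed_oxygen) 0 else -common + phi * (1 - y[2] / p$o2_init),
           common))
  }
  out <- deSolve::lsoda(c(s0, params$o2_init, 0), times, rhs, params,
                        rtol = 1e-9, atol = 1e-10)
  colnames(out) <- c("time", "s0", "o2", "o2rx")
  out
}

# run the package integrator for a single voxel under constant fluence
single_voxel_run <- function(psi, s0, seconds, params = kinetics_params(),
                             fixed_oxygen = FALSE, n_sub = 10L) {
  fl <- structure(list(psi = array(psi, dim = c(1, 1, 1))),
                  class = "fluence_grid")
  st <- structure(list(idx = 1L, dims = c(1L, 1L, 1L), fgbm = 1,
                       fgbm_total = 1, s0 = s0,
                       o2 = params$o2_init, o2rx = 0, killed = FALSE,
                       t = 0), class = "kinetics_state")
  sched <- tibble::tibble(light_on = TRUE, duration_s = seconds)
  kinetics_run(st, fl, sched, power_W = 1, params = params,
               fixed_oxygen = fixed_oxygen, n_sub = n_sub)
}
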