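#' Volumetric heat source from the light field
#'
#' `qdot = mua * Psi * power`, converted to W/m^3 (mua in cm^-1, Psi in
#' mW/cm^2 per W): the absorbed optical power density. Zero when the light
#' is off.
#'
#' @param optics a `scene_optics` (same grid as `fluence`)
#' @param fluence a `fluence_grid`
#' @param power_W source power, W
#' @param light_on logical
#' @return 3-D array, W/m^3
#' @export
heat_source <- function(optics, fluence, power_W, light_on = TRUE) {
  if (!identical(dim(optics$mua), dim(fluence$psi)))
    stop("optics and fluence grids do not match")
  if (power_W < 0) stop("power must be >= 0")
  if (!light_on) return(array(0, dim = dim(optics$mua)))
  optics$mua * fluence$psi * power_W * 1000
}

#' Temperature sub-grid for the heat solver
#'
#' Builds a cubic-voxel temperature grid covering a cube of side `size_cm`
#' centered at `center_cm` (default: the tumor-sphere corner of the cavity,
#' where heating is strongest), resampling material fractions and the
#' fluence map from the scene by nearest neighbor. Initial temperature is
#' 37 C in brain-majority voxels and 22 C (room temperature) elsewhere.
#' Boundary voxels facing brain get a 37 C floor clamp (metabolic
#' regulation); other boundary voxels are fixed at 22 C.
#'
#' @param grid a [tissue_grid]
#' @param fluence a `fluence_grid` on the same scene
#' @param optics a `scene_optics` on the same scene
#' @param power_W source power, W
#' @param center_cm cube center, cm; `NULL` picks the sphere corner from the
#'   scene metadata (or the grid center if absent)
#' @param size_cm cube side, cm
#' @param n voxels per axis of the sub-grid
#' @param materials material table supplying `rho`, `cp`, `kappa`
#' @param t_brain,t_room initial/boundary temperatures, C
#' @return a `temperature_grid`
#' @export
thermal_subgrid <- function(grid, fluence, optics, power_W = 2,
                            center_cm = NULL, size_cm = 1.6, n = 32L,
                            materials = material_table(),
                            t_brain = 37, t_room = 22) {
  stopifnot(inherits(grid, "tissue_grid"))
  if (!identical(dim(optics$mua), grid_shape(grid)) ||
      !identical(dim(fluence$psi), grid_shape(grid)))
    stop("optics/fluence must live on the scene grid")
  d <- grid_shape(grid)
  ext <- d * grid$spacing
  if (is.null(center_cm)) {
    center_cm <- if (!is.null(grid$meta$sphere_center_cm))
      as.numeric(grid$meta$sphere_center_cm) else ext / 2
  }
  n <- as.integer(n)
  dxs <- size_cm / n
  lo <- center_cm - size_cm / 2
  # keep the cube inside the scene
  lo <- pmin(pmax(lo, 0), ext - size_cm)
  if (any(lo < 0)) stop("thermal sub-grid larger than the scene")
  centers <- lapply(1:3, function(a) lo[a] + (seq_len(n) - 0.5) * dxs)
  src_idx <- lapply(1:3, function(a)
    pmin(pmax(ceiling(centers[[a]] / grid$spacing[a]), 1L), d[a]))
  ii <- src_idx[[1]]; jj <- src_idx[[2]]; kk <- src_idx[[3]]
  pick <- function(arr3) arr3[ii, jj, kk, drop = FALSE]

  qdot <- pick(heat_source(optics, fluence, power_W, light_on = TRUE))
  brain_frac <- pick(grid$fractions[, , , "white"] +
                     grid$fractions[, , , "gray"] +
                     grid$fractions[, , , "gbm"])
  mix_thermal <- function(prop) {
    out <- array(0, dim = rep(n, 3))
    for (m in pdt_materials()) {
      v <- materials[[prop]][match(m, materials$material)]
      out <- out + v * pick(grid$fractions[, , , m])
    }
    out
  }
  rho <- mix_thermal("rho"); cp <- mix_thermal("cp"); kap <- mix_thermal("kappa")

  is_brain <- brain_frac >= 0.5
  T0 <- array(t_room, dim = rep(n, 3))
  T0[is_brain] <- t_brain

  bc <- array(0L, dim = rep(n, 3))
  edge <- array(FALSE, dim = rep(n, 3))
  edge[c(1, n), , ] <- TRUE; edge[, c(1, n), ] <- TRUE; edge[, , c(1, n)] <- TRUE
  bc[edge & is_brain] <- 1L
  bc[edge & !is_brain] <- 2L

  new_temperature_grid(T0, rho, cp, kap, qdot, bc, dx_m = dxs / 100,
                       t_brain = t_brain, t_room = t_room)
}

#' Construct a temperature grid directly
#'
#' Low-level constructor used by [thermal_subgrid()] and the analytic
#' validation tests. Boundary-condition codes: 0 none (insulated edge face),
#' 1 floor clamp at `t_brain`, 2 fixed Dirichlet at `t_room`.
#'
#' @param T0,rho,cp,kappa,qdot 3-D arrays (temperature C; SI material
#'   properties; source W/m^3)
#' @param bc integer 3-D array of boundary-condition codes
#' @param dx_m cubic voxel edge, m
#' @param t_brain,t_room clamp / Dirichlet temperatures, C
#' @return a `temperature_grid`
#' @export
new_temperature_grid <- function(T0, rho, cp, kappa, qdot = NULL, bc = NULL,
                                 dx_m, t_brain = 37, t_room = 22) {
  d <- dim(T0)
  if (is.null(qdot)) qdot <- array(0, dim = d)
  if (is.null(bc)) bc <- array(0L, dim = d)
  stopifnot(identical(dim(rho), d), identical(dim(cp), d),
            identical(dim(kappa), d), identical(dim(qdot), d),
            identical(dim(bc), d), dx_m > 0)
  structure(list(T = T0, rho = rho, cp = cp, kappa = kappa, qdot = qdot,
                 bc = bc, dx_m = dx_m, t_brain = t_brain, t_room = t_room,
                 t = 0,
                 max_trace = tibble::tibble(t = numeric(), max_T = numeric(),
                                            light_on = logical()),
                 damage = FALSE),
            class = "temperature_grid")
}

#' @export
print.temperature_grid <- function(x, ...) {
  cat("<temperature_grid> ", paste(dim(x$T), collapse = " x "),
      " voxels, dx ", signif(x$dx_m * 1000, 3), " mm, t = ", x$t, " s\n",
      "  T range [", signif(min(x$T), 4), ", ", signif(max(x$T), 4),
      "] C", if (x$damage) "  [damage threshold reached]", "\n", sep = "")
  invisible(x)
}

# shared driver for equilibrate/evolve
run_thermal <- function(tg, schedule, safety = 0.9, damage_T = 48) {
  schedule <- quantize_schedule(schedule)
  sched <- as.matrix(schedule[, c("light_on", "duration_s")])
  storage.mode(sched) <- "double"
  res <- thermal_run_cpp(as.numeric(tg$T), as.integer(dim(tg$T)), tg$dx_m,
                         as.numeric(tg$rho), as.numeric(tg$cp),
                         as.numeric(tg$kappa), as.numeric(tg$qdot), sched,
                         as.integer(tg$bc), tg$t_brain, tg$t_room, safety)
  tg$T <- array(res$T, dim = dim(tg$T))
  trace <- tibble::tibble(t = tg$t + res$t, max_T = res$max_trace,
                          light_on = res$light_on > 0)
  tg$t <- tg$t + sum(schedule$duration_s)
  tg$max_trace <- dplyr::bind_rows(tg$max_trace, trace)
  tg$damage <- tg$damage || any(trace$max_T >= damage_T)
  tg$dt_stability <- res$dt_stability
  tg
}

#' Equilibrate the temperature field with the light off
#'
#' Evolves the grid for `duration_s` seconds with no source so the initial
#' 37 C / 22 C contrast relaxes; the standard protocol runs 5 minutes of
#' equilibration before the first light-on.
#'
#' @param tg a `temperature_grid`
#' @param duration_s equilibration time, s
#' @param safety fraction of the explicit stability limit used for the step
#' @return updated `temperature_grid`
#' @export
equilibrate <- function(tg, duration_s = 300, safety = 0.9) {
  stopifnot(inherits(tg, "temperature_grid"), duration_s >= 0)
  if (duration_s == 0) return(tg)
  run_thermal(tg, tibble::tibble(light_on = FALSE, duration_s = duration_s),
              safety = safety)
}

#' Evolve the temperature field over an illumination schedule
#'
#' Forward-Euler conduction with harmonic-mean face conductivities; the
#' source term is active during light-on intervals only. The per-second grid
#' maximum is appended to `max_trace` and the damage flag raised if it
#' reaches `damage_T` (48 C).
#'
#' @param tg a `temperature_grid` (typically after [equilibrate()])
#' @param schedule tibble from [build_schedule()]
#' @param safety fraction of the explicit stability limit
#' @param damage_T damage threshold, C
#' @return updated `temperature_grid`
#' @export
thermal_evolve <- function(tg, schedule, safety = 0.9, damage_T = 48) {
  stopifnot(inherits(tg, "temperature_grid"))
  run_thermal(tg, schedule, safety = safety, damage_T = damage_T)
}

#' Write the temperature field as NIfTI
#' @param tg a `temperature_grid`
#' @param path basename; writes `<path>.nii.gz`
#' @export
write_temperature <- function(tg, path) {
  img <- RNifti::asNifti(tg$T, pixdim = rep(tg$dx_m * 100, 3))
  RNifti::writeNifti(img, paste0(path, ".nii.gz"))
  invisible(path)
}
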