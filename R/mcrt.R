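#' Sample exponential free paths
#'
#' Path lengths between interactions for total attenuation `mu_t` (cm^-1),
#' drawn from the same generator the transport kernel uses; mean `1/mu_t`.
#'
#' @param mu_t total attenuation coefficient, cm^-1 (must be > 0)
#' @param n number of draws
#' @param seed integer seed
#' @return numeric vector of path lengths, cm
#' @export
sample_step <- function(mu_t, n = 1L, seed = 1L) {
  if (mu_t <= 0) stop("mu_t must be > 0 (mu_t <= 0 free-streams in transport)")
  sample_step_cpp(mu_t, n, seed)
}

#' Sample Henyey-Greenstein deflection cosines
#'
#' Scattering-angle cosines for anisotropy `g`; `g = 0` is isotropic and the
#' sample mean converges to `g`.
#'
#' @param g anisotropy factor, in (-1, 1)
#' @param n number of draws
#' @param seed integer seed
#' @return numeric vector of cosines in `[-1, 1]`
#' @export
sample_hg <- function(g, n = 1L, seed = 1L) {
  if (abs(g) >= 1) stop("g must lie strictly inside (-1, 1)")
  sample_hg_cpp(g, n, seed)
}

#' Light source specification
#'
#' @param type `"isotropic"` point emitter (the bare fiber inside the
#'   diffusing balloon) or `"pencil"` collimated beam (validation runs)
#' @param position_cm source position, cm; default the balloon centroid
#'   stored in the scene optics' grid metadata must be supplied explicitly
#' @param direction unit direction for pencil beams
#' @return a `source_spec` list
#' @export
source_spec <- function(type = c("isotropic", "pencil"),
                        position_cm, direction = c(0, 0, 1)) {
  type <- match.arg(type)
  stopifnot(length(position_cm) == 3)
  direction <- direction / sqrt(sum(direction^2))
  structure(list(type = type, position_cm = as.numeric(position_cm),
                 direction = direction), class = "source_spec")
}

#' Monte Carlo fluence-rate map
#'
#' Transports `n_packets` photon packets through the scene and returns the
#' per-voxel fluence rate in mW/cm^2 per watt of launched source power
#' (track-length estimator). Absorption uses implicit capture with
#' Russian-roulette termination; refractive-index mismatches at voxel faces
#' apply unpolarized Fresnel reflection/refraction unless `fresnel = FALSE`;
#' grid edges absorb (escaping weight is tallied). Voxels with zero total
#' attenuation free-stream. Reproducible per `seed` and independent of
#' packet order (one counter-seeded stream per packet).
#'
#' @param optics a `scene_optics` from [mix_optics()] (or a compatible list
#'   of `mua`, `mus`, `g`, `n` arrays plus `spacing`)
#' @param source a [source_spec()]; default an isotropic point at the grid
#'   center
#' @param n_packets number of photon packets (> 0)
#' @param seed integer seed
#' @param fresnel apply Fresnel reflection/refraction at index mismatches
#' @param roulette_wmin weight below which Russian roulette triggers
#' @param roulette_surv roulette survival probability
#' @return a `fluence_grid`: `psi` (3-D array, mW/cm^2 per W), the energy
#'   ledger (`escaped`, `absorbed`, `roulette_killed` weight fractions),
#'   `n_packets`, `seed`, `spacing`, `source`
#' @export
transport <- function(optics, source = NULL, n_packets = 1e5, seed = 1L,
                      fresnel = TRUE, roulette_wmin = 1e-4,
                      roulette_surv = 0.1) {
  if (n_packets <= 0) stop("n_packets must be positive")
  d <- dim(optics$mua)
  spacing <- optics$spacing
  if (is.null(source))
    source <- source_spec("isotropic", position_cm = d * spacing / 2)
  pos <- source$position_cm
  if (any(pos <= 0) || any(pos >= d * spacing))
    stop("source must lie inside the grid")
  res <- mcrt_transport_cpp(as.numeric(optics$mua), as.numeric(optics$mus),
                            as.numeric(optics$g), as.numeric(optics$n),
                            as.integer(d), as.numeric(spacing),
                            pos, source$direction,
                            if (source$type == "isotropic") 0L else 1L,
                            n_packets, seed, fresnel,
                            roulette_wmin, roulette_surv)
  vvol <- prod(spacing)
  psi <- array(res$psi_raw / (vvol * res$n_packets) * 1000, dim = d)
  structure(list(psi = psi,
                 escaped = res$escaped / res$n_packets,
                 absorbed = res$absorbed / res$n_packets,
                 roulette_killed = res$roulette_killed / res$n_packets,
                 n_packets = res$n_packets, seed = seed,
                 spacing = spacing, source = source),
            class = "fluence_grid")
}

#' @export
print.fluence_grid <- function(x, ...) {
  cat("<fluence_grid> ", paste(dim(x$psi), collapse = " x "),
      " voxels, ", format(x$n_packets, big.mark = ","), " packets (seed ",
      x$seed, ")\n", sep = "")
  cat(sprintf("  energy ledger: absorbed %.4f, escaped %.4f, roulette %.4f\n",
              x$absorbed, x$escaped, x$roulette_killed))
  invisible(x)
}

#' Cumulative fluence delivered by a schedule
#'
#' Time-integrates the fluence-rate map over the light-on intervals of an
#' illumination schedule: `J/cm^2 = psi (mW/cm^2 per W) * power (W) *
#' on-time (s) / 1000`. Dark intervals contribute nothing.
#'
#' @param fluence a `fluence_grid` from [transport()]
#' @param power_W source power, W (>= 0)
#' @param schedule tibble with columns `light_on`, `duration_s` (from
#'   [build_schedule()])
#' @return 3-D array of cumulative fluence, J/cm^2
#' @export
fluence_to_dose <- function(fluence, power_W, schedule) {
  if (power_W < 0) stop("power must be >= 0")
  on_s <- sum(schedule$duration_s[schedule$light_on])
  fluence$psi * power_W * on_s / 1000
}

#' Write / read a fluence grid as NIfTI + JSON metadata
#' @param fluence a `fluence_grid`
#' @param path basename; writes `<path>.nii.gz` and `<path>.json`
#' @return `path` invisibly (write); a `fluence_grid` (read)
#' @export
write_fluence <- function(fluence, path) {
  img <- RNifti::asNifti(fluence$psi, pixdim = fluence$spacing)
  RNifti::writeNifti(img, paste0(path, ".nii.gz"))
  meta <- list(format = "pdtsim-fluence", version = 1L,
               units = "mW/cm^2 per W",
               n_packets = fluence$n_packets, seed = fluence$seed,
               spacing_cm = fluence$spacing,
               escaped = fluence$escaped, absorbed = fluence$absorbed,
               roulette_killed = fluence$roulette_killed,
               source = unclass(fluence$source))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fluence
#' @export
read_fluence <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "pdtsim-fluence"))
    stop("not a pdtsim fluence file: ", path)
  psi <- strip_nifti(RNifti::readNifti(paste0(path, ".nii.gz")))
  src <- source_spec(meta$source$type, meta$source$position_cm,
                     meta$source$direction)
  structure(list(psi = psi, escaped = meta$escaped, absorbed = meta$absorbed,
                 roulette_killed = meta$roulette_killed,
                 n_packets = meta$n_packets, seed = meta$seed,
                 spacing = as.numeric(meta$spacing_cm), source = src),
            class = "fluence_grid")
}
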