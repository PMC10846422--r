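#' Treatment time from the injected intralipid volume
#'
#' The trial's dosimetry algorithm: the irradiation time (minutes) for a 2 W
#' source to deliver the design fluence of 200 J/cm^2 at the balloon wall is
#' `t = 0.1176 V + 3.4276` for an intralipid fill of `V` ml, reported to
#' 0.1 min. A 44 ml fill gives 8.6 min.
#'
#' @param v_ml injected intralipid volume, ml (>= 0)
#' @return treatment time, minutes (rounded to 0.1)
#' @export
#' @examples
#' treatment_time_from_volume(44)  # 8.6
treatment_time_from_volume <- function(v_ml) {
  if (any(v_ml < 0)) stop("intralipid volume must be >= 0")
  round(0.1176 * v_ml + 3.4276, 1)
}

#' Illumination protocol specification
#'
#' Captures a trial-style protocol: source power, total irradiation time
#' (given directly or derived from the intralipid fill volume), fraction
#' count and break length, initial PpIX concentration, and the variant flags
#' used in the parameter studies. The standard protocol is 2 W, 8.6 min of
#' light split into 5 equal fractions with 2 min breaks (16.6 min total),
#' 5 uM PpIX, threshold scale 1.
#'
#' @param power_W source power, W
#' @param irradiation_min total light-on time, minutes; default derived from
#'   `intralipid_ml` via [treatment_time_from_volume()]
#' @param intralipid_ml balloon fill volume, ml
#' @param n_fractions number of equal light-on fractions (>= 1)
#' @param break_min break between fractions, minutes
#' @param ppix0_uM initial PpIX concentration for pure GBM, uM
#' @param fixed_oxygen neglect oxygen depletion (hold oxygen at its initial
#'   value)
#' @param fractionated `FALSE` collapses the schedule to a single light-on
#'   interval of `irradiation_min`
#' @param threshold_scale multiplier on the 560 uM kill threshold
#' @return a `protocol_spec`
#' @export
#' @examples
#' protocol_spec()  # the standard protocol
protocol_spec <- function(power_W = 2, irradiation_min = NULL,
                          intralipid_ml = 44, n_fractions = 5L,
                          break_min = 2, ppix0_uM = 5,
                          fixed_oxygen = FALSE, fractionated = TRUE,
                          threshold_scale = 1) {
  if (power_W < 0) stop("power must be >= 0")
  if (is.null(irradiation_min))
    irradiation_min <- treatment_time_from_volume(intralipid_ml)
  if (irradiation_min < 0 || break_min < 0) stop("durations must be >= 0")
  if (n_fractions < 1) stop("n_fractions must be >= 1")
  if (ppix0_uM < 0) stop("PpIX concentration must be >= 0")
  if (threshold_scale <= 0) stop("threshold_scale must be > 0")
  structure(list(power_W = power_W, irradiation_min = irradiation_min,
                 intralipid_ml = intralipid_ml,
                 n_fractions = as.integer(n_fractions),
                 break_min = break_min, ppix0_uM = ppix0_uM,
                 fixed_oxygen = isTRUE(fixed_oxygen),
                 fractionated = isTRUE(fractionated),
                 threshold_scale = threshold_scale),
            class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  sched <- build_schedule(x)
  cat(sprintf(
    "<protocol_spec> %g W, %g min light%s, %g uM PpIX, total %g min\n",
    x$power_W, x$irradiation_min,
    if (x$fractionated && x$n_fractions > 1)
      sprintf(" in %d fractions (%g min breaks)", x$n_fractions, x$break_min)
    else " unfractionated",
    x$ppix0_uM, sum(sched$duration_s) / 60))
  invisible(x)
}

#' Build the illumination schedule
#'
#' Splits the irradiation time into `n_fractions` equal light-on intervals
#' separated by `n_fractions - 1` dark breaks (or a single on-interval when
#' unfractionated). The standard protocol gives 5 x 103.2 s on + 4 x 120 s
#' off = 996 s (16.6 min).
#'
#' @param spec a [protocol_spec()]
#' @return tibble with columns `light_on` (logical), `duration_s`
#' @export
build_schedule <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  total_on <- spec$irradiation_min * 60
  if (!spec$fractionated || spec$n_fractions == 1L)
    return(tibble::tibble(light_on = TRUE, duration_s = total_on))
  on_s <- total_on / spec$n_fractions
  off_s <- spec$break_min * 60
  n <- spec$n_fractions
  tibble::tibble(
    light_on = rep(c(TRUE, FALSE), n)[1:(2 * n - 1)],
    duration_s = rep(c(on_s, off_s), n)[1:(2 * n - 1)])
}

#' Quantize a schedule to whole seconds
#'
#' The kinetics and thermal loops advance one second at a time; fractional
#' segment durations (e.g. 103.2 s fractions) are converted to integer
#' seconds by rounding the cumulative schedule, so the total duration and
#' total on-time are preserved to the second.
#'
#' @param schedule tibble from [build_schedule()]
#' @return schedule with integer `duration_s`
#' @export
quantize_schedule <- function(schedule) {
  cum <- round(cumsum(schedule$duration_s))
  out <- schedule
  out$duration_s <- diff(c(0, cum))
  out[out$duration_s > 0, , drop = FALSE]
}

#' Monte Carlo settings for a treatment run
#' @param n_packets photon packets for the fluence map
#' @param seed integer seed
#' @param fresnel Fresnel handling at index mismatches
#' @return a list
#' @export
mc_settings <- function(n_packets = 2e4, seed = 1L, fresnel = TRUE) {
  list(n_packets = n_packets, seed = as.integer(seed), fresnel = fresnel)
}

# depth (mm beyond the cavity wall) of the deepest killed voxel along a ray
# from the balloon center through direction u
kill_depth_along <- function(grid, killed_full, direction) {
  d <- grid_shape(grid)
  sp <- grid$spacing
  center <- grid$meta$balloon_center_cm
  semi_c <- grid$meta$cavity_semi_cm
  if (is.null(center) || is.null(semi_c)) return(NA_real_)
  u <- direction / sqrt(sum(direction^2))
  t_wall <- sqrt(1 / sum((u / semi_c)^2))
  ts <- seq(0, 0.8, by = min(sp) / 2)  # cm beyond the wall
  depth <- NA_real_
  for (s in ts) {
    p <- center + (t_wall + s) * u
    ijk <- ceiling(p / sp)
    if (any(ijk < 1) || any(ijk > d)) break
    if (killed_full[ijk[1], ijk[2], ijk[3]]) depth <- s * 10
  }
  depth
}

#' Run a full treatment
#'
#' Orchestrates the pipeline: computes (or reuses) the per-watt fluence map,
#' integrates the PDT kinetics second-by-second across the schedule, applies
#' the kill threshold, and (optionally) evolves the temperature sub-grid
#' with 5 min of dark equilibration before first light-on. Fully
#' reproducible from (scene, spec, settings, seed).
#'
#' @param grid a [tissue_grid]
#' @param spec a [protocol_spec()]
#' @param mc [mc_settings()]
#' @param params [kinetics_params()]
#' @param fluence optional precomputed `fluence_grid` (per watt) to reuse;
#'   protocols differing only in PpIX concentration share one map
#' @param thermal run the heat solver (logical), or a list of arguments for
#'   [thermal_subgrid()]
#' @param equilibrate_s dark equilibration before the protocol, s
#' @param probe_dirs named list of unit directions for kill-depth probes
#' @param materials material table
#' @return a `treatment_result`: `series` (per-second tibble), `summary`
#'   row, `kill_depth` tibble, `max_trace` (if thermal), final `state`,
#'   `fluence`, provenance (`seed`, `config_hash`)
#' @export
run_treatment <- function(grid, spec, mc = mc_settings(),
                          params = kinetics_params(), fluence = NULL,
                          thermal = FALSE, equilibrate_s = 300,
                          probe_dirs = list(x = c(1, 0, 0), y = c(0, 1, 0),
                                            z = c(0, 0, 1)),
                          materials = material_table()) {
  stopifnot(inherits(grid, "tissue_grid"), inherits(spec, "protocol_spec"))
  optics <- mix_optics(grid, materials, ppix0_uM = spec$ppix0_uM)
  if (is.null(fluence)) {
    src <- source_spec("isotropic", position_cm = grid$meta$balloon_center_cm %||%
                         (grid_shape(grid) * grid$spacing / 2))
    # fluence is computed per watt from PpIX-free optics, so one map serves
    # every concentration and power (absorption by PpIX is negligible there)
    optics0 <- mix_optics(grid, materials, ppix0_uM = 0)
    fluence <- transport(optics0, source = src, n_packets = mc$n_packets,
                         seed = mc$seed, fresnel = mc$fresnel)
  }
  schedule <- build_schedule(spec)
  st <- kinetics_state(grid, ppix0_uM = spec$ppix0_uM, params = params)
  st <- kinetics_run(st, fluence, schedule, power_W = spec$power_W,
                     params = params, fixed_oxygen = spec$fixed_oxygen,
                     threshold_scale = spec$threshold_scale)
  thr <- apply_threshold(st, params$threshold * spec$threshold_scale)

  killed_full <- array(FALSE, dim = grid_shape(grid))
  killed_full[st$idx] <- thr$killed
  kd <- tibble::tibble(
    probe = names(probe_dirs),
    kill_depth_mm = vapply(probe_dirs, function(u)
      kill_depth_along(grid, killed_full, u), numeric(1)))

  tg <- NULL
  if (!isFALSE(thermal)) {
    targs <- if (isTRUE(thermal)) list() else thermal
    tg <- do.call(thermal_subgrid,
                  c(list(grid = grid, fluence = fluence, optics = optics,
                         power_W = spec$power_W, materials = materials),
                    targs))
    tg <- equilibrate(tg, duration_s = equilibrate_s)
    tg <- thermal_evolve(tg, schedule)
  }

  cfg <- list(spec = unclass(spec), params = unclass(params),
              mc = mc, shape = grid_shape(grid), spacing = grid$spacing)
  structure(list(series = st$series, kill_depth = kd,
                 state = st, killed = killed_full, fluence = fluence,
                 temperature = tg,
                 max_trace = if (!is.null(tg)) tg$max_trace else NULL,
                 summary = tibble::tibble(
                   pct_gbm_remaining = min(max(thr$pct_gbm_remaining, 0), 100),
                   pct_gbm_killed = min(max(100 - thr$pct_gbm_remaining, 0), 100),
                   max_T = if (!is.null(tg)) max(tg$max_trace$max_T) else NA_real_,
                   damage = if (!is.null(tg)) tg$damage else NA,
                   total_time_min = sum(schedule$duration_s) / 60,
                   energy_J = spec$power_W *
                     sum(schedule$duration_s[schedule$light_on])),
                 spec = spec, seed = mc$seed,
                 config_hash = rlang::hash(cfg)),
            class = "treatment_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.treatment_result <- function(x, ...) {
  s <- x$summary
  cat("<treatment_result>\n")
  cat(sprintf("  GBM remaining: %.1f%% (killed %.1f%%) after %.1f min\n",
              s$pct_gbm_remaining, s$pct_gbm_killed, s$total_time_min))
  if (!is.na(s$max_T))
    cat(sprintf("  max temperature: %.1f C%s\n", s$max_T,
                if (isTRUE(s$damage)) " [>= 48 C damage threshold]" else ""))
  kd <- x$kill_depth
  ok <- !is.na(kd$kill_depth_mm)
  if (any(ok))
    cat("  kill depth (mm): ",
        paste(sprintf("%s %.2f", kd$probe[ok], kd$kill_depth_mm[ok]),
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy the per-second time series of a treatment
#' @param x a `treatment_result`
#' @param ... unused
#' @return tibble of per-second state summaries
#' @export
as_tibble.treatment_result <- function(x, ...) x$series

#' Run a one-axis protocol sweep
#'
#' Repeats [run_treatment()] along one protocol axis, reusing a single
#' per-watt fluence map across all runs (the fluence field does not depend
#' on PpIX concentration and scales linearly with power). Returns one row
#' per value with the end-of-treatment outcome.
#'
#' @param grid a [tissue_grid]
#' @param base_spec the reference [protocol_spec()]
#' @param axis one of `"ppix0"`, `"power"`, `"time"`, `"threshold_scale"`,
#'   `"fixed_oxygen"`, `"fractionated"`
#' @param values vector of axis values
#' @param mc,params,thermal,... forwarded to [run_treatment()]
#' @param keep_results attach the full `treatment_result`s as a list column
#' @return tibble: `axis`, `value`, `pct_gbm_remaining`, `pct_gbm_killed`,
#'   `max_T`, `fluence_hash`
#' @export
run_sweep <- function(grid, base_spec, axis, values, mc = mc_settings(),
                      params = kinetics_params(), thermal = FALSE,
                      keep_results = FALSE, ...) {
  field <- switch(axis, ppix0 = "ppix0_uM", power = "power_W",
                  time = "irradiation_min", threshold_scale = "threshold_scale",
                  fixed_oxygen = "fixed_oxygen", fractionated = "fractionated",
                  stop("unknown sweep axis: ", axis))
  optics0 <- mix_optics(grid, ppix0_uM = 0)
  src <- source_spec("isotropic",
                     position_cm = grid$meta$balloon_center_cm %||%
                       (grid_shape(grid) * grid$spacing / 2))
  fl <- transport(optics0, source = src, n_packets = mc$n_packets,
                  seed = mc$seed, fresnel = mc$fresnel)
  rows <- lapply(values, function(v) {
    spec <- base_spec
    spec[[field]] <- v
    res <- run_treatment(grid, spec, mc = mc, params = params, fluence = fl,
                         thermal = thermal, ...)
    tibble::tibble(axis = axis, value = v,
                   pct_gbm_remaining = res$summary$pct_gbm_remaining,
                   pct_gbm_killed = res$summary$pct_gbm_killed,
                   max_T = res$summary$max_T,
                   fluence_hash = rlang::hash(fl$psi),
                   result = if (keep_results) list(res) else list(NULL))
  })
  out <- dplyr::bind_rows(rows)
  if (!keep_results) out$result <- NULL
  out
}
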