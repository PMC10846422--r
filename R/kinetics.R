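#' PDT kinetics parameters
#'
#' Constants of the macroscopic singlet-oxygen model. Defaults: `xi`
#' 3.7e-3 cm^2 mW^-1 s^-1 (oxygen consumption per unit photosensitizer and
#' fluence rate), `sigma` 9e-5 uM^-1 (photobleaching ratio), `rho_lc` 33 uM
#' (low-concentration correction), `beta` 11.9 uM (triplet decay /
#' oxygen-quenching ratio), `phi0` 21.6 uM/s (maximum Krogh-cylinder
#' perfusion rate), `alpha_solubility` 1.295 uM/mmHg and `p_tio2` 30 mmHg
#' (so the initial tissue oxygen is 38.85 uM), `q0` 26.3 uM/s (cerebral
#' metabolic oxygen consumption, folded into the perfusion calibration),
#' `threshold` 560 uM of cumulative reacted singlet oxygen for cell kill,
#' and the Krogh geometry (`vz` 200 um/s, `Rc` 2.5 um, `Rt` 30 um, `lz`
#' 200 um).
#'
#' @param ... named overrides of any default
#' @param o2_init initial/equilibrium tissue oxygen, uM; `NULL` (default)
#'   uses `alpha_solubility * p_tio2`
#' @return a `kinetics_params` list
#' @export
#' @examples
#' kinetics_params()$threshold
#' initial_o2(kinetics_params())
kinetics_params <- function(..., o2_init = NULL) {
  p <- list(xi = 3.7e-3, sigma = 9e-5, rho_lc = 33, beta = 11.9,
            phi0 = 21.6, alpha_solubility = 1.295, p_tio2 = 30,
            q0 = 26.3, threshold = 560,
            vz = 200, Rc = 2.5, Rt = 30, lz = 200)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown kinetics parameter: ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  if (any(unlist(p[c("xi", "sigma", "rho_lc", "beta", "phi0", "threshold")]) <= 0))
    stop("kinetics parameters must be positive")
  if (p$alpha_solubility < 0 || p$p_tio2 < 0)
    stop("oxygen solubility and partial pressure must be >= 0")
  p$o2_init <- if (is.null(o2_init)) p$alpha_solubility * p$p_tio2 else o2_init
  structure(p, class = "kinetics_params")
}

#' Initial tissue oxygen concentration
#'
#' `[3O2]_0 = alpha * PtiO2` (uM): Henry-law solubility times the tissue
#' oxygen partial pressure; 1.295 x 30 = 38.85 uM at the defaults.
#'
#' @param params a [kinetics_params()]
#' @return concentration, uM
#' @export
initial_o2 <- function(params = kinetics_params()) {
  params$alpha_solubility * params$p_tio2
}

#' Krogh-derived oxygen perfusion rate
#'
#' Maximum rate of tissue oxygen resupply as a function of global treatment
#' time: `Phi(t) = Phi0 * P(t')` with `t' = (t - 750)/632.1` and `P` the
#' quartic rational polynomial of the Krogh-cylinder fit (leading-order
#' asymptote 0.99).
#'
#' @param t_seconds time since first light-on, s (vectorized)
#' @param phi0 scale, uM/s
#' @return perfusion rate, uM/s
#' @export
perfusion_phi <- function(t_seconds, phi0 = 21.6) {
  if (any(!is.finite(t_seconds))) stop("t must be finite")
  vapply(t_seconds, perfusion_phi_cpp, numeric(1), phi0 = phi0)
}

#' Kinetics state over the photosensitized voxels
#'
#' Builds the per-voxel state (PpIX, tissue oxygen, cumulative reacted
#' singlet oxygen, kill mask) restricted to voxels carrying photosensitizer
#' (`F_GBM > 0`); all other voxels have no PDT dynamics.
#'
#' @param grid a [tissue_grid]
#' @param ppix0_uM initial PpIX for pure GBM, uM
#' @param params a [kinetics_params()]
#' @return a `kinetics_state`
#' @export
kinetics_state <- function(grid, ppix0_uM = 5, params = kinetics_params()) {
  fgbm <- grid$fractions[, , , "gbm"]
  idx <- which(fgbm > 0)
  structure(list(
    idx = idx, dims = grid_shape(grid),
    fgbm = fgbm[idx], fgbm_total = sum(fgbm[idx]),
    s0 = ppix0_uM * fgbm[idx],
    o2 = rep(params$o2_init, length(idx)),
    o2rx = rep(0, length(idx)),
    killed = rep(FALSE, length(idx)),
    t = 0), class = "kinetics_state")
}

#' Integrate the PDT kinetics over an illumination schedule
#'
#' Advances the coupled photosensitizer / oxygen / reacted-singlet-oxygen
#' system one second at a time across the schedule (fluence rate is zero in
#' dark intervals), with `n_sub` RK4 sub-steps per second. Voxels whose
#' cumulative reacted singlet oxygen reaches `params$threshold *
#' threshold_scale` are flagged killed; dynamics continue in killed voxels.
#' With `fixed_oxygen = TRUE` the oxygen pool is held exactly at its initial
#' value (no depletion, no perfusion).
#'
#' @param state a [kinetics_state()]
#' @param fluence a `fluence_grid` from [transport()] (per-watt map)
#' @param schedule tibble from [build_schedule()]
#' @param power_W source power, W
#' @param params a [kinetics_params()]
#' @param fixed_oxygen hold oxygen constant
#' @param threshold_scale multiplier on the kill threshold
#' @param n_sub RK4 sub-steps per second (>= 1)
#' @return updated `kinetics_state` with a `series` tibble attached:
#'   per-second `t`, `pct_gbm_remaining`, `mean_s0`, `mean_o2`, `max_o2rx`,
#'   `light_on`
#' @export
kinetics_run <- function(state, fluence, schedule, power_W = 2,
                         params = kinetics_params(), fixed_oxygen = FALSE,
                         threshold_scale = 1, n_sub = 10L) {
  stopifnot(inherits(state, "kinetics_state"))
  if (power_W < 0) stop("power must be >= 0")
  if (threshold_scale <= 0) stop("threshold_scale must be > 0")
  psi <- fluence$psi[state$idx] * power_W
  schedule <- quantize_schedule(schedule)
  sched <- as.matrix(schedule[, c("light_on", "duration_s")])
  storage.mode(sched) <- "double"
  res <- kinetics_run_cpp(psi, state$s0, state$o2, state$o2rx, state$killed,
                          state$fgbm, state$fgbm_total, sched, state$t,
                          params$xi, params$sigma, params$rho_lc,
                          params$beta, params$phi0, params$o2_init,
                          params$threshold * threshold_scale,
                          fixed_oxygen, as.integer(n_sub))
  series <- tibble::tibble(t = res$series[, 1],
                           pct_gbm_remaining = res$series[, 2],
                           mean_s0 = res$series[, 3],
                           mean_o2 = res$series[, 4],
                           max_o2rx = res$series[, 5],
                           light_on = res$series[, 6] > 0)
  out <- state
  out$s0 <- res$s0; out$o2 <- res$o2; out$o2rx <- res$o2rx
  out$killed <- res$killed; out$t <- res$t
  out$series <- if (is.null(state$series)) series
                else dplyr::bind_rows(state$series, series)
  out
}

#' Apply the singlet-oxygen kill threshold
#'
#' Marks voxels whose cumulative reacted singlet oxygen has reached the
#' threshold and computes the percentage of GBM remaining, weighting voxels
#' by their GBM fraction: `100 * sum(F_GBM over alive) / sum(F_GBM over all
#' post-resection GBM voxels)`.
#'
#' @param state a `kinetics_state`
#' @param threshold kill threshold, uM (> 0)
#' @return list with `killed` (logical over the state's voxels) and
#'   `pct_gbm_remaining`
#' @export
apply_threshold <- function(state, threshold = kinetics_params()$threshold) {
  if (threshold <= 0) stop("threshold must be > 0")
  killed <- state$o2rx >= threshold
  pct <- if (state$fgbm_total > 0)
    100 * sum(state$fgbm[!killed]) / state$fgbm_total else 100
  list(killed = killed, pct_gbm_remaining = pct)
}

#' Residual whole-tumor percentage after resection plus PDT
#'
#' Surgery removes `resected_pct` of the tumor; PDT then kills
#' `kill_pct` of what resection left behind. The remaining fraction of the
#' original tumor is `(100 - resected_pct) * (100 - kill_pct) / 100`; with
#' 95% resection, kill fractions of 39% and 61% leave 3.05% and 1.95%.
#'
#' @param kill_pct percentage of post-resection GBM killed by PDT
#' @param resected_pct percentage of the tumor removed surgically
#' @return percentage of the full tumor remaining
#' @export
#' @examples
#' residual_tumor_pct(39)  # 3.05
#' residual_tumor_pct(61)  # 1.95
residual_tumor_pct <- function(kill_pct, resected_pct = 95) {
  stopifnot(kill_pct >= 0, kill_pct <= 100,
            resected_pct >= 0, resected_pct <= 100)
  (100 - resected_pct) * (100 - kill_pct) / 100
}

#' Cerebral metabolic oxygen consumption from the skin-rate scaling
#'
#' Scales a skin metabolic rate in uM/s by the ratio of cerebral to skin
#' oxygen consumption quoted per 100 g tissue: `1.5 * 3.5 / 0.2 = 26.3 uM/s`
#' at the defaults.
#'
#' @param q_skin_uMs skin metabolic rate, uM/s
#' @param cerebral_ml cerebral rate, ml/100g/min
#' @param skin_ml skin rate, ml/100g/min
#' @return cerebral metabolic rate, uM/s (rounded to 0.1)
#' @export
metabolic_q0 <- function(q_skin_uMs = 1.5, cerebral_ml = 3.5, skin_ml = 0.2) {
  stopifnot(q_skin_uMs > 0, cerebral_ml > 0, skin_ml > 0)
  # half-up to 0.1 (26.25 reports as 26.3)
  floor(q_skin_uMs * cerebral_ml / skin_ml * 10 + 0.5) / 10
}
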