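#' Default run configuration
#'
#' Nested configuration mirroring the module structure, with defaults equal
#' to the study's standard conditions: the full-size phantom geometry, 2 W,
#' 8.6 min irradiation in 5 fractions with 2 min breaks, 5 uM initial PpIX,
#' 560 uM kill threshold, and the default kinetics/thermal constants.
#'
#' @return nested named list with blocks `phantom`, `mcrt`, `kinetics`,
#'   `thermal`, `protocol`, plus `seed` and `schema_version`
#' @export
default_config <- function() {
  list(
    schema_version = 1L,
    seed = 1L,
    phantom = list(grid_shape = c(250L, 231L, 155L),
                   extent_cm = c(5.8, 5.4, 3.6),
                   balloon_axes_cm = c(7, 4, 3),
                   rim_thickness_mm = 2, sphere_radius_mm = 3,
                   saline_gap_mm = 1, brain_white_frac = 0.7,
                   rim_noise = 0, margin_cm = 1),
    mcrt = list(n_packets = 1e5, fresnel = TRUE),
    kinetics = list(xi = 3.7e-3, sigma = 9e-5, rho_lc = 33, beta = 11.9,
                    phi0 = 21.6, alpha_solubility = 1.295, p_tio2 = 30,
                    q0 = 26.3, threshold = 560,
                    vz = 200, Rc = 2.5, Rt = 30, lz = 200),
    thermal = list(size_cm = 3.5, n_voxels = 152L, t_brain = 37, t_room = 22,
                   equilibrate_s = 300, damage_T = 48),
    protocol = list(power_W = 2, intralipid_ml = 44, irradiation_min = NULL,
                    n_fractions = 5L, break_min = 2, ppix0_uM = 5,
                    fixed_oxygen = FALSE, fractionated = TRUE,
                    threshold_scale = 1)
  )
}

# per-key validation: sign/range constraints on physical quantities
check_config_block <- function(block, values, defaults) {
  unknown <- setdiff(names(values), names(defaults))
  if (length(unknown))
    stop("unknown config key: ", paste0(block, ".", unknown[1]))
  nonneg <- c("rim_thickness_mm", "sphere_radius_mm", "saline_gap_mm",
              "rim_noise", "margin_cm", "power_W", "break_min", "ppix0_uM",
              "equilibrate_s", "irradiation_min")
  positive <- c("n_packets", "xi", "sigma", "rho_lc", "beta", "phi0",
                "threshold", "threshold_scale", "size_cm", "n_voxels",
                "intralipid_ml", "n_fractions")
  for (k in names(values)) {
    v <- values[[k]]
    if (k %in% nonneg && !is.null(v) && any(v < 0))
      stop("config key ", block, ".", k, " must be >= 0")
    if (k %in% positive && !is.null(v) && any(v <= 0))
      stop("config key ", block, ".", k, " must be > 0")
  }
  if (identical(block, "phantom")) {
    for (k in c("grid_shape", "extent_cm", "balloon_axes_cm"))
      if (!is.null(values[[k]]) &&
          (length(values[[k]]) != 3 || any(values[[k]] <= 0)))
        stop("config key phantom.", k, " must be 3 positive values")
    if (!is.null(values$brain_white_frac) &&
        (values$brain_white_frac < 0 || values$brain_white_frac > 1))
      stop("config key phantom.brain_white_frac must lie in [0, 1]")
  }
  invisible(TRUE)
}

merge_config <- function(user) {
  def <- default_config()
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stop("unknown config block: ", unknown[1])
  for (blk in intersect(names(user), c("phantom", "mcrt", "kinetics",
                                       "thermal", "protocol"))) {
    check_config_block(blk, user[[blk]], def[[blk]])
    def[[blk]] <- utils::modifyList(def[[blk]], user[[blk]],
                                    keep.null = TRUE)
  }
  if (!is.null(user$seed)) def$seed <- as.integer(user$seed)
  if (!is.null(user$schema_version) && user$schema_version != 1L)
    stop("unsupported config schema_version: ", user$schema_version)
  def
}

#' Load / save a run configuration
#'
#' YAML configuration with blocks `[phantom] [mcrt] [kinetics] [thermal]
#' [protocol]` plus `seed`. Unknown blocks or keys are rejected with the
#' offending key path; physical quantities are validated for sign/range.
#' Omitted keys take the standard-protocol defaults, so an empty file
#' reproduces the standard study conditions.
#'
#' @param path YAML file path
#' @return `load_config`: the merged, validated configuration list;
#'   `save_config`: `path`, invisibly
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  merge_config(user)
}

#' @rdname load_config
#' @param config a configuration list
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Protocol spec from a configuration
#' @param config list from [load_config()] / [default_config()]
#' @return a [protocol_spec()]
#' @export
config_protocol <- function(config) {
  p <- config$protocol
  protocol_spec(power_W = p$power_W, irradiation_min = p$irradiation_min,
                intralipid_ml = p$intralipid_ml,
                n_fractions = p$n_fractions, break_min = p$break_min,
                ppix0_uM = p$ppix0_uM, fixed_oxygen = p$fixed_oxygen,
                fractionated = p$fractionated,
                threshold_scale = p$threshold_scale)
}

#' Phantom from a configuration
#' @param config list from [load_config()] / [default_config()]
#' @return a [tissue_grid]
#' @export
config_phantom <- function(config) {
  ph <- config$phantom
  make_phantom(grid_shape = ph$grid_shape, extent_cm = ph$extent_cm,
               balloon_axes_cm = ph$balloon_axes_cm,
               rim_thickness_mm = ph$rim_thickness_mm,
               sphere_radius_mm = ph$sphere_radius_mm,
               saline_gap_mm = ph$saline_gap_mm,
               brain_white_frac = ph$brain_white_frac,
               rim_noise = ph$rim_noise, margin_cm = ph$margin_cm,
               seed = config$seed)
}

#' Kinetics parameters from a configuration
#' @param config list from [load_config()] / [default_config()]
#' @return a [kinetics_params()]
#' @export
config_kinetics <- function(config) {
  k <- config$kinetics
  kinetics_params(xi = k$xi, sigma = k$sigma, rho_lc = k$rho_lc,
                  beta = k$beta, phi0 = k$phi0,
                  alpha_solubility = k$alpha_solubility,
                  p_tio2 = k$p_tio2, q0 = k$q0, threshold = k$threshold,
                  vz = k$vz, Rc = k$Rc, Rt = k$Rt, lz = k$lz)
}

#' Summarize a treatment result
#'
#' Flat, JSON-serializable summary: end-of-treatment % GBM remaining,
#' maximum temperature, kill depth per probe line, the energy ledger of the
#' fluence run, and provenance (seed, config hash).
#'
#' @param result a `treatment_result`
#' @return named list
#' @export
summarize_treatment <- function(result) {
  stopifnot(inherits(result, "treatment_result"))
  s <- result$summary
  kd <- setNames(as.list(result$kill_depth$kill_depth_mm),
                 paste0("kill_depth_mm_", result$kill_depth$probe))
  c(list(pct_gbm_remaining = s$pct_gbm_remaining,
         pct_gbm_killed = s$pct_gbm_killed,
         max_T = s$max_T, damage = s$damage,
         total_time_min = s$total_time_min,
         energy_J = s$energy_J),
    kd,
    list(energy_ledger = list(absorbed = result$fluence$absorbed,
                              escaped = result$fluence$escaped,
                              roulette_killed = result$fluence$roulette_killed),
         n_packets = result$fluence$n_packets,
         seed = result$seed, config_hash = result$config_hash))
}

#' @rdname summarize_treatment
#' @param path output JSON path
#' @export
write_summary <- function(result, path) {
  jsonlite::write_json(summarize_treatment(result), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Validate a written treatment summary against the shipped schema
#'
#' Checks the JSON summary for the schema's required keys and numeric
#' ranges (a light-weight structural validation).
#'
#' @param path path to a summary JSON written by [write_summary()]
#' @return `TRUE` invisibly; errors describing the first violation otherwise
#' @export
validate_summary <- function(path) {
  schema <- jsonlite::read_json(system.file("extdata", "summary-schema.json",
                                            package = "pdtsim"),
                                simplifyVector = TRUE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(schema$required, names(obj))
  if (length(missing))
    stop("summary is missing required field(s): ",
         paste(missing, collapse = ", "))
  for (k in names(schema$properties)) {
    pr <- schema$properties[[k]]
    v <- obj[[k]]
    if (identical(pr$type, "number") && !(is.numeric(v) || is.na(v)))
      stop("summary field ", k, " must be numeric")
    if (is.numeric(v) && !is.null(pr$minimum) && !is.na(v) && v < pr$minimum)
      stop("summary field ", k, " below minimum")
    if (is.numeric(v) && !is.null(pr$maximum) && !is.na(v) && v > pr$maximum)
      stop("summary field ", k, " above maximum")
  }
  invisible(TRUE)
}
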