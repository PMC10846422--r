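#' Material property table
#'
#' Optical and thermal properties of the five materials in the scene. Optical
#' entries (635 nm): absorption coefficient `mua` (cm^-1), scattering
#' coefficient `mus` (cm^-1), refractive index `n`, Henyey-Greenstein
#' anisotropy `g`. Thermal entries: density `rho` (kg/m^3), specific heat
#' `cp` (J/(kg K)), conductivity `kappa` (W/(m K)); brain tissue uses
#' literature-typical constants, intralipid and saline are treated as water.
#'
#' @param overrides optional named list of lists, e.g.
#'   `list(gbm = list(mua = 1.5))`, merged over the defaults.
#' @return A tibble with one row per material (`white`, `gray`, `gbm`,
#'   `intralipid`, `saline`).
#' @export
#' @examples
#' material_table()
material_table <- function(overrides = NULL) {
  tbl <- tibble::tibble(
    material = c("white", "gray", "gbm", "intralipid", "saline"),
    mua   = c(0.63, 0.99, 1.3, 0.001, 0.003),
    mus   = c(686.0, 202.0, 218.0, 10.0, 0.003),
    n     = c(1.38, 1.38, 1.38, 1.33, 1.33),
    g     = c(0.85, 0.85, 0.85, 0.875, 0.9),
    rho   = c(1046, 1046, 1046, 1000, 1000),
    cp    = c(3630, 3630, 3630, 4180, 4180),
    kappa = c(0.51, 0.51, 0.51, 0.60, 0.60)
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides))
    for (m in names(overrides)) {
      i <- match(m, tbl$material)
      if (is.na(i)) stop("unknown material in overrides: ", m)
      for (f in names(overrides[[m]])) {
        if (!f %in% names(tbl)) stop("unknown material field: ", f)
        tbl[[f]][i] <- overrides[[m]][[f]]
      }
    }
  }
  validate_materials(tbl)
  tbl
}

#' @keywords internal
validate_materials <- function(tbl) {
  stopifnot(is.data.frame(tbl),
            all(c("material", "mua", "mus", "n", "g") %in% names(tbl)))
  if (any(tbl$mua < 0)) stop("mua must be >= 0")
  if (any(tbl$mus < 0)) stop("mus must be >= 0")
  if (any(tbl$g <= -1 | tbl$g >= 1)) stop("g must lie in (-1, 1)")
  if (any(tbl$n < 1)) stop("refractive index must be >= 1")
  if (!is.null(tbl$rho) && any(tbl$rho <= 0)) stop("rho must be positive")
  invisible(tbl)
}

# canonical material order used by all fraction arrays
pdt_materials <- function() c("white", "gray", "gbm", "intralipid", "saline")

#' PpIX extinction coefficient at 630 nm
#'
#' Default 0.0265 cm^-1 per (ug/ml). By the simulator's default numeric
#' convention the micromolar PpIX concentration multiplies this coefficient
#' directly (see [ppix_absorption()]).
#' @export
ppix_extinction <- function() 0.0265

# PpIX molecular weight, g/mol (for the unit-rigorous conversion)
ppix_mw <- function() 562.7
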