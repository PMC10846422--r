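#' @title Voxelized tissue scene
#' @description A `tissue_grid` holds per-voxel material fractions on a
#'   regular lattice together with region labels. Fractions always sum to 1
#'   in every voxel. Coordinates are cell-centered, 0-based voxel indices,
#'   axis order (x, y, z); voxel `(i, j, k)` is centered at
#'   `((i + 0.5) dx, (j + 0.5) dy, (k + 0.5) dz)`.
#' @name tissue_grid
NULL

# region label codes
REGION_BRAIN <- 0L
REGION_BALLOON <- 1L
REGION_SALINE <- 2L
REGION_RIM <- 3L
REGION_SPHERE <- 4L

region_names <- function() {
  c(brain = REGION_BRAIN, balloon = REGION_BALLOON, saline = REGION_SALINE,
    rim = REGION_RIM, tumor_sphere = REGION_SPHERE)
}

new_tissue_grid <- function(fractions, labels, spacing, meta = list()) {
  structure(list(fractions = fractions, labels = labels,
                 spacing = spacing, meta = meta),
            class = "tissue_grid")
}

#' Validate a tissue grid
#'
#' Checks fraction closure (sum to 1 within `tol` in every voxel), the
#' `[0, 1]` range of each fraction, and shape consistency.
#'
#' @param grid a `tissue_grid`
#' @param tol closure tolerance (default 1e-9)
#' @return the grid, invisibly; errors on violation
#' @export
validate_tissue_grid <- function(grid, tol = 1e-9) {
  stopifnot(inherits(grid, "tissue_grid"))
  fr <- grid$fractions
  d <- dim(fr)
  if (length(d) != 4L || d[4] != 5L)
    stop("fractions must be a 4-D array with 5 material channels")
  if (!identical(dim(grid$labels), d[1:3]))
    stop("label array shape does not match fractions")
  if (length(grid$spacing) != 3L || any(grid$spacing <= 0))
    stop("spacing must be 3 positive voxel edge lengths (cm)")
  if (any(fr < -tol) || any(fr > 1 + tol))
    stop("material fractions must lie in [0, 1]")
  s <- rowSums(matrix(fr, ncol = 5L))
  if (max(abs(s - 1)) > tol)
    stop("material fractions must sum to 1 in every voxel (max deviation ",
         format(max(abs(s - 1))), ")")
  invisible(grid)
}

#' @export
print.tissue_grid <- function(x, ...) {
  d <- dim(x$fractions)[1:3]
  cat("<tissue_grid> ", paste(d, collapse = " x "), " voxels, spacing ",
      paste(signif(x$spacing, 3), collapse = " x "), " cm\n", sep = "")
  tb <- table(factor(x$labels, levels = region_names(),
                     labels = names(region_names())))
  for (nm in names(tb)) cat(sprintf("  %-13s %d voxels\n", nm, tb[[nm]]))
  invisible(x)
}

#' Grid shape helper
#' @param grid a `tissue_grid`
#' @return integer voxel counts per axis
#' @export
grid_shape <- function(grid) dim(grid$fractions)[1:3]

# cell-centered coordinates (cm) along one axis
axis_centers <- function(n, d) (seq_len(n) - 0.5) * d

#' Ellipsoid volume (cm^3)
#'
#' Volume of an ellipsoid given its full axis lengths, `4/3 pi (a b c) / 8`.
#' The 7 x 4 x 3 cm treatment balloon has a volume of 44 cm^3 to the nearest
#' integer.
#' @param axes_cm full axis lengths, cm
#' @export
#' @examples
#' ellipsoid_volume(c(7, 4, 3))
ellipsoid_volume <- function(axes_cm) {
  stopifnot(length(axes_cm) == 3, all(axes_cm > 0))
  4 / 3 * pi * prod(axes_cm / 2)
}

#' Build the synthetic resection-cavity phantom
#'
#' Constructs the voxelized scene: an ellipsoidal intralipid-filled balloon
#' inside the resection cavity, a saline-filled gap between balloon and
#' cavity wall, a residual GBM rim up to `rim_thickness_mm` deep in which the
#' GBM fraction falls linearly from 1 at the cavity wall to 0 at rim depth,
#' a small solid tumor sphere seated on the cavity wall in the top-right
#' (+x/+y) corner, and white/gray-matter brain elsewhere. The balloon may be
#' truncated by the grid on the side away from the sphere; on the sphere
#' side at least `margin_cm` of brain must remain.
#'
#' @param grid_shape integer voxel counts per axis (default the full-study
#'   grid, 250 x 231 x 155)
#' @param extent_cm physical grid extents, cm (default 5.8 x 5.4 x 3.6)
#' @param balloon_axes_cm full axis lengths of the balloon ellipsoid, cm
#' @param rim_thickness_mm residual-tumor rim depth, mm (default 2)
#' @param sphere_radius_mm radius of the solid tumor sphere, mm
#' @param saline_gap_mm thickness of the saline-filled gap between balloon
#'   and cavity wall, mm
#' @param brain_white_frac white-matter fraction of background brain
#' @param rim_noise amplitude of smooth multiplicative heterogeneity applied
#'   to the rim GBM fraction (0 disables; deterministic given `seed`)
#' @param margin_cm required brain margin beyond the cavity on the sphere
#'   (+x) side, cm
#' @param seed integer seed for the rim heterogeneity field
#' @return a [tissue_grid]
#' @export
#' @examples
#' ph <- make_phantom(grid_shape = c(24, 24, 24), extent_cm = c(2.4, 2.4, 2.4),
#'                    balloon_axes_cm = c(1.8, 1.4, 1.2), margin_cm = 0.3)
#' ph
make_phantom <- function(grid_shape = c(250L, 231L, 155L),
                         extent_cm = c(5.8, 5.4, 3.6),
                         balloon_axes_cm = c(7, 4, 3),
                         rim_thickness_mm = 2,
                         sphere_radius_mm = 3,
                         saline_gap_mm = 1,
                         brain_white_frac = 0.7,
                         rim_noise = 0,
                         margin_cm = 1,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 2),
            length(extent_cm) == 3, all(extent_cm > 0),
            length(balloon_axes_cm) == 3, all(balloon_axes_cm > 0),
            brain_white_frac >= 0, brain_white_frac <= 1,
            rim_noise >= 0, saline_gap_mm >= 0)
  if (rim_thickness_mm < 0) stop("rim thickness must be >= 0")
  nx <- as.integer(grid_shape[1]); ny <- as.integer(grid_shape[2])
  nz <- as.integer(grid_shape[3])
  spacing <- extent_cm / grid_shape
  semi <- balloon_axes_cm / 2
  gap <- saline_gap_mm / 10
  rim <- rim_thickness_mm / 10
  rs <- sphere_radius_mm / 10

  if (2 * semi[2] + 2 * gap >= extent_cm[2] ||
      2 * semi[3] + 2 * gap >= extent_cm[3])
    stop("balloon is larger than the grid in y or z")

  # balloon centered in y/z; in x pushed left until the cavity leaves at
  # least margin_cm of brain on the sphere (+x) side
  cx <- min(extent_cm[1] / 2, extent_cm[1] - margin_cm - semi[1] - gap)
  if (cx + semi[1] + gap + margin_cm > extent_cm[1] + 1e-9)
    stop("cavity does not fit with the required brain margin on the sphere side")
  center <- c(cx, extent_cm[2] / 2, extent_cm[3] / 2)

  xs <- axis_centers(nx, spacing[1])
  ys <- axis_centers(ny, spacing[2])
  zs <- axis_centers(nz, spacing[3])

  semi_c <- semi + gap  # cavity = balloon + saline gap
  ex <- ((xs - center[1]) / semi[1])^2
  ey <- ((ys - center[2]) / semi[2])^2
  ez <- ((zs - center[3]) / semi[3])^2
  re2_b <- outer(outer(ex, ey, "+"), ez, "+")  # balloon normalized radius^2
  exc <- ((xs - center[1]) / semi_c[1])^2
  eyc <- ((ys - center[2]) / semi_c[2])^2
  ezc <- ((zs - center[3]) / semi_c[3])^2
  re2_c <- outer(outer(exc, eyc, "+"), ezc, "+")

  # approximate Euclidean depth beyond the cavity surface:
  # d ~ (re - 1) / |grad re|, with grad re = (p - c) / (semi^2 re)
  gx <- ((xs - center[1]) / semi_c[1]^2)^2
  gy <- ((ys - center[2]) / semi_c[2]^2)^2
  gz <- ((zs - center[3]) / semi_c[3]^2)^2
  gnorm2 <- outer(outer(gx, gy, "+"), gz, "+")
  re_c <- sqrt(re2_c)
  depth <- (re_c - 1) * re_c / pmax(sqrt(gnorm2), 1e-12)

  in_balloon <- re2_b <= 1
  in_cavity <- re2_c <= 1

  f_gbm <- pmin(pmax(1 - depth / max(rim, 1e-12), 0), 1)
  f_gbm[in_cavity] <- 0
  if (rim <= 0) f_gbm[] <- 0

  if (rim_noise > 0) {
    noise <- smooth_noise_field(c(nx, ny, nz), seed = seed)
    f_gbm <- pmin(pmax(f_gbm * (1 + rim_noise * noise), 0), 1)
  }

  # solid tumor sphere seated on the cavity wall, top-right (+x/+y) corner
  u <- c(1, 1, 0) / sqrt(2)
  tmag <- sqrt(1 / sum((u / semi_c)^2))
  sphere_center <- center + u * tmag
  sx <- (xs - sphere_center[1])^2
  sy <- (ys - sphere_center[2])^2
  sz <- (zs - sphere_center[3])^2
  d2_sphere <- outer(outer(sx, sy, "+"), sz, "+")
  in_sphere <- d2_sphere <= rs^2 & !in_balloon
  f_gbm[in_sphere] <- 1

  labels <- array(REGION_BRAIN, dim = c(nx, ny, nz))
  labels[f_gbm > 0] <- REGION_RIM
  labels[in_cavity & !in_balloon] <- REGION_SALINE
  labels[in_balloon] <- REGION_BALLOON
  labels[in_sphere] <- REGION_SPHERE

  fr <- array(0, dim = c(nx, ny, nz, 5L),
              dimnames = list(NULL, NULL, NULL, pdt_materials()))
  fr[, , , "intralipid"][in_balloon] <- 1
  sal <- in_cavity & !in_balloon & !in_sphere
  fr[, , , "saline"][sal] <- 1
  tissue <- !in_balloon & !sal
  f_gbm[!tissue] <- 0
  fr[, , , "gbm"] <- f_gbm
  rest <- 1 - f_gbm
  rest[!tissue] <- 0
  fr[, , , "white"] <- rest * brain_white_frac
  fr[, , , "gray"] <- rest * (1 - brain_white_frac)

  grid <- new_tissue_grid(fr, labels, spacing,
                          meta = list(extent_cm = extent_cm,
                                      balloon_axes_cm = balloon_axes_cm,
                                      balloon_center_cm = center,
                                      cavity_semi_cm = semi_c,
                                      sphere_center_cm = sphere_center,
                                      sphere_radius_cm = rs,
                                      rim_thickness_cm = rim,
                                      seed = as.integer(seed)))
  validate_tissue_grid(grid)
  grid
}

# smooth multiplicative heterogeneity: coarse Gaussian lattice, trilinearly
# interpolated to the grid; deterministic per seed
smooth_noise_field <- function(shape, n_coarse = 8L, seed = 1L) {
  rng <- local({
    set.seed(as.integer(seed))
    array(stats::rnorm(n_coarse^3), dim = rep(n_coarse, 3))
  })
  interp_axis <- function(n) {
    u <- (seq_len(n) - 0.5) / n * (n_coarse - 1) + 1
    i0 <- pmin(floor(u), n_coarse - 1)
    list(i0 = i0, w = u - i0)
  }
  ax <- lapply(shape, interp_axis)
  out <- array(0, dim = shape)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 0) 1 - ax[[1]]$w else ax[[1]]$w
    wy <- if (dy == 0) 1 - ax[[2]]$w else ax[[2]]$w
    wz <- if (dz == 0) 1 - ax[[3]]$w else ax[[3]]$w
    vals <- rng[cbind(rep(ax[[1]]$i0 + dx, times = shape[2] * shape[3]),
                      rep(rep(ax[[2]]$i0 + dy, each = shape[1]),
                          times = shape[3]),
                      rep(ax[[3]]$i0 + dz, each = shape[1] * shape[2]))]
    w <- as.vector(outer(outer(wx, wy), wz))
    out <- out + array(vals * w, dim = shape)
  }
  out
}

#' Desk-scale demonstration phantom
#'
#' A reduced phantom preserving the scene's structure (balloon, saline gap,
#' 2 mm rim, tumor sphere, brain) at a size where transport, kinetics and
#' heat runs complete in seconds: 0.5 mm voxels over a 2.4 cm cube with a
#' 1.8 x 1.4 x 1.2 cm balloon.
#'
#' @param n voxels per axis (default 48)
#' @param seed seed forwarded to [make_phantom()]
#' @param ... further arguments to [make_phantom()]
#' @return a [tissue_grid]
#' @export
demo_phantom <- function(n = 48L, seed = 1L, ...) {
  make_phantom(grid_shape = rep(as.integer(n), 3),
               extent_cm = rep(2.4, 3),
               balloon_axes_cm = c(1.8, 1.4, 1.2),
               sphere_radius_mm = 2,
               saline_gap_mm = 0.5,
               margin_cm = 0.3,
               seed = seed, ...)
}

#' Initial PpIX concentration field
#'
#' Per-voxel protoporphyrin IX concentration at the start of treatment,
#' `C = PpIX0 * F_GBM` (uM), proportional to the local GBM fraction.
#'
#' @param grid a [tissue_grid]
#' @param ppix0_uM initial concentration for a voxel of pure GBM, uM
#' @return 3-D array of concentrations, uM
#' @export
ppix_field <- function(grid, ppix0_uM = 5) {
  stopifnot(inherits(grid, "tissue_grid"))
  if (ppix0_uM < 0) stop("PpIX concentration must be >= 0")
  ppix0_uM * grid$fractions[, , , "gbm"]
}
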