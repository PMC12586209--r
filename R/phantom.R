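#' Voxel density volume
#'
#' Axis-aligned voxel grid of mineral-equivalent bone density (g/cm3,
#' dipotassium-phosphate calibration) with voxel spacing and world origin in
#' mm, plus optional anatomical landmarks (head center, neck/shaft axes,
#' greater-trochanter and distal shaft points, world mm).
#'
#' @param values 3D numeric array, non-negative and finite, >= 2 voxels per
#'   axis. Axis order is (x, y, z).
#' @param spacing voxel size, mm; scalar or length-3.
#' @param origin world coordinate of the center of voxel (1,1,1), mm.
#' @param landmarks optional named list of 3-vectors / axis descriptors.
#' @return Object of class `density_volume`.
#' @export
density_volume <- function(values, spacing, origin = c(0, 0, 0),
                           landmarks = list()) {
  if (length(dim(values)) != 3) stop("values must be a 3D array")
  if (any(dim(values) < 2)) stop("grid needs >= 2 voxels per axis")
  if (any(!is.finite(values))) stop("density values must be finite")
  if (any(values < 0)) stop("density values must be >= 0")
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin), landmarks = landmarks),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Density volume %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 3), collapse = " x ")))
  inb <- x$values > 0
  cat(sprintf("  in-bone voxels: %d (%.1f%%), density range [%.3g, %.3g]\n",
              sum(inb), 100 * mean(inb),
              if (any(inb)) min(x$values[inb]) else 0, max(x$values)))
  invisible(x)
}

# world coordinates of all voxel centers, n x 3
.voxel_centers <- function(vol) {
  d <- dim(vol$values)
  gx <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1]
  gy <- vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2]
  gz <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  list(x = gx, y = gy, z = gz)
}

#' Parametric proximal-femur phantom specification
#'
#' Geometry and densities of a three-primitive proximal femur: a head
#' sphere, a neck cylinder inclined at the neck-shaft angle, and a shaft
#' cylinder, each with a cortical shell around a trabecular interior.
#' The defaults are adult-scale (head radius 24 mm, neck 16 mm x 45 mm,
#' neck-shaft angle 125 deg, shaft radius 14 mm x 90 mm, 3 mm cortex).
#' Densities are mineral-equivalent g/cm3.
#'
#' @param head_radius,neck_radius,shaft_radius radii, mm.
#' @param neck_length,shaft_length lengths, mm.
#' @param neck_shaft_angle angle between neck and shaft axes, degrees.
#' @param cortical_thickness cortical shell thickness, mm.
#' @param cortical_density,trabecular_density shell / interior density,
#'   g/cm3 (cortical >= trabecular >= 0).
#' @param voxel_spacing voxel size of the generated volume, mm.
#' @param target_abmd optional areal BMD (g/cm2); when given, the generated
#'   volume is rescaled so its anteroposterior projection matches it.
#' @param noise_sd relative amplitude of optional smooth density noise.
#' @return Object of class `femur_phantom_spec`.
#' @export
femur_phantom_spec <- function(head_radius = 24, neck_radius = 16,
                               neck_length = 45, neck_shaft_angle = 125,
                               shaft_radius = 14, shaft_length = 90,
                               cortical_thickness = 3,
                               cortical_density = 1.2,
                               trabecular_density = 0.3,
                               voxel_spacing = 2, target_abmd = NULL,
                               noise_sd = 0) {
  s <- list(head_radius = head_radius, neck_radius = neck_radius,
            neck_length = neck_length, neck_shaft_angle = neck_shaft_angle,
            shaft_radius = shaft_radius, shaft_length = shaft_length,
            cortical_thickness = cortical_thickness,
            cortical_density = cortical_density,
            trabecular_density = trabecular_density,
            voxel_spacing = voxel_spacing, target_abmd = target_abmd,
            noise_sd = noise_sd)
  lens <- c(head_radius, neck_radius, neck_length, shaft_radius,
            shaft_length, cortical_thickness)
  if (any(lens <= 0)) stop("all lengths and radii must be > 0")
  if (voxel_spacing <= 0) stop("voxel_spacing must be > 0")
  if (trabecular_density < 0 || cortical_density < trabecular_density)
    stop("need cortical_density >= trabecular_density >= 0")
  structure(s, class = "femur_phantom_spec")
}

# inside-depth (mm, > 0 inside) of points relative to a sphere
.depth_sphere <- function(p, center, r) {
  r - sqrt((p[, 1] - center[1])^2 + (p[, 2] - center[2])^2 +
             (p[, 3] - center[3])^2)
}

# inside-depth of points relative to a finite cylinder from a to b
.depth_cylinder <- function(p, a, b, r) {
  ab <- b - a
  L <- sqrt(sum(ab^2))
  u <- ab / L
  dp <- cbind(p[, 1] - a[1], p[, 2] - a[2], p[, 3] - a[3])
  t <- dp %*% u
  radial <- sqrt(pmax(rowSums(dp^2) - t^2, 0))
  pmin(r - radial, t, L - t)
}

#' Generate a proximal-femur density phantom
#'
#' Voxelizes the head-sphere / neck-cylinder / shaft-cylinder union of a
#' [femur_phantom_spec()]: voxels within `cortical_thickness` of the outer
#' bone surface receive the cortical density, deeper voxels the trabecular
#' density, background is 0. The shaft axis is +z (distal end at the
#' origin) and the neck lies in the x-z plane, pointing medially (+x).
#' Landmarks (head center, neck and shaft axes, greater-trochanter and
#' distal points) are populated in world mm. Optional smooth multiplicative
#' noise (a trilinearly upsampled coarse random field) is controlled by
#' `noise_sd` and `seed`. If `target_abmd` is set, densities are rescaled
#' so the anteroposterior projection ([project_abmd()] along y) matches it.
#'
#' @param spec a [femur_phantom_spec()].
#' @param seed integer seed for the optional noise field.
#' @return A [density_volume()].
#' @export
generate_femur_phantom <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "femur_phantom_spec"))
  if (spec$voxel_spacing > spec$cortical_thickness)
    warning("voxel_spacing exceeds cortical_thickness: the cortical shell ",
            "is not resolvable at this resolution")
  beta <- (180 - spec$neck_shaft_angle) * pi / 180
  shaft_a <- c(0, 0, 0)
  shaft_b <- c(0, 0, spec$shaft_length)
  neck_dir <- c(sin(beta), 0, cos(beta))
  neck_a <- shaft_b
  neck_b <- neck_a + spec$neck_length * neck_dir
  head_c <- neck_b

  lo <- pmin(shaft_a - spec$shaft_radius, neck_b - spec$head_radius,
             c(-spec$shaft_radius, -max(spec$shaft_radius, spec$neck_radius,
                                        spec$head_radius), 0)) -
    2 * spec$voxel_spacing
  hi <- pmax(shaft_b + spec$shaft_radius, head_c + spec$head_radius) +
    2 * spec$voxel_spacing
  hi[2] <- max(spec$shaft_radius, spec$neck_radius, spec$head_radius) +
    2 * spec$voxel_spacing
  lo[2] <- -hi[2]

  h <- spec$voxel_spacing
  nx <- max(2L, ceiling((hi[1] - lo[1]) / h))
  ny <- max(2L, ceiling((hi[2] - lo[2]) / h))
  nz <- max(2L, ceiling((hi[3] - lo[3]) / h))
  gx <- lo[1] + (seq_len(nx) - 0.5) * h
  gy <- lo[2] + (seq_len(ny) - 0.5) * h
  gz <- lo[3] + (seq_len(nz) - 0.5) * h
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))

  depth <- pmax(.depth_sphere(pts, head_c, spec$head_radius),
                .depth_cylinder(pts, neck_a, neck_b, spec$neck_radius),
                .depth_cylinder(pts, shaft_a, shaft_b, spec$shaft_radius))
  vals <- numeric(nrow(pts))
  shell <- depth > 0 & depth <= spec$cortical_thickness
  core <- depth > spec$cortical_thickness
  vals[shell] <- spec$cortical_density
  vals[core] <- spec$trabecular_density
  arr <- array(vals, dim = c(nx, ny, nz))

  if (spec$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    # coarse random field, trilinearly upsampled -> smooth in space
    cdim <- pmax(2L, ceiling(c(nx, ny, nz) / 6))
    coarse <- array(rnorm(prod(cdim)), dim = cdim)
    ix <- (seq_len(nx) - 1) / (nx - 1) * (cdim[1] - 1) + 1
    iy <- (seq_len(ny) - 1) / (ny - 1) * (cdim[2] - 1) + 1
    iz <- (seq_len(nz) - 1) / (nz - 1) * (cdim[3] - 1) + 1
    noise <- .trilinear_grid(coarse, ix, iy, iz)
    inb <- arr > 0
    arr[inb] <- pmax(arr[inb] * (1 + spec$noise_sd * noise[inb]), 0)
  }

  vol <- density_volume(arr, spacing = h,
                        origin = lo + 0.5 * h,
                        landmarks = list(
                          head_center = head_c,
                          neck_axis = neck_dir,
                          neck_base = neck_a,
                          shaft_axis = c(0, 0, 1),
                          gt_point = c(-spec$shaft_radius, 0,
                                       spec$shaft_length),
                          distal_point = shaft_a))
  if (!is.null(spec$target_abmd)) {
    cur <- project_abmd(vol, "y")
    vol$values <- vol$values * (spec$target_abmd / cur)
  }
  vol
}

# trilinear interpolation of a 3D array at fractional grid indices
# (vectors ix, iy, iz define a tensor grid)
.trilinear_grid <- function(arr, ix, iy, iz) {
  d <- dim(arr)
  f <- function(i, n) pmin(pmax(i, 1), n)
  x0 <- f(floor(ix), d[1]); x1 <- f(x0 + 1, d[1]); tx <- ix - x0
  y0 <- f(floor(iy), d[2]); y1 <- f(y0 + 1, d[2]); ty <- iy - y0
  z0 <- f(floor(iz), d[3]); z1 <- f(z0 + 1, d[3]); tz <- iz - z0
  out <- array(0, dim = c(length(ix), length(iy), length(iz)))
  TX <- array(tx, dim = dim(out))
  TY <- aperm(array(ty, dim = c(length(iy), length(ix), length(iz))),
              c(2, 1, 3))
  TZ <- aperm(array(tz, dim = c(length(iz), length(ix), length(iy))),
              c(2, 3, 1))
  g <- function(a, b, c) arr[a, b, c, drop = FALSE]
  out <- g(x0, y0, z0) * (1 - TX) * (1 - TY) * (1 - TZ) +
    g(x1, y0, z0) * TX * (1 - TY) * (1 - TZ) +
    g(x0, y1, z0) * (1 - TX) * TY * (1 - TZ) +
    g(x1, y1, z0) * TX * TY * (1 - TZ) +
    g(x0, y0, z1) * (1 - TX) * (1 - TY) * TZ +
    g(x1, y0, z1) * TX * (1 - TY) * TZ +
    g(x0, y1, z1) * (1 - TX) * TY * TZ +
    g(x1, y1, z1) * TX * TY * TZ
  out
}

#' Project a density volume to areal BMD
#'
#' Line-integrates volumetric density (g/cm3) along one grid axis and
#' averages the resulting areal map (g/cm2) over the projected bone
#' footprint (pixels whose integral is positive). This mimics how a planar
#' DXA measurement reports areal BMD over the bone region, and is used to
#' rescale phantoms to a requested aBMD. Exactly linear in density and
#' invariant to grid translation.
#'
#' @param vol a [density_volume()].
#' @param direction projection axis: 1/2/3 or "x"/"y"/"z".
#' @return Mean areal density over the footprint, g/cm2.
#' @export
project_abmd <- function(vol, direction = "y") {
  stopifnot(inherits(vol, "density_volume"))
  ax <- if (is.character(direction)) match(direction, c("x", "y", "z")) else
    as.integer(direction)
  if (is.na(ax) || ax < 1 || ax > 3) stop("direction must be x, y or z")
  thickness_cm <- vol$spacing[ax] / 10
  areal <- apply(vol$values, setdiff(1:3, ax), sum) * thickness_cm
  footprint <- areal > 0
  if (!any(footprint)) stop("empty bone mask: projection undefined")
  mean(areal[footprint])
}
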