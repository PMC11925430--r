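#' Specification of a synthetic skull phantom
#'
#' An ellipsoidal calvarial shell with analytically known local thickness and
#' density. `thickness_field` and `density_field` are functions of surface
#' direction `(azimuth, elevation)` in degrees (see [direction_angles()])
#' returning mm and HU respectively; constants are accepted and promoted.
#' Suture gaps are great-arc bands of soft tissue splitting the shell into
#' the five calvarial bones.
#'
#' @param outer_radii Ellipsoid semi-axes (mm) in the canonical frame
#'   (left-right, anterior-posterior, inferior-superior).
#' @param thickness_field Function `(az, el) -> mm`, or a single number.
#' @param density_field Function `(az, el) -> HU`, or a single number.
#' @param suture_gaps Band layout from [default_suture_bands()], or `NULL`
#'   for an unbroken shell.
#' @param background_hu HU outside the shell (air by default).
#' @param blur_fwhm Gaussian partial-volume blur, full width at half maximum
#'   in mm (0 = none).
#' @param noise_sd Additive i.i.d. Gaussian noise SD in HU (0 = none).
#' @param spacing Voxel spacing (mm).
#' @param margin_mm Padding around the shell.
#' @param rng_seed Seed for the noise generator.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(outer_radii = c(57, 72, 60),
                         thickness_field = 3,
                         density_field = 800,
                         suture_gaps = default_suture_bands(),
                         background_hu = -1000,
                         blur_fwhm = 0.8,
                         noise_sd = 15,
                         spacing = c(0.5, 0.5, 1.5),
                         margin_mm = 5,
                         rng_seed = 1L) {
  outer_radii <- as.numeric(outer_radii)
  spacing <- as.numeric(spacing)
  if (length(outer_radii) != 3L || any(!is.finite(outer_radii)) ||
      any(outer_radii <= 0))
    stop("outer_radii must be three positive semi-axes (mm)", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive values (mm)", call. = FALSE)
  if (blur_fwhm < 0 || noise_sd < 0)
    stop("blur_fwhm and noise_sd must be non-negative", call. = FALSE)
  as_field <- function(f) {
    if (is.function(f)) f else {
      v <- as.numeric(f)
      function(az, el) rep(v, length(az))
    }
  }
  structure(
    list(outer_radii = outer_radii,
         thickness_field = as_field(thickness_field),
         density_field = as_field(density_field),
         suture_gaps = suture_gaps, background_hu = background_hu,
         blur_fwhm = blur_fwhm, noise_sd = noise_sd, spacing = spacing,
         margin_mm = margin_mm, rng_seed = as.integer(rng_seed)),
    class = "phantom_spec"
  )
}

# Ellipsoid surface radius along unit directions.
#' @keywords internal
ellipsoid_radius <- function(dirs, radii) {
  dirs <- rbind(dirs)
  1 / sqrt((dirs[, 1] / radii[1])^2 + (dirs[, 2] / radii[2])^2 +
             (dirs[, 3] / radii[3])^2)
}

#' Rasterize a skull phantom with analytic ground truth
#'
#' Builds the HU volume of the shell described by a [phantom_spec()]
#' (rasterization, then partial-volume blur, then noise) together with the
#' analytic per-location ground truth evaluated on the standard direction
#' grid *before* any degradation.
#'
#' @param spec A `phantom_spec`.
#' @param n_locations Ground-truth grid size (icosphere vertices).
#' @return List with elements `volume` (a `calvarisk_volume`) and `truth`
#'   (data.frame: location, azimuth, elevation, bone, thickness_mm,
#'   density_hu).
#' @export
generate_skull_phantom <- function(spec, n_locations = 2562L) {
  stopifnot(inherits(spec, "phantom_spec"))
  ext <- max(spec$outer_radii) + spec$margin_mm
  nd <- as.integer(ceiling(2 * ext / spec$spacing)) + 1L
  # voxel-centre offsets from the phantom centre
  ax <- lapply(1:3, function(a) (seq_len(nd[a]) - 1) * spec$spacing[a] - ext)
  X <- rep(ax[[1]], times = nd[2] * nd[3])
  Y <- rep(rep(ax[[2]], each = nd[1]), times = nd[3])
  Z <- rep(ax[[3]], each = nd[1] * nd[2])
  r <- sqrt(X^2 + Y^2 + Z^2)
  r[r == 0] <- 1e-9
  r_out <- r / sqrt((X / spec$outer_radii[1])^2 +
                      (Y / spec$outer_radii[2])^2 +
                      (Z / spec$outer_radii[3])^2)
  az <- atan2(X, Y) * 180 / pi
  el <- asin(pmin(1, pmax(-1, Z / r))) * 180 / pi
  thick <- spec$thickness_field(az, el)
  in_shell <- r <= r_out & r >= r_out - thick
  hu <- rep(spec$background_hu, length(r))
  if (any(in_shell)) {
    hu[in_shell] <- spec$density_field(az[in_shell], el[in_shell])
    if (!is.null(spec$suture_gaps) && spec$suture_gaps$width_mm > 0) {
      sh <- which(in_shell)
      u <- cbind(X[sh], Y[sh], Z[sh]) / r[sh]
      lab <- classify_direction(u, radius_mm = r_out[sh],
                                bands = spec$suture_gaps)
      hu[sh[lab == "suture"]] <- spec$suture_gaps$gap_hu
    }
  }
  vol <- array(hu, dim = nd)
  rm(X, Y, Z, r, r_out, az, el, thick, in_shell, hu)
  if (spec$blur_fwhm > 0)
    vol <- gaussian_blur3(vol, spec$spacing, spec$blur_fwhm)
  if (spec$noise_sd > 0) {
    set.seed(spec$rng_seed)
    vol <- vol + array(rnorm(length(vol), sd = spec$noise_sd), dim = nd)
  }
  volume <- new_volume(vol, spacing = spec$spacing,
                       origin = -ext + numeric(3))
  # analytic ground truth on the standard grid, pre-degradation
  dirs <- icosphere_directions(icosphere_level_for(n_locations))
  dirs <- dirs[seq_len(n_locations), , drop = FALSE]
  ang <- direction_angles(dirs)
  rr <- ellipsoid_radius(dirs, spec$outer_radii)
  truth <- data.frame(
    location = seq_len(n_locations),
    azimuth = ang$azimuth, elevation = ang$elevation,
    bone = classify_direction(dirs, radius_mm = rr, bands = spec$suture_gaps),
    thickness_mm = spec$thickness_field(ang$azimuth, ang$elevation),
    density_hu = spec$density_field(ang$azimuth, ang$elevation)
  )
  list(volume = volume, truth = truth)
}

# Smallest icosphere level whose vertex count reaches n.
#' @keywords internal
icosphere_level_for <- function(n) {
  counts <- 10 * 4^(0:6) + 2
  lev <- which(counts >= n)[1] - 1L
  if (is.na(lev)) stop("n_locations too large (max ", max(counts), ")",
                       call. = FALSE)
  lev
}
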