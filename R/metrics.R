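#' Local cranial bone thickness along centroid rays
#'
#' Thickness at a grid location is the chord length of the ray from the
#' calvarial centroid through the mask: the outer 0.5-crossing of the
#' trilinearly sampled mask minus the inner crossing, in mm, with linear
#' sub-step refinement. Locations whose ray misses the mask are flagged
#' invalid.
#'
#' @param mask A labelled `calvaria_mask`.
#' @param grid A `location_grid` from [build_location_grid()].
#' @param step_mm Ray sampling step (mm).
#' @return Data frame with `location`, `thickness_mm`, `valid`.
#' @export
compute_local_thickness <- function(mask, grid, step_mm = 0.25) {
  stopifnot(inherits(mask, "calvaria_mask"), inherits(grid, "location_grid"))
  prof <- ray_profiles(array(as.numeric(mask$mask), dim(mask$mask)),
                       mask, grid$centroid, grid$directions,
                       step_mm = step_mm, outside = 0)
  cr <- ray_crossings(prof, level = 0.5)
  data.frame(location = seq_len(grid$n),
             thickness_mm = cr$r_out - cr$r_in,
             valid = !is.na(cr$r_in))
}

# Sub-step inner/outer 0.5-crossings of a sampled profile matrix.
#' @keywords internal
ray_crossings <- function(prof, level = 0.5) {
  M <- prof$values
  radii <- prof$radii
  hit <- M >= level
  first <- ray_first_hit(hit)
  last <- ray_last_hit(hit)
  ns <- length(radii)
  n <- nrow(M)
  r_in <- r_out <- rep(NA_real_, n)
  ok <- which(!is.na(first))
  for (i in ok) {
    f <- first[i]; l <- last[i]
    if (f > 1) {
      v0 <- M[i, f - 1]; v1 <- M[i, f]
      r_in[i] <- radii[f - 1] + (radii[f] - radii[f - 1]) *
        (level - v0) / (v1 - v0)
    } else r_in[i] <- radii[1]
    if (l < ns) {
      v0 <- M[i, l]; v1 <- M[i, l + 1]
      # profile descends through `level` between samples l and l+1
      r_out[i] <- radii[l] + (radii[l + 1] - radii[l]) * (v0 - level) / (v0 - v1)
    } else r_out[i] <- radii[ns]
  }
  list(r_in = r_in, r_out = r_out, first = first, last = last)
}

#' Local cranial bone density along centroid rays
#'
#' Density at a location is a robust mean of nearest-voxel HU samples along
#' the interior of the chord(s) through the mask around that direction.
#' Three choices control partial-volume contamination:
#' * nearest-voxel lookup — no interpolation across the anisotropic slice
#'   direction;
#' * an interior margin per chord end (a fixed allowance plus half the voxel
#'   extent along the ray) that trims the boundary layers;
#' * a one-sided trim of the lowest `trim_frac` of samples, since blur and
#'   residual boundary contamination only pull bone HU downward.
#' A small cluster of sub-rays (`n_subrays`, tilted by `subray_angle_deg`)
#' is pooled per location to average out image noise. A chord too thin for
#' any interior sample falls back to the sample at the chord midpoint.
#'
#' @param vol The HU `calvarisk_volume` the mask was computed from.
#' @param mask A labelled `calvaria_mask`.
#' @param grid A `location_grid`.
#' @param step_mm Ray sampling step (mm).
#' @param margin_mm Fixed part of the chord trim at each surface (mm).
#' @param trim_frac Fraction of lowest samples discarded per location.
#' @param n_subrays Rays pooled per location (1, or 5 = centre + 4 tilts).
#' @param subray_angle_deg Tilt of the 4 auxiliary rays.
#' @return Data frame with `location`, `density_hu`, `valid`.
#' @export
compute_local_density <- function(vol, mask, grid, step_mm = 0.25,
                                  margin_mm = 0.35, trim_frac = 0.25,
                                  n_subrays = 5L, subray_angle_deg = 0.9) {
  stopifnot(inherits(vol, "calvarisk_volume"),
            inherits(mask, "calvaria_mask"), inherits(grid, "location_grid"))
  stopifnot(n_subrays %in% c(1L, 5L))
  dirs <- grid$directions
  n <- grid$n
  if (n_subrays == 5L) {
    # orthonormal tangent pair per direction
    up <- matrix(rep(c(0, 0, 1), each = n), n, 3)
    flip <- abs(dirs[, 3]) > 0.9
    up[flip, ] <- matrix(rep(c(0, 1, 0), each = sum(flip)), sum(flip), 3)
    t1 <- cross3(up, dirs)
    t1 <- t1 / sqrt(rowSums(t1^2))
    t2 <- cross3(dirs, t1)
    eps <- tan(subray_angle_deg * pi / 180)
    alldirs <- rbind(dirs, dirs + eps * t1, dirs - eps * t1,
                     dirs + eps * t2, dirs - eps * t2)
    alldirs <- alldirs / sqrt(rowSums(alldirs^2))
  } else {
    alldirs <- dirs
  }
  mprof <- ray_profiles(array(as.numeric(mask$mask), dim(mask$mask)),
                        mask, grid$centroid, alldirs,
                        step_mm = step_mm, outside = 0)
  vprof <- ray_profiles(vol$values, mask, grid$centroid, alldirs,
                        step_mm = step_mm, outside = -1000,
                        interp = "nearest")
  cr <- ray_crossings(mprof, level = 0.5)
  radii <- mprof$radii
  extent <- abs(alldirs) %*% mask$spacing  # voxel extent along each ray (mm)
  dens <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rays <- seq(i, nrow(alldirs), by = n)
    samples <- numeric(0)
    for (j in rays) {
      if (is.na(cr$r_in[j])) next
      m <- margin_mm + extent[j] / 2
      use <- radii >= cr$r_in[j] + m & radii <= cr$r_out[j] - m &
        mprof$values[j, ] >= 0.5
      if (!any(use))
        use <- which.min(abs(radii - (cr$r_in[j] + cr$r_out[j]) / 2))
      samples <- c(samples, vprof$values[j, use])
    }
    if (!length(samples)) next
    if (trim_frac > 0 && length(samples) > 2) {
      k <- ceiling(trim_frac * length(samples))
      samples <- sort(samples)[-seq_len(k)]
    }
    dens[i] <- mean(samples)
  }
  data.frame(location = seq_len(n), density_hu = dens, valid = !is.na(dens))
}

#' @keywords internal
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Per-location thickness and density maps
#'
#' Convenience wrapper combining [compute_local_thickness()] and
#' [compute_local_density()] into the standardized per-location table.
#'
#' @inheritParams compute_local_density
#' @return Data frame: `location`, `azimuth`, `elevation`, `bone`,
#'   `thickness_mm`, `density_hu`, `valid` (both measures available).
#' @export
compute_calvaria_maps <- function(vol, mask, grid, step_mm = 0.25) {
  th <- compute_local_thickness(mask, grid, step_mm = step_mm)
  de <- compute_local_density(vol, mask, grid, step_mm = step_mm)
  data.frame(location = seq_len(grid$n), azimuth = grid$azimuth,
             elevation = grid$elevation, bone = grid$bone,
             thickness_mm = th$thickness_mm, density_hu = de$density_hu,
             valid = th$valid & de$valid)
}

#' Per-bone and global summaries of calvaria maps
#'
#' Mean thickness and density per bone region — frontal, parietal (left and
#' right merged) and occipital — plus the global calvarial mean over all
#' valid non-suture locations. For unicoronal cases, supplying
#' `ucc_fused_side` additionally reports frontal and parietal means on the
#' fused and open sides separately.
#'
#' @param maps Data frame from [compute_calvaria_maps()].
#' @param ucc_fused_side Optional `"left"` or `"right"`.
#' @return Data frame: `region`, `n_locations`, `thickness_mm`,
#'   `density_hu`. Regions with no valid location yield `NA`.
#' @export
summarize_bones <- function(maps, ucc_fused_side = NULL) {
  ok <- maps$valid & maps$bone %in% bone_levels()
  m <- maps[ok, , drop = FALSE]
  side <- ifelse(grepl("_L$", m$bone), "left",
                 ifelse(grepl("_R$", m$bone), "right", "none"))
  base <- sub("_[LR]$", "", m$bone)
  summ <- function(sel, region) {
    data.frame(region = region, n_locations = sum(sel),
               thickness_mm = if (any(sel)) mean(m$thickness_mm[sel]) else NA_real_,
               density_hu = if (any(sel)) mean(m$density_hu[sel]) else NA_real_)
  }
  out <- rbind(
    summ(base == "frontal", "frontal"),
    summ(base == "parietal", "parietal"),
    summ(base == "occipital", "occipital"),
    summ(rep(TRUE, nrow(m)), "global")
  )
  if (!is.null(ucc_fused_side)) {
    ucc_fused_side <- match.arg(ucc_fused_side, c("left", "right"))
    open_side <- setdiff(c("left", "right"), ucc_fused_side)
    out <- rbind(
      out,
      summ(base == "frontal" & side == ucc_fused_side, "frontal_fused_side"),
      summ(base == "frontal" & side == open_side, "frontal_open_side"),
      summ(base == "parietal" & side == ucc_fused_side, "parietal_fused_side"),
      summ(base == "parietal" & side == open_side, "parietal_open_side")
    )
  }
  rownames(out) <- NULL
  out
}

#' Quantify one volume end to end
#'
#' Segment, label, build the standard grid and return maps plus summaries.
#'
#' @param vol A `calvarisk_volume` (already resampled if desired).
#' @param hu_threshold Bone threshold (HU).
#' @param n_locations Grid size.
#' @param suture_bands Canonical suture layout.
#' @param ucc_fused_side Optional side-resolved summary (see
#'   [summarize_bones()]).
#' @return List with `mask`, `grid`, `maps`, `summary`.
#' @export
quantify_volume <- function(vol, hu_threshold = 150, n_locations = 2562L,
                            suture_bands = default_suture_bands(),
                            ucc_fused_side = NULL) {
  mask <- segment_calvaria(vol, hu_threshold = hu_threshold)
  mask <- label_bones(mask, suture_bands = suture_bands)
  grid <- build_location_grid(mask, n_locations = n_locations)
  maps <- compute_calvaria_maps(vol, mask, grid)
  list(mask = mask, grid = grid, maps = maps,
       summary = summarize_bones(maps, ucc_fused_side = ucc_fused_side))
}
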