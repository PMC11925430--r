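#' Calvaria mask container
#'
#' Binary bone mask aligned to a volume, with optional per-voxel bone labels
#' (integer codes into `levels`: none, the five bones, suture).
#' @keywords internal
new_calvaria_mask <- function(mask, vol, bone_labels = NULL) {
  levels <- c("none", bone_levels(), "suture")
  if (is.null(bone_labels)) bone_labels <- array(1L, dim(mask))
  structure(
    list(mask = mask, bone_labels = bone_labels, levels = levels,
         spacing = vol$spacing, origin = vol$origin,
         orientation = vol$orientation),
    class = "calvaria_mask"
  )
}

#' @export
print.calvaria_mask <- function(x, ...) {
  cat("<calvaria_mask> ", sum(x$mask), " bone voxels of ",
      length(x$mask), "\n", sep = "")
  invisible(x)
}

#' Segment the calvaria by thresholding
#'
#' Classical bone segmentation for phantom-grade volumes: voxels at or above
#' `hu_threshold` HU, morphologically closed (which bridges suture gaps so
#' the calvarial bones form one object), then restricted to the largest
#' 6-connected component. Deterministic. The default closing depth is
#' chosen to bridge gaps up to `2 * close_mm` wide; components further
#' apart than that stay separate and only the largest survives.
#'
#' @param vol A `calvarisk_volume` in HU.
#' @param hu_threshold Bone threshold in HU (default 150).
#' @param close_mm Closing depth in mm per side (6-neighbourhood cross,
#'   `ceiling(close_mm / min(spacing))` iterations); 0 disables closing.
#' @return A `calvaria_mask`.
#' @export
segment_calvaria <- function(vol, hu_threshold = 150, close_mm = 1.25) {
  stopifnot(inherits(vol, "calvarisk_volume"))
  m <- vol$values >= hu_threshold
  if (!any(m)) stop("no bone found: no voxel reaches ", hu_threshold, " HU",
                    call. = FALSE)
  if (close_mm > 0) {
    iter <- as.integer(ceiling(close_mm / min(vol$spacing)))
    m <- array(.binary_close3d(m, dim(m), iter), dim(m))
  }
  lab <- .cc_label3d(m, dim(m))
  tab <- tabulate(lab[lab > 0L])
  m <- array(lab == which.max(tab), dim(m))
  new_calvaria_mask(m, vol)
}

# Physical centroid of the mask in the canonical frame.
#' @keywords internal
mask_centroid <- function(mask) {
  d <- dim(mask$mask)
  idx <- which(mask$mask) - 1L
  x <- idx %% d[1]
  y <- (idx %/% d[1]) %% d[2]
  z <- idx %/% (d[1] * d[2])
  phys <- cbind(mask$origin[1] + x * mask$spacing[1],
                mask$origin[2] + y * mask$spacing[2],
                mask$origin[3] + z * mask$spacing[3])
  colMeans(phys %*% t(mask$orientation))
}

#' Label the five cranial bones on a calvaria mask
#'
#' Every mask voxel gets exactly one of the five bone labels, assigned by
#' the angular sector of its direction from the calvarial centroid in the
#' canonical frame; voxels inside the canonical suture bands are labelled
#' `suture` and excluded from bone summaries.
#'
#' @param mask A `calvaria_mask` (nonempty).
#' @param suture_bands Layout from [default_suture_bands()].
#' @return The mask with `bone_labels` filled in.
#' @export
label_bones <- function(mask, suture_bands = default_suture_bands()) {
  stopifnot(inherits(mask, "calvaria_mask"))
  if (!any(mask$mask)) stop("mask is empty", call. = FALSE)
  if (is.null(mask$orientation))
    stop("mask has no orientation metadata", call. = FALSE)
  d <- dim(mask$mask)
  sel <- which(mask$mask)
  idx <- sel - 1L
  x <- idx %% d[1]
  y <- (idx %/% d[1]) %% d[2]
  z <- idx %/% (d[1] * d[2])
  phys <- cbind(mask$origin[1] + x * mask$spacing[1],
                mask$origin[2] + y * mask$spacing[2],
                mask$origin[3] + z * mask$spacing[3])
  canon <- phys %*% t(mask$orientation)
  ctr <- colMeans(canon)
  off <- sweep(canon, 2, ctr)
  r <- sqrt(rowSums(off^2))
  r[r == 0] <- 1e-9
  lab <- classify_direction(off / r, radius_mm = r, bands = suture_bands)
  codes <- match(lab, mask$levels)
  bl <- array(1L, d)
  bl[sel] <- codes
  mask$bone_labels <- bl
  mask$centroid <- ctr
  mask$rmax <- max(r)  # radial extent: lets ray sampling stop early
  mask
}

#' Standardized per-location direction grid
#'
#' A deterministic icosphere grid of surface directions from the calvarial
#' centroid, identical for every subject: this shared grid *is* the
#' cross-subject correspondence. Each location carries the label of the
#' first labelled bone voxel hit along its ray.
#'
#' @param mask A labelled `calvaria_mask` (see [label_bones()]).
#' @param n_locations Number of grid locations (default 2562, icosphere
#'   level 4).
#' @param step_mm Ray sampling step.
#' @return A `location_grid` list: `directions` (canonical unit vectors),
#'   `azimuth`, `elevation`, `bone`, `centroid`, `n`.
#' @export
build_location_grid <- function(mask, n_locations = 2562L, step_mm = 0.5) {
  stopifnot(inherits(mask, "calvaria_mask"))
  dirs <- icosphere_directions(icosphere_level_for(n_locations))
  dirs <- dirs[seq_len(n_locations), , drop = FALSE]
  ctr <- if (!is.null(mask$centroid)) mask$centroid else mask_centroid(mask)
  ang <- direction_angles(dirs)
  prof <- ray_profiles(array(as.numeric(mask$mask), dim(mask$mask)),
                       mask, ctr, dirs, step_mm = step_mm, outside = 0)
  cr <- ray_crossings(prof, level = 0.5)
  bone <- rep("none", n_locations)
  ok <- !is.na(cr$r_in)
  if (any(ok)) {
    # label of the nearest voxel at the chord midpoint (robust to boundary
    # rounding at the crossings)
    ri <- (cr$r_in[ok] + cr$r_out[ok]) / 2
    p <- sweep(dirs[ok, , drop = FALSE] * ri, 2, ctr, "+")
    bone[ok] <- nearest_label(mask, p)
  }
  structure(
    list(directions = dirs, azimuth = ang$azimuth, elevation = ang$elevation,
         bone = bone, centroid = ctr, n = n_locations),
    class = "location_grid"
  )
}

# Mask-frame nearest-voxel label lookup for canonical points.
#' @keywords internal
nearest_label <- function(mask, pts_canon) {
  phys <- pts_canon %*% mask$orientation  # inverse of the canonical mapping
  d <- dim(mask$mask)
  i <- pmin(pmax(round((phys[, 1] - mask$origin[1]) / mask$spacing[1]), 0), d[1] - 1)
  j <- pmin(pmax(round((phys[, 2] - mask$origin[2]) / mask$spacing[2]), 0), d[2] - 1)
  k <- pmin(pmax(round((phys[, 3] - mask$origin[3]) / mask$spacing[3]), 0), d[3] - 1)
  codes <- mask$bone_labels[1 + i + d[1] * (j + d[2] * k)]
  mask$levels[codes]
}

# Sample an array along centroid rays for all grid directions at once.
# Returns a list(values = n_dirs x n_samples matrix, radii).
#' @keywords internal
ray_profiles <- function(values, geom, centroid, dirs, step_mm = 0.25,
                         outside = -1000, rmax = NULL,
                         interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  d <- dim(values)
  if (is.null(rmax)) {
    rmax <- if (!is.null(geom$rmax)) {
      # mask radial extent plus one voxel diagonal of slack
      geom$rmax + sqrt(sum(geom$spacing^2))
    } else {
      ext <- (d - 1) * geom$spacing
      sqrt(sum(ext^2))  # full diagonal: rays cannot escape unnoticed
    }
  }
  radii <- seq(step_mm, rmax, by = step_mm)
  nl <- nrow(dirs); ns <- length(radii)
  # canonical-frame points, mapped back into the voxel frame
  px <- outer(dirs[, 1], radii) + centroid[1]
  py <- outer(dirs[, 2], radii) + centroid[2]
  pz <- outer(dirs[, 3], radii) + centroid[3]
  canon <- cbind(as.vector(px), as.vector(py), as.vector(pz))
  phys <- canon %*% geom$orientation
  v <- if (interp == "linear")
    interp3(values, geom$spacing, geom$origin, phys, outside = outside)
  else
    nearest3(values, geom$spacing, geom$origin, phys, outside = outside)
  list(values = matrix(v, nl, ns), radii = radii)
}

#' @keywords internal
ray_first_hit <- function(hit) {
  apply(hit, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
}

#' @keywords internal
ray_last_hit <- function(hit) {
  apply(hit, 1, function(z) if (any(z)) max(which(z)) else NA_integer_)
}
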