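#' Icosphere direction grid
#'
#' Generates the vertices of a geodesic sphere obtained by repeated 4-fold
#' subdivision of a regular icosahedron. Vertex counts per level are
#' 12, 42, 162, 642, 2562, ... (`10 * 4^level + 2`). The vertex order is
#' deterministic, so the grid provides a fixed cross-subject correspondence.
#'
#' @param level Non-negative integer subdivision level.
#' @return A numeric matrix with one unit row-vector per direction.
#' @export
icosphere_directions <- function(level = 4L) {
  stopifnot(level >= 0, level <= 6)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (lev in seq_len(level)) {
    midpoint_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    new_v <- vector("list", 0L)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- midpoint_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      new_v[[length(new_v) + 1L]] <<- m
      idx <- nv + length(new_v)
      midpoint_cache[[key]] <- idx
      idx
    }
    new_f <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      new_f[4 * t - 3, ] <- c(a, ab, ca)
      new_f[4 * t - 2, ] <- c(b, bc, ab)
      new_f[4 * t - 1, ] <- c(c, ca, bc)
      new_f[4 * t, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, new_v))
    f <- new_f
  }
  unname(v)
}

#' Convert unit directions to azimuth/elevation angles
#'
#' The canonical frame is x = subject left, y = anterior, z = superior.
#' Azimuth is measured in degrees from the anterior direction (0 = front,
#' positive toward the left, +/-180 = back); elevation in degrees from the
#' axial plane (90 = vertex).
#'
#' @param dirs Matrix of unit row-vectors.
#' @return A data.frame with columns `azimuth` and `elevation` (degrees).
#' @export
direction_angles <- function(dirs) {
  dirs <- rbind(dirs)
  data.frame(
    azimuth = atan2(dirs[, 1], dirs[, 2]) * 180 / pi,
    elevation = asin(pmin(1, pmax(-1, dirs[, 3]))) * 180 / pi
  )
}

#' Canonical suture band layout
#'
#' Great-arc bands at fixed canonical positions: a coronal pair (between
#' frontal and parietal sectors), a lambdoid pair (between parietal and
#' occipital sectors) and a sagittal/metopic midline band over the vertex.
#'
#' @param width_mm Band width in mm on the outer surface.
#' @param gap_hu HU of the soft tissue filling the gap (phantoms only).
#' @return List describing the bands.
#' @export
default_suture_bands <- function(width_mm = 2, gap_hu = 50) {
  stopifnot(width_mm >= 0)
  list(width_mm = width_mm, gap_hu = gap_hu,
       coronal_deg = 45, lambdoid_deg = 135, midline_min_elev_deg = 15)
}

#' Bone/suture label of calvarial surface directions
#'
#' Assigns each direction one of the five bone labels
#' (`frontal_L`, `frontal_R`, `parietal_L`, `parietal_R`, `occipital`) by
#' angular sector, or `suture` inside a canonical suture band. Band angular
#' width at a direction is `width_mm / radius_mm` (small-angle chord), so the
#' same physical width is used regardless of head size.
#'
#' @param dirs Matrix of unit row-vectors in the canonical frame.
#' @param radius_mm Surface radius (mm) at each direction; scalar or vector.
#' @param bands Suture layout from [default_suture_bands()]; `NULL` for no
#'   suture bands.
#' @return Character vector of labels.
#' @export
classify_direction <- function(dirs, radius_mm = 75, bands = default_suture_bands()) {
  dirs <- rbind(dirs)
  ang <- direction_angles(dirs)
  az <- ang$azimuth; el <- ang$elevation
  left <- dirs[, 1] >= 0
  lab <- character(nrow(dirs))
  frontal <- abs(az) < 45
  occip <- abs(az) >= 135
  parietal <- !frontal & !occip
  lab[frontal & left] <- "frontal_L"
  lab[frontal & !left] <- "frontal_R"
  lab[parietal & left] <- "parietal_L"
  lab[parietal & !left] <- "parietal_R"
  lab[occip] <- "occipital"
  if (!is.null(bands) && bands$width_mm > 0) {
    half_deg <- (bands$width_mm / 2) / radius_mm * 180 / pi
    midline_deg <- asin(pmin(1, abs(dirs[, 1]))) * 180 / pi
    # midline band: sagittal suture over the vertex plus the metopic suture
    # through the frontal sector (separates frontal_L from frontal_R)
    sut <- (abs(abs(az) - bands$coronal_deg) < half_deg) |
      (abs(abs(az) - bands$lambdoid_deg) < half_deg) |
      (midline_deg < half_deg &
         (el > bands$midline_min_elev_deg | abs(az) < bands$coronal_deg))
    lab[sut] <- "suture"
  }
  lab
}

#' @keywords internal
bone_levels <- function() {
  c("frontal_L", "frontal_R", "parietal_L", "parietal_R", "occipital")
}

# Trilinear interpolation of a 3-D array at arbitrary physical points.
# `pts` are physical coordinates (mm) in the array's own (voxel) frame;
# voxel centres sit at origin + (index - 1) * spacing. Points outside the
# grid get `outside`.
#' @keywords internal
interp3 <- function(values, spacing, origin, pts, outside = -1000) {
  d <- dim(values)
  ix <- (pts[, 1] - origin[1]) / spacing[1]
  iy <- (pts[, 2] - origin[2]) / spacing[2]
  iz <- (pts[, 3] - origin[3]) / spacing[3]
  inside <- ix >= 0 & ix <= d[1] - 1 & iy >= 0 & iy <= d[2] - 1 &
    iz >= 0 & iz <= d[3] - 1
  x0 <- pmin(pmax(floor(ix), 0), d[1] - 2)
  y0 <- pmin(pmax(floor(iy), 0), d[2] - 2)
  z0 <- pmin(pmax(floor(iz), 0), d[3] - 2)
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  base <- function(xx, yy, zz) values[1 + xx + d[1] * (yy + d[2] * zz)]
  v <- base(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    base(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    base(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
    base(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
    base(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
    base(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
    base(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
    base(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  v[!inside] <- outside
  v
}

# Nearest-neighbour lookup companion to interp3: returns the value of the
# voxel whose centre is closest to each point (no cross-voxel mixing).
#' @keywords internal
nearest3 <- function(values, spacing, origin, pts, outside = -1000) {
  d <- dim(values)
  i <- round((pts[, 1] - origin[1]) / spacing[1])
  j <- round((pts[, 2] - origin[2]) / spacing[2])
  k <- round((pts[, 3] - origin[3]) / spacing[3])
  inside <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 &
    k >= 0 & k <= d[3] - 1
  i <- pmin(pmax(i, 0), d[1] - 1)
  j <- pmin(pmax(j, 0), d[2] - 1)
  k <- pmin(pmax(k, 0), d[3] - 1)
  v <- values[1 + i + d[1] * (j + d[2] * k)]
  v[!inside] <- outside
  v
}

# Separable Gaussian blur with edge clamping; fwhm in mm, per-axis sigma
# converted to voxels through the spacing. Normalised weights guarantee the
# output range never exceeds the input range.
#' @keywords internal
gaussian_blur3 <- function(values, spacing, fwhm) {
  if (fwhm <= 0) return(values)
  sig <- fwhm / (2 * sqrt(2 * log(2))) / spacing
  for (axis in 1:3) {
    s <- sig[axis]
    r <- ceiling(3 * s)
    if (r < 1) next
    w <- dnorm(seq(-r, r), sd = s)
    w <- w / sum(w)
    n <- dim(values)[axis]
    out <- array(0, dim(values))
    for (k in seq(-r, r)) {
      idx <- pmin(pmax(seq_len(n) + k, 1L), n)
      shifted <- switch(axis,
        values[idx, , , drop = FALSE],
        values[, idx, , drop = FALSE],
        values[, , idx, drop = FALSE]
      )
      out <- out + w[k + r + 1] * shifted
    }
    values <- out
  }
  values
}
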