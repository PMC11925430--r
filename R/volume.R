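#' CT-like volume container
#'
#' A light S3 container for a 3-D scalar grid in Hounsfield units with its
#' geometry: voxel `spacing` (mm; in-plane x, in-plane y, slice), `origin`
#' (mm, physical position of the first voxel centre) and an `orientation`
#' matrix mapping physical voxel-frame offsets to the canonical patient frame
#' (x left, y anterior, z superior).
#'
#' @param values 3-D numeric array of HU values.
#' @param spacing Positive mm triple.
#' @param origin mm triple, default zeros.
#' @param orientation 3x3 rotation matrix, default identity.
#' @return An object of class `calvarisk_volume`.
#' @export
new_volume <- function(values, spacing, origin = c(0, 0, 0),
                       orientation = diag(3)) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive finite values",
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("volume values must be finite", call. = FALSE)
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin),
         orientation = orientation),
    class = "calvarisk_volume"
  )
}

#' @export
print.calvarisk_volume <- function(x, ...) {
  cat("<calvarisk_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm, HU range [", round(min(x$values)), ", ", round(max(x$values)),
      "]\n", sep = "")
  invisible(x)
}

#' Voxel volume of a grid (mm^3)
#' @param vol A `calvarisk_volume`.
#' @return Product of the spacings, in mm^3.
#' @export
voxel_volume <- function(vol) prod(vol$spacing)

#' Read a CT-like volume from NIfTI or NRRD
#'
#' Format is chosen by extension: `.nii` / `.nii.gz` (NIfTI-1 via RNifti) or
#' `.nrrd`. Spacing is always taken from the file header and validated.
#'
#' @param path File path.
#' @return A `calvarisk_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    vals <- array(as.numeric(img), dim = dim(img))
    sp <- RNifti::pixdim(img)[1:3]
    new_volume(vals, spacing = sp)
  } else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    read_nrrd(path)
  } else {
    stop("unsupported volume format (expected NIfTI .nii/.nii.gz or NRRD ",
         ".nrrd): ", path, call. = FALSE)
  }
}

#' Write a CT-like volume to NIfTI or NRRD
#'
#' @param vol A `calvarisk_volume`.
#' @param path Destination path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "calvarisk_volume"))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(vol$values)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd(vol, path)
  } else {
    stop("unsupported volume format (expected NIfTI .nii/.nii.gz or NRRD ",
         ".nrrd): ", path, call. = FALSE)
  }
  invisible(path)
}

#' Resolution-based exclusion filter
#'
#' Splits volumes into those meeting the acquisition-resolution requirement
#' (in-plane resolution at most `max_inplane` mm and slice thickness at most
#' `max_slice` mm, boundary inclusive) and those excluded. The defaults are
#' the standard 0.5 mm / 1.5 mm inclusion rule for partial-volume control.
#'
#' @param vols List of `calvarisk_volume` objects.
#' @param max_inplane,max_slice Inclusive upper bounds in mm.
#' @return List with elements `kept` and `excluded` (lists of volumes) and
#'   `kept_idx` (integer indices into `vols`).
#' @export
filter_by_resolution <- function(vols, max_inplane = 0.5, max_slice = 1.5) {
  ok <- vapply(vols, function(v) {
    max(v$spacing[1:2]) <= max_inplane && v$spacing[3] <= max_slice
  }, logical(1))
  list(kept = vols[ok], excluded = vols[!ok], kept_idx = which(ok))
}

#' Resample a volume to a target spacing by trilinear interpolation
#'
#' The output grid starts at the input origin and spans the same physical
#' extent (within one voxel). Sample points outside the input grid are filled
#' with `outside` (air, -1000 HU, by CT convention).
#'
#' @param vol A `calvarisk_volume`.
#' @param target_spacing mm triple, default the uniform 0.5/0.5/1.5 mm grid.
#' @param outside Fill value for out-of-grid samples.
#' @return A resampled `calvarisk_volume`.
#' @export
resample_volume <- function(vol, target_spacing = c(0.5, 0.5, 1.5),
                            outside = -1000) {
  stopifnot(inherits(vol, "calvarisk_volume"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0))
    stop("target spacing must be three positive values", call. = FALSE)
  d <- dim(vol$values)
  if (any(d < 2L))
    stop("cannot resample a degenerate volume (a dimension has < 2 samples)",
         call. = FALSE)
  extent <- (d - 1) * vol$spacing
  nd <- pmax(2L, as.integer(floor(extent / target_spacing + 1e-9)) + 1L)
  xs <- vol$origin[1] + (seq_len(nd[1]) - 1) * target_spacing[1]
  ys <- vol$origin[2] + (seq_len(nd[2]) - 1) * target_spacing[2]
  zs <- vol$origin[3] + (seq_len(nd[3]) - 1) * target_spacing[3]
  out <- array(0, nd)
  grid_xy <- cbind(rep(xs, times = nd[2]), rep(ys, each = nd[1]))
  for (k in seq_len(nd[3])) {  # slice-wise to bound memory
    pts <- cbind(grid_xy, zs[k])
    out[, , k] <- interp3(vol$values, vol$spacing, vol$origin, pts,
                          outside = outside)
  }
  new_volume(out, spacing = target_spacing, origin = vol$origin,
             orientation = vol$orientation)
}
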