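#' Volume: a 3D scalar field with physical spacing
#'
#' The basic container for images, probability maps and label volumes. Voxels
#' are stored in axis order (z, y, x) with 1-based indices; `spacing` gives
#' mm per voxel along (z, y, x) and `origin` the physical coordinate (mm) of
#' voxel (1,1,1).
#'
#' @param voxels 3D numeric (or integer) array, axis order (z, y, x).
#' @param spacing numeric length-3, mm per voxel along (z, y, x); all > 0.
#' @param origin numeric length-3, physical position of the first voxel (mm).
#' @return an object of class `dent_volume`.
#' @export
volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) stopf("volume(): voxels must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stopf("volume(): spacing must be 3 positive numbers")
  structure(list(voxels = voxels, spacing = spacing, origin = as.numeric(origin)),
            class = "dent_volume")
}

#' @export
print.dent_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<dent_volume %d x %d x %d (z,y,x), spacing %.3g x %.3g x %.3g mm, range [%.4g, %.4g]>\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.dent_volume <- function(x) dim(x$voxels)

is_volume <- function(x) inherits(x, "dent_volume")

#' Read a 3D NIfTI file as a Volume
#'
#' Header pixel dimensions and the qform/sform translation are mapped into the
#' internal (z, y, x) axis order.
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @return a [volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("read_volume(): file not found: %s", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stopf("read_volume(): expected a 3D image, got %dD", length(dim(img)))
  sp <- RNifti::pixdim(img)            # (x, y, z)
  xf <- try(RNifti::xform(img), silent = TRUE)
  orig <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  arr <- aperm(as.array(img), c(3, 2, 1))
  volume(arr, spacing = rev(sp[1:3]), origin = rev(orig))
}

#' Write a Volume to a NIfTI file
#'
#' @param v a [volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type; label volumes should use an integer
#'   type (e.g. `"uint16"`), images the default `"double"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, datatype = "double") {
  stopifnot(is_volume(v))
  arr <- aperm(v$voxels, c(3, 2, 1))   # back to (x, y, z)
  sp <- rev(v$spacing)
  org <- rev(v$origin)
  xf <- diag(4)
  xf[1, 1] <- sp[1]; xf[2, 2] <- sp[2]; xf[3, 3] <- sp[3]
  xf[1:3, 4] <- org
  img <- RNifti::asNifti(arr)
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Clip and normalize intensities
#'
#' Clamps to `[lo, hi]` and rescales linearly to `[0, 1]`, the standard CBCT
#' preprocessing (default window 0–2500 suppresses extreme values around metal
#' artifacts).
#'
#' @param v a [volume()].
#' @param lo,hi clipping window; `hi > lo`.
#' @return a [volume()] with all values in `[0, 1]`.
#' @export
clip_normalize <- function(v, lo = 0, hi = 2500) {
  stopifnot(is_volume(v))
  if (hi <= lo) stopf("clip_normalize(): hi must exceed lo")
  out <- (pmin(pmax(v$voxels, lo), hi) - lo) / (hi - lo)
  volume(out, v$spacing, v$origin)
}

#' Resample a Volume to isotropic spacing
#'
#' Output shape per axis is `round(shape * spacing / target_mm)`; intensities
#' are interpolated trilinearly, label volumes with `mode = "nearest"`. The
#' default 0.4 mm matches the pipeline's working resolution.
#'
#' @param v a [volume()].
#' @param target_mm positive scalar target spacing (mm).
#' @param mode `"linear"` (images) or `"nearest"` (labels).
#' @return a [volume()] with spacing `(target_mm, target_mm, target_mm)`.
#' @export
resample_isotropic <- function(v, target_mm = 0.4, mode = c("linear", "nearest")) {
  stopifnot(is_volume(v))
  mode <- match.arg(mode)
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stopf("resample_isotropic(): target_mm must be a positive scalar")
  d <- dim(v$voxels)
  nd <- pmax(1L, as.integer(round(d * v$spacing / target_mm)))
  # source (1-based, fractional) index of each output voxel, axis-wise
  src <- lapply(1:3, function(ax) (seq_len(nd[ax]) - 1) * target_mm / v$spacing[ax] + 1)
  if (mode == "nearest") {
    idx <- lapply(1:3, function(ax) clampi(as.integer(round(src[[ax]])), 1L, d[ax]))
    out <- v$voxels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    lo <- lapply(1:3, function(ax) clampi(floor(src[[ax]]), 1, d[ax]))
    hi <- lapply(1:3, function(ax) clampi(lo[[ax]] + 1, 1, d[ax]))
    fr <- lapply(1:3, function(ax) clampi(src[[ax]] - lo[[ax]], 0, 1))
    out <- array(0, nd)
    for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
      iz <- if (cz == 0) lo[[1]] else hi[[1]]
      iy <- if (cy == 0) lo[[2]] else hi[[2]]
      ix <- if (cx == 0) lo[[3]] else hi[[3]]
      wz <- if (cz == 0) 1 - fr[[1]] else fr[[1]]
      wy <- if (cy == 0) 1 - fr[[2]] else fr[[2]]
      wx <- if (cx == 0) 1 - fr[[3]] else fr[[3]]
      w <- outer(outer(wz, wy), wx)
      dim(w) <- nd
      out <- out + w * v$voxels[iz, iy, ix, drop = FALSE]
    }
  }
  volume(out, rep(target_mm, 3), v$origin)
}

#' Deterministic sliding-window tiling
#'
#' Covers the full shape with half-open windows of size `patch` (clamped to
#' the shape). Stride per axis is `ceiling(patch * (1 - overlap_fraction))`;
#' the last window per axis is shifted to end exactly at the boundary.
#' Ordering is z-major (z outermost).
#'
#' @param shape integer length-3 volume shape (z, y, x).
#' @param patch integer length-3 window size.
#' @param overlap_fraction in `[0, 1)`.
#' @return list of windows, each `list(start, size)` with 1-based inclusive
#'   `start`.
#' @export
sliding_windows <- function(shape, patch, overlap_fraction = 0) {
  shape <- as.integer(shape); patch <- as.integer(patch)
  stopifnot(length(shape) == 3L, length(patch) == 3L,
            overlap_fraction >= 0, overlap_fraction < 1)
  patch <- pmin(patch, shape)
  stride <- pmax(1L, as.integer(ceiling(patch * (1 - overlap_fraction))))
  starts <- lapply(1:3, function(ax) {
    s <- seq.int(1L, max(1L, shape[ax] - patch[ax] + 1L), by = stride[ax])
    last <- shape[ax] - patch[ax] + 1L
    if (s[length(s)] != last) s <- c(s, last)
    s
  })
  out <- list()
  for (sz in starts[[1]]) for (sy in starts[[2]]) for (sx in starts[[3]])
    out[[length(out) + 1L]] <- list(start = c(sz, sy, sx), size = patch)
  out
}

# Crop a 3D array (or (C,...) 4D array) at a window.
crop_window <- function(a, win) {
  s <- win$start; e <- win$start + win$size - 1L
  if (length(dim(a)) == 3L) a[s[1]:e[1], s[2]:e[2], s[3]:e[3], drop = FALSE]
  else a[, s[1]:e[1], s[2]:e[2], s[3]:e[3], drop = FALSE]
}
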