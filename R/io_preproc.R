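#' Raw-resolution volume container
#'
#' A 3D intensity array together with its voxel spacing in millimetres.
#' The package convention is axis 1 = left-right, axis 2 = anterior-posterior,
#' axis 3 = inferior-superior, so axial slices are indexed along axis 3.
#'
#' @param data 3D numeric array with finite values.
#' @param spacing Positive length-3 numeric, mm per voxel.
#' @return An object of class `raw_volume`.
#' @export
raw_volume <- function(data, spacing = c(1, 1, 1)) {
  assert_that(is.array(data) && length(dim(data)) == 3,
              "data must be a 3D array")
  assert_that(all(is.finite(data)), "data must be finite")
  assert_that(length(spacing) == 3 && all(spacing > 0),
              "spacing must be 3 positive values")
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "raw_volume")
}

#' @export
print.raw_volume <- function(x, ...) {
  cat(sprintf("<raw_volume> %s voxels, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

as_raw_volume <- function(x) {
  if (inherits(x, "raw_volume")) return(x)
  raw_volume(x)
}

#' Read / write NIfTI volumes
#'
#' `load_volume()` reads a NIfTI file into a [raw_volume()] (spacing taken
#' from the NIfTI pixdim); `save_volume()` writes a [raw_volume()] or plain
#' array (spacing 1 mm) to `.nii` / `.nii.gz`.
#'
#' @param path File path.
#' @return `load_volume()` returns a `raw_volume`; `save_volume()` returns
#'   `path` invisibly.
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("NIfTI file not found: '%s'", path),
                 class = c("erasevae_format_error", "erasevae_error"))
  }
  img <- tryCatch(RNifti::readNifti(path), error = function(e) {
    rlang::abort(sprintf("malformed NIfTI file '%s': %s", path,
                         conditionMessage(e)),
                 class = c("erasevae_format_error", "erasevae_error"))
  })
  dat <- array(as.numeric(img), dim = dim(img))
  raw_volume(dat, spacing = RNifti::pixdim(img)[1:3])
}

#' @param vol A `raw_volume` or plain 3D array.
#' @rdname load_volume
#' @export
save_volume <- function(vol, path) {
  vol <- as_raw_volume(vol)
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample to isotropic resolution
#'
#' Separable cubic (Keys/Catmull-Rom) interpolation to `target_mm` isotropic
#' spacing, preserving the physical extent within one voxel per axis.
#'
#' @param raw A [raw_volume()].
#' @param target_mm Target isotropic spacing in mm (default 1).
#' @return A `raw_volume` at isotropic spacing.
#' @export
resample_isotropic <- function(raw, target_mm = 1) {
  raw <- as_raw_volume(raw)
  assert_that(target_mm > 0, "target_mm must be positive")
  d <- dim(raw$data)
  out <- raw$data
  for (axis in 1:3) {
    n_out <- max(1L, round(d[axis] * raw$spacing[axis] / target_mm))
    if (n_out == d[axis] && abs(raw$spacing[axis] - target_mm) < 1e-12) next
    M <- cubic_resample_matrix(d[axis], n_out)
    out <- apply_axis(out, M, axis)
  }
  raw_volume(out, spacing = rep(target_mm, 3))
}

#' Normalize in-brain intensities to \[0, 1\]
#'
#' Robust min-max normalization: intensities inside the brain mask are
#' percentile-clipped and mapped linearly to \[0, 1\]; background voxels are
#' set to exactly 0.
#'
#' @param raw A [raw_volume()] or 3D array.
#' @param mask Binary brain mask aligned to the volume.
#' @param probs Lower/upper percentile clip (default 1st and 99th).
#' @return A `raw_volume` with values in \[0, 1\].
#' @export
normalize_volume <- function(raw, mask, probs = c(0.01, 0.99)) {
  raw <- as_raw_volume(raw)
  mask <- as_binary_array(mask)
  assert_that(identical(dim(raw$data), dim(mask)),
              "volume/mask shape mismatch")
  inside <- raw$data[mask == 1]
  assert_that(length(inside) > 0, "brain mask is empty")
  lims <- stats::quantile(inside, probs, names = FALSE, type = 7)
  if (diff(lims) <= 0) {
    rlang::abort("constant image inside the brain mask",
                 class = c("erasevae_degenerate_error", "erasevae_error"))
  }
  out <- clip01((raw$data - lims[1]) / (lims[2] - lims[1])) * mask
  raw_volume(out, raw$spacing)
}

#' Crop background and zero-pad to a fixed shape
#'
#' Crops the volume to the bounding box of the brain mask and zero-pads to
#' `target_shape` with the brain bounding box centered.
#'
#' @param raw A [raw_volume()] or 3D array.
#' @param mask Binary brain mask (defines the bounding box).
#' @param target_shape Output shape (default `c(191, 158, 163)`).
#' @return A `raw_volume` of shape `target_shape`.
#' @export
crop_pad <- function(raw, mask, target_shape = c(191, 158, 163)) {
  raw <- as_raw_volume(raw)
  mask <- as_binary_array(mask)
  assert_that(identical(dim(raw$data), dim(mask)),
              "volume/mask shape mismatch")
  idx <- which(mask == 1, arr.ind = TRUE)
  assert_that(nrow(idx) > 0, "brain mask is empty")
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  bb <- hi - lo + 1
  if (any(bb > target_shape)) {
    rlang::abort(sprintf(
      "brain bounding box (%s) exceeds target shape (%s)",
      paste(bb, collapse = "x"), paste(target_shape, collapse = "x")),
      class = c("erasevae_size_error", "erasevae_error"))
  }
  cropped <- raw$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  out <- array(0, dim = target_shape)
  start <- floor((target_shape - bb) / 2) + 1
  out[start[1]:(start[1] + bb[1] - 1),
      start[2]:(start[2] + bb[2] - 1),
      start[3]:(start[3] + bb[3] - 1)] <- cropped
  raw_volume(out, raw$spacing)
}

#' Downsample to the canonical training grid
#'
#' Separable cubic interpolation to `out_shape` (default 64^3), clipping
#' intensities to \[0, 1\]. Masks should be downsampled with the same
#' transform and re-binarized (`binarize = TRUE` thresholds at 0.5).
#'
#' @param raw A [raw_volume()] or 3D array.
#' @param out_shape Output shape (default `c(64, 64, 64)`).
#' @param clip Clip the result to \[0, 1\] (default `TRUE`).
#' @param binarize Re-binarize at 0.5 after interpolation (for masks).
#' @return A 3D array of shape `out_shape`.
#' @export
downsample <- function(raw, out_shape = c(64, 64, 64), clip = TRUE,
                       binarize = FALSE) {
  raw <- as_raw_volume(raw)
  d <- dim(raw$data)
  assert_that(all(d >= out_shape),
              "input shape must be >= output shape per axis")
  out <- raw$data
  for (axis in 1:3) {
    if (out_shape[axis] == dim(out)[axis]) next
    M <- cubic_resample_matrix(dim(out)[axis], out_shape[axis])
    out <- apply_axis(out, M, axis)
  }
  if (binarize) out <- (out > 0.5) * 1 else if (clip) out <- clip01(out)
  out
}

#' Full preprocessing chain
#'
#' Resample to isotropic resolution, normalize in-brain intensities, crop and
#' pad around the brain, and downsample to the canonical grid. The mask (and
#' optional annotation) undergo the identical geometric transforms, with
#' re-binarization at 0.5 after each interpolation.
#'
#' @param raw A [raw_volume()].
#' @param mask Binary brain mask aligned to `raw`.
#' @param annotation Optional binary annotation mask.
#' @param target_mm Isotropic spacing (default 1 mm).
#' @param pad_shape Crop/pad shape (default `c(191, 158, 163)`).
#' @param out_shape Final shape (default `c(64, 64, 64)`).
#' @return List with `volume`, `mask` and (if given) `annotation`, all of
#'   shape `out_shape`.
#' @export
preprocess_volume <- function(raw, mask, annotation = NULL, target_mm = 1,
                              pad_shape = c(191, 158, 163),
                              out_shape = c(64, 64, 64)) {
  raw <- as_raw_volume(raw)
  mask_rv <- raw_volume((as_binary_array(mask)) * 1, raw$spacing)
  geom <- function(x, bin) {
    r <- resample_isotropic(x, target_mm)
    if (bin) r$data <- (r$data > 0.5) * 1
    r
  }
  r_vol <- geom(raw, FALSE)
  r_mask <- geom(mask_rv, TRUE)
  n_vol <- normalize_volume(r_vol, r_mask$data)
  c_vol <- crop_pad(n_vol, r_mask$data, pad_shape)
  c_mask <- crop_pad(r_mask, r_mask$data, pad_shape)
  out <- list(volume = downsample(c_vol, out_shape),
              mask = downsample(c_mask, out_shape, binarize = TRUE))
  if (!is.null(annotation)) {
    a_rv <- raw_volume(as_binary_array(annotation, "annotation") * 1,
                       raw$spacing)
    r_a <- geom(a_rv, TRUE)
    c_a <- crop_pad(r_a, r_mask$data, pad_shape)
    out$annotation <- downsample(c_a, out_shape, binarize = TRUE)
  }
  out
}

#' Extract / restack axial slices
#'
#' `extract_slices()` returns the ordered 2D slices of a volume along an
#' axis (default the axial axis 3); `stack_slices()` is its inverse.
#'
#' @param vol 3D array.
#' @param axis Slicing axis (1, 2 or 3; default 3 = axial).
#' @return A list of 2D matrices / a 3D array.
#' @export
extract_slices <- function(vol, axis = 3) {
  assert_that(length(dim(vol)) == 3, "vol must be a 3D array")
  assert_that(axis %in% 1:3, "axis must be 1, 2 or 3")
  lapply(seq_len(dim(vol)[axis]), function(i) {
    idx <- list(TRUE, TRUE, TRUE)
    idx[[axis]] <- i
    m <- do.call(`[`, c(list(vol), idx, list(drop = FALSE)))
    array(m, dim = dim(vol)[-axis])
  })
}

#' @param slices List of 2D matrices from `extract_slices()`.
#' @rdname extract_slices
#' @export
stack_slices <- function(slices, axis = 3) {
  assert_that(length(slices) > 0, "no slices given")
  d2 <- dim(slices[[1]])
  d <- append(d2, length(slices), after = axis - 1)
  out <- array(0, dim = d)
  for (i in seq_along(slices)) {
    idx <- list(TRUE, TRUE, TRUE)
    idx[[axis]] <- i
    out <- do.call(`[<-`, c(list(out), idx, list(slices[[i]])))
  }
  out
}
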