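#' Activity volumes and lung masks
#'
#' `lungcv` works on plain 3D arrays carrying a small amount of metadata:
#' an `activity_volume` is a numeric 3D array of activity concentration
#' (arbitrary units) with a voxel pitch in mm and a provenance tag
#' (`"phantom"` truth or `"reconstruction"`); a `lung_mask` is a logical 3D
#' array on the same grid with a `variant` tag (`"full"` or `"peeled"`).
#'
#' @param data numeric (or logical, for masks) 3D array.
#' @param pitch_mm voxel pitch in mm (isotropic).
#' @param provenance `"phantom"` or `"reconstruction"`.
#' @param variant `"full"` or `"peeled"`.
#'
#' @return An object of class `activity_volume` or `lung_mask`: the input
#'   array with `pitch_mm` and provenance/variant attributes.
#' @export
activity_volume <- function(data, pitch_mm,
                            provenance = c("phantom", "reconstruction")) {
  stopifnot(is.array(data), length(dim(data)) == 3L, is.numeric(pitch_mm),
            pitch_mm > 0)
  provenance <- match.arg(provenance)
  structure(data, pitch_mm = pitch_mm, provenance = provenance,
            class = c("activity_volume", class(data)))
}

#' @rdname activity_volume
#' @export
lung_mask <- function(data, pitch_mm, variant = c("full", "peeled")) {
  stopifnot(is.array(data), length(dim(data)) == 3L, pitch_mm > 0)
  variant <- match.arg(variant)
  storage.mode(data) <- "logical"
  structure(data, pitch_mm = pitch_mm, variant = variant,
            class = c("lung_mask", class(data)))
}

#' @rdname activity_volume
#' @param x object to query.
#' @export
voxel_pitch <- function(x) {
  p <- attr(x, "pitch_mm")
  if (is.null(p)) stop("object carries no voxel pitch", call. = FALSE)
  p
}

#' Physical volume of a mask
#'
#' @param mask a `lung_mask`.
#' @return Volume in litres.
#' @export
mask_volume_L <- function(mask) {
  sum(mask) * (voxel_pitch(mask) / 10)^3 / 1000
}

#' @export
print.activity_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<activity_volume> %d x %d x %d @ %.2f mm (%s)\n",
              d[1], d[2], d[3], voxel_pitch(x), attr(x, "provenance")))
  cat(sprintf("  range [%.4g, %.4g], total %.4g\n",
              min(x), max(x), sum(x)))
  invisible(x)
}

#' @export
print.lung_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<lung_mask:%s> %d x %d x %d @ %.2f mm, %d voxels (%.3f L)\n",
              attr(x, "variant"), d[1], d[2], d[3], voxel_pitch(x),
              sum(x), mask_volume_L(x)))
  invisible(x)
}

# strip lungcv classes but keep the data (internal)
as_plain_array <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Read and write volumes as NIfTI
#'
#' Volumes and masks are exchanged with other software as NIfTI files; the
#' affine encodes the isotropic voxel pitch. Masks are written as 0/1.
#'
#' @param x an `activity_volume` or `lung_mask`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns an
#'   `activity_volume`; `read_mask` returns a `lung_mask` (non-zero voxels).
#' @export
write_volume <- function(x, path) {
  arr <- as_plain_array(x)
  storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(voxel_pitch(x), 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  activity_volume(array(as.numeric(img), dim = dim(img)), pitch_mm = pd[1],
                  provenance = "reconstruction")
}

#' @rdname write_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  lung_mask(array(as.numeric(img) != 0, dim = dim(img)), pitch_mm = pd[1])
}
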