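#' Settings for the sliding-kernel CV analysis
#'
#' @param kernel_cm side length of the cubic kernel in cm; default 3, which
#'   corresponds to 9 x 9 x 9 = 729 voxels at a 3.3 mm reconstruction pitch.
#' @param bin_percent width of the frequency-function bins in percent CV.
#' @param min_voxels minimum number of in-lung voxels a kernel must contain
#'   for its CV to be defined (>= 2: the floor for a standard deviation).
#' @return A `cv_settings` list.
#' @export
cv_settings <- function(kernel_cm = 3, bin_percent = 1, min_voxels = 2L) {
  stopifnot(kernel_cm > 0, bin_percent > 0, min_voxels >= 2L)
  structure(list(kernel_cm = kernel_cm, bin_percent = bin_percent,
                 min_voxels = as.integer(min_voxels)),
            class = "cv_settings")
}

#' Kernel side length in voxels
#'
#' Converts the kernel side from cm to voxels at a given pitch, rounded to
#' the nearest integer and forced odd so the kernel has a centre voxel.
#'
#' @param settings a [cv_settings()].
#' @param pitch_mm voxel pitch in mm.
#' @return Odd integer kernel side in voxels.
#' @export
kernel_side_voxels <- function(settings, pitch_mm) {
  k <- round(settings$kernel_cm * 10 / pitch_mm)
  k <- as.integer(k)
  if (k %% 2L == 0L) {
    # choose the nearer odd side
    lo <- k - 1L; hi <- k + 1L
    k <- if (abs(lo * pitch_mm - settings$kernel_cm * 10) <=
             abs(hi * pitch_mm - settings$kernel_cm * 10)) lo else hi
  }
  max(1L, k)
}

#' Sliding-kernel coefficient-of-variance matrix
#'
#' Steps a cubic kernel voxel-by-voxel through the volume and, at every
#' voxel of the centre mask, computes the coefficient of variance
#' `CV = 100 * SD / mean` (sample SD, n-1 denominator) over the in-lung
#' voxels inside the kernel centred there. Voxels outside the lung are
#' excluded from the statistics. A centre is invalid when its kernel holds
#' fewer than `min_voxels` in-lung voxels or a non-positive mean.
#'
#' Edge peeling shrinks the analysis volume itself: both the kernel centres
#' and the voxels entering the local statistics are drawn from the peeled
#' lung, which keeps the blurred lung edge out of the CV distribution
#' entirely. Pass a different `centres` mask to restrict only where CV
#' values are stored while sampling statistics from `mask`.
#'
#' @param vol an [activity_volume()] (typically a filtered reconstruction).
#' @param mask the analysis [lung_mask()] (typically peeled) defining which
#'   voxels enter the kernel statistics; same grid as `vol`.
#' @param settings a [cv_settings()].
#' @param centres optional [lung_mask()] of allowed kernel centres;
#'   defaults to `mask`.
#' @return A `cv_matrix`: list with `values` (3D array, percent CV at valid
#'   centres, `NA` elsewhere), `valid` (logical array), `settings`,
#'   `kernel_voxels` (side in voxels) and `pitch_mm`.
#' @export
cv_kernel <- function(vol, mask, settings = cv_settings(), centres = mask) {
  stopifnot(inherits(vol, "activity_volume"), inherits(mask, "lung_mask"),
            all(dim(vol) == dim(mask)), all(dim(centres) == dim(mask)))
  k <- kernel_side_voxels(settings, voxel_pitch(vol))
  if (any(k > dim(vol))) stop("kernel larger than the volume", call. = FALSE)
  m <- as_plain_array(mask)
  ctr <- as_plain_array(centres)
  v <- as_plain_array(vol)
  vm <- v * m
  n_in <- box_sum_3d(m + 0, k)
  s1 <- box_sum_3d(vm, k)
  s2 <- box_sum_3d(vm * vm, k)
  mean_in <- s1 / pmax(n_in, 1)
  var_in <- (s2 - n_in * mean_in^2) / pmax(n_in - 1, 1)
  var_in[var_in < 0] <- 0                      # numerical guard
  valid <- ctr & n_in >= settings$min_voxels & mean_in > 0
  values <- array(NA_real_, dim = dim(v))
  values[valid] <- 100 * sqrt(var_in[valid]) / mean_in[valid]
  structure(list(values = values, valid = valid, settings = settings,
                 kernel_voxels = k, pitch_mm = voxel_pitch(vol)),
            class = "cv_matrix")
}

#' @export
print.cv_matrix <- function(x, ...) {
  vals <- x$values[x$valid]
  cat(sprintf(
    "<cv_matrix> kernel %d^3 voxels, %d valid centres, CV %.1f-%.1f%%\n",
    x$kernel_voxels, length(vals),
    if (length(vals)) min(vals) else NA, if (length(vals)) max(vals) else NA))
  invisible(x)
}

#' CV frequency function
#'
#' Histograms the valid CV values into half-open bins `[k, k+1)` percent
#' (for the default 1% bin width), starting at 0, and normalises the
#' frequencies to percent so the total area under the curve is 100%.
#'
#' @param cvm a `cv_matrix` with at least one valid value, or a numeric
#'   vector of CV values in percent.
#' @param settings a [cv_settings()] (for the bin width).
#' @return A `frequency_function` data frame with columns `bin_left`
#'   (percent) and `frequency` (percent, summing to 100).
#' @export
frequency_function <- function(cvm, settings = cv_settings()) {
  vals <- if (inherits(cvm, "cv_matrix")) cvm$values[cvm$valid] else
    as.numeric(cvm)
  if (length(vals) == 0L) {
    stop("no valid CV values to histogram", call. = FALSE)
  }
  w <- settings$bin_percent
  bin <- floor(vals / w)
  nb <- max(bin) + 1L
  counts <- tabulate(bin + 1L, nbins = nb)
  out <- data.frame(bin_left = (seq_len(nb) - 1L) * w,
                    frequency = 100 * counts / length(vals))
  structure(out, bin_percent = w, n_values = length(vals),
            class = c("frequency_function", "data.frame"))
}

#' Modal CV threshold from a healthy reference group
#'
#' Averages the frequency functions of a healthy reference group (arithmetic
#' mean, bins aligned at 0) and returns the midpoint of the highest-frequency
#' bin of the mean curve as the CV threshold CV_T. Ties are broken toward
#' the lower bin. With 1%-wide bins a peak in `[20, 21)` gives CV_T = 20.5.
#'
#' @param ffs a list of `frequency_function`s on identical binning (a single
#'   `frequency_function` is accepted).
#' @return CV_T in percent.
#' @export
modal_cvt <- function(ffs) {
  if (inherits(ffs, "frequency_function")) ffs <- list(ffs)
  stopifnot(length(ffs) >= 1L)
  w <- attr(ffs[[1]], "bin_percent")
  for (f in ffs) {
    if (!inherits(f, "frequency_function")) {
      stop("inputs must be frequency functions", call. = FALSE)
    }
    if (!isTRUE(all.equal(attr(f, "bin_percent"), w)) ||
        f$bin_left[1] != 0) {
      stop("frequency functions are on inconsistent binning", call. = FALSE)
    }
  }
  nb <- max(vapply(ffs, nrow, 1L))
  acc <- numeric(nb)
  for (f in ffs) acc[seq_len(nrow(f))] <- acc[seq_len(nrow(f))] + f$frequency
  mean_f <- acc / length(ffs)
  (which.max(mean_f) - 1L) * w + w / 2
}

#' AUC above a CV threshold
#'
#' The package's global inhomogeneity score: the percentage of valid CV
#' values strictly greater than the threshold `cvt`. Computed from the raw
#' CV values (not the binned frequency function), so there is no bin-edge
#' ambiguity; 100% means every CV value exceeds the threshold.
#'
#' @param cvm a `cv_matrix` (or numeric vector of CV values in percent).
#' @param cvt CV threshold in percent (>= 0), e.g. from [modal_cvt()].
#' @return AUC(CV_T) in percent, in `[0, 100]`.
#' @export
auc_above <- function(cvm, cvt) {
  stopifnot(cvt >= 0 || is.infinite(cvt))
  vals <- if (inherits(cvm, "cv_matrix")) cvm$values[cvm$valid] else
    as.numeric(cvm)
  if (length(vals) == 0L) stop("no valid CV values", call. = FALSE)
  100 * mean(vals > cvt)
}

#' One-call CV analysis of a volume
#'
#' Runs [cv_kernel()], [frequency_function()] and [auc_above()] on a volume
#' and returns the summary a clinical analysis would report.
#'
#' @param vol an [activity_volume()].
#' @param mask the full analysis [lung_mask()]; peeled internally.
#' @param cvt CV threshold in percent (from a healthy reference group).
#' @param settings a [cv_settings()].
#' @param peel_layers edge layers to peel before analysis.
#' @return A list: `cvt`, `auc` (percent), `n_valid`, `volume_full_L`,
#'   `volume_peeled_L`, `frequency` (the frequency function), `cv` (the
#'   `cv_matrix`).
#' @export
cv_analysis <- function(vol, mask, cvt, settings = cv_settings(),
                        peel_layers = 1L) {
  peeled <- peel(mask, peel_layers)
  cvm <- cv_kernel(vol, peeled, settings)
  ff <- frequency_function(cvm, settings)
  list(cvt = cvt, auc = auc_above(cvm, cvt),
       n_valid = sum(cvm$valid),
       volume_full_L = mask_volume_L(mask),
       volume_peeled_L = mask_volume_L(peeled),
       frequency = ff, cv = cvm)
}

#' Write a CV matrix as NIfTI
#'
#' Invalid centres are stored as `NaN`.
#'
#' @param cvm a `cv_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cv_matrix <- function(cvm, path) {
  arr <- cvm$values
  arr[!cvm$valid] <- NaN
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(cvm$pitch_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}
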