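#' Define the lung from a reconstruction of a homogeneous distribution
#'
#' For simulated data the lung is defined on the reconstruction of the
#' homogeneous (normal) activity distribution: every voxel with a value
#' strictly greater than half the global maximum belongs to the lung. Because
#' the half-maximum contour of a blurred sharp edge sits at the true edge
#' location, this recovers the physical lung boundary to within roughly the
#' system resolution.
#'
#' @param recon an [activity_volume()], reconstruction of the uniform case.
#' @return A [lung_mask()] (variant `"full"`).
#' @export
lung_from_reconstruction <- function(recon) {
  stopifnot(inherits(recon, "activity_volume"))
  mx <- max(recon)
  if (mx <= 0) stop("cannot segment an all-zero volume", call. = FALSE)
  m <- as_plain_array(recon) > 0.5 * mx
  lung_mask(m, pitch_mm = voxel_pitch(recon))
}

#' Define the lung from a CT-derived attenuation map
#'
#' Thresholds the attenuation map at `threshold` (voxels with mu below it
#' are lung candidates), discards low-attenuation components that touch the
#' volume border (exterior air), and keeps the two largest remaining
#' components (the two lungs). With lung tissue around 0.04 cm^-1 and soft
#' tissue around 0.16 cm^-1, the default threshold of 0.12 cm^-1 captures
#' the whole lung cavity.
#'
#' @param attenuation an attenuation map (cm^-1, 3D array with a `pitch_mm`
#'   attribute) whose body envelope is closed.
#' @param threshold attenuation threshold in cm^-1 (> 0).
#' @return A [lung_mask()] (variant `"full"`).
#' @export
lung_from_ct <- function(attenuation, threshold = 0.12) {
  stopifnot(is.array(attenuation), length(dim(attenuation)) == 3L,
            threshold > 0)
  pitch <- attr(attenuation, "pitch_mm")
  if (is.null(pitch)) stop("attenuation map carries no voxel pitch",
                           call. = FALSE)
  d <- dim(attenuation)
  low <- array(unclass(attenuation) < threshold, dim = d)
  lab <- label_components(low)
  if (max(lab) == 0L) stop("no voxels below the attenuation threshold",
                           call. = FALSE)
  border_ids <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                         lab[, , c(1, d[3])]))
  border_ids <- border_ids[border_ids > 0L]
  interior <- lab
  interior[interior %in% border_ids] <- 0L
  sizes <- tabulate(interior[interior > 0L])
  if (length(sizes) == 0L || all(sizes == 0L)) {
    stop("no interior low-attenuation component: nothing to segment",
         call. = FALSE)
  }
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(2L, sum(sizes > 0)))]
  lung_mask(array(interior %in% keep, dim = d), pitch_mm = pitch)
}

#' Peel edge layers off a lung mask
#'
#' Erodes the mask with the face-adjacent (6-neighbour) structuring element
#' `layers` times, removing one voxel-wide peripheral layer per pass. The
#' lung periphery of a reconstruction carries high CV values that reflect
#' the blurred edge rather than ventilation inhomogeneity, so CV analysis is
#' run on the peeled mask.
#'
#' @param mask a [lung_mask()].
#' @param layers number of layers to remove (>= 0).
#' @return The peeled [lung_mask()] (variant `"peeled"` when `layers` > 0),
#'   with attribute `removed_fraction_percent`.
#' @export
peel <- function(mask, layers = 1L) {
  stopifnot(inherits(mask, "lung_mask"), layers >= 0)
  layers <- as.integer(layers)
  m <- as_plain_array(mask)
  n0 <- sum(m)
  if (layers > 0L) {
    for (l in seq_len(layers)) {
      m <- erode_face(m)
      if (!any(m)) {
        stop(sprintf("peeling emptied the mask at layer %d", l),
             call. = FALSE)
      }
    }
  }
  out <- lung_mask(m, pitch_mm = voxel_pitch(mask),
                   variant = if (layers > 0L) "peeled" else "full")
  attr(out, "removed_fraction_percent") <- 100 * (n0 - sum(m)) / n0
  attr(out, "hilum") <- attr(mask, "hilum")
  out
}
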