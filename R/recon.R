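#' Reconstruction settings
#'
#' Settings for OSEM reconstruction and the 3D Butterworth post-filter.
#' Defaults follow common clinical ventilation SPECT practice: 10 iterations
#' of 16 subsets, Butterworth cut-off 0.5 cm^-1 of order 3 (a power of 6 in
#' the squared-gain convention).
#'
#' @param iterations number of full OSEM iterations (>= 1).
#' @param subsets number of ordered subsets; must divide the angle count.
#' @param cutoff_cm cut-off frequency of the Butterworth post-filter, cm^-1.
#' @param order Butterworth order n; the gain is
#'   `1 / sqrt(1 + (f/fc)^(2n))`, so the gain at the cut-off is `1/sqrt(2)`.
#' @param track_loglik if `TRUE`, [osem()] records the Poisson log-likelihood
#'   of the full data after every full iteration.
#' @return A `recon_settings` list.
#' @export
recon_settings <- function(iterations = 10L, subsets = 16L,
                           cutoff_cm = 0.5, order = 3L,
                           track_loglik = FALSE) {
  stopifnot(iterations >= 1L, subsets >= 1L, cutoff_cm > 0, order >= 1L)
  structure(list(iterations = as.integer(iterations),
                 subsets = as.integer(subsets),
                 cutoff_cm = cutoff_cm, order = as.integer(order),
                 track_loglik = isTRUE(track_loglik)),
            class = "recon_settings")
}

# bit-reversed ordering of 0..(m-1), falling back to the identity when m is
# not a power of two
bit_reversed <- function(m) {
  b <- log2(m)
  if (b != round(b)) return(seq_len(m))
  nbits <- as.integer(b)
  rev_bits <- vapply(0:(m - 1), function(v) {
    r <- 0L
    for (k in seq_len(nbits)) {
      r <- bitwOr(bitwShiftL(r, 1L), bitwAnd(v, 1L))
      v <- bitwShiftR(v, 1L)
    }
    r
  }, integer(1))
  rev_bits + 1L
}

#' OSEM reconstruction
#'
#' Basic ordered-subset expectation maximisation matched to the package's
#' parallel-beam projector: multiplicative EM updates per subset with the
#' ratio backprojection normalised by the subset sensitivity. Angles are
#' assigned to subsets by stride and subsets are visited in bit-reversed
#' order. The initial estimate is uniform inside the field of view
#' (voxels with positive sensitivity); voxels with zero sensitivity are
#' masked out of the update and reported via the `masked_voxels` attribute.
#' Voxel values stay nonnegative throughout, and the result is deterministic
#' given its inputs.
#'
#' @param proj a `projection_set` (counts or mean counts, >= 0).
#' @param geom the [acquisition_geometry()] of the acquisition.
#' @param settings a [recon_settings()]; `subsets` must divide the number of
#'   angles. The Butterworth filter is *not* applied here; see
#'   [butterworth3d()].
#' @param attenuation optional attenuation map (cm^-1) for attenuation
#'   correction with the projector's line-integral model; default off, which
#'   matches data simulated without attenuation.
#' @return An [activity_volume()] (provenance `"reconstruction"`). If
#'   `settings$track_loglik`, the attribute `loglik` holds the Poisson
#'   log-likelihood after each full iteration.
#' @export
osem <- function(proj, geom, settings = recon_settings(),
                 attenuation = NULL) {
  stopifnot(inherits(proj, "projection_set"),
            inherits(geom, "acquisition_geometry"),
            inherits(settings, "recon_settings"))
  dcounts <- dim(proj$counts)
  n <- dcounts[1]; nz <- dcounts[2]; n_ang <- dcounts[3]
  if (n_ang != geom$n_angles) {
    stop("projection set and geometry disagree on the angle count",
         call. = FALSE)
  }
  if (n_ang %% settings$subsets != 0L) {
    stop("subsets must divide the number of angles", call. = FALSE)
  }
  if (any(proj$counts < 0)) stop("projections must be nonnegative",
                                 call. = FALSE)
  ops <- lapply(geom$angles_deg, function(a) {
    rotation_operator(n, a * pi / 180)
  })
  mumat <- NULL
  atts <- vector("list", n_ang)
  if (!is.null(attenuation)) {
    mm <- unclass(attenuation); attributes(mm) <- list(dim = dim(attenuation))
    dim(mm) <- c(n * n, nz)
    pitch_cm <- geom$pitch_mm / 10
    for (a in seq_len(n_ang)) {
      atts[[a]] <- attenuation_factors(mm, ops[[a]], n, nz, pitch_cm)
    }
  }
  per_subset <- n_ang %/% settings$subsets
  subset_angles <- lapply(seq_len(settings$subsets), function(s) {
    seq.int(s, n_ang, by = settings$subsets)
  })
  # subset sensitivities: backprojection of unit projections
  sens <- lapply(subset_angles, function(ang) {
    acc <- matrix(0, n * n, nz)
    for (a in ang) {
      if (is.null(atts[[a]])) {
        acc <- acc + ops[[a]]$colsum      # same for every z slice
      } else {
        acc <- acc + backproject_one(matrix(1, n, nz), ops[[a]], n, nz,
                                     atts[[a]])
      }
    }
    acc
  })
  total_sens <- Reduce(`+`, sens)
  fov <- total_sens > 1e-8 * max(total_sens)
  masked <- sum(!fov)
  est <- matrix(0, n * n, nz)
  est[fov] <- 1
  eps <- 1e-12
  loglik <- numeric(0)
  order_sub <- bit_reversed(settings$subsets)
  for (it in seq_len(settings$iterations)) {
    for (s in order_sub) {
      back <- matrix(0, n * n, nz)
      for (a in subset_angles[[s]]) {
        fp <- project_one(est, ops[[a]], n, nz, atts[[a]])
        ratio <- proj$counts[, , a] / pmax(fp, eps)
        ratio[fp <= eps & proj$counts[, , a] <= 0] <- 0
        back <- back + backproject_one(ratio, ops[[a]], n, nz, atts[[a]])
      }
      upd <- est * back
      pos <- sens[[s]] > eps
      upd[pos] <- upd[pos] / sens[[s]][pos]
      upd[!pos] <- 0
      est <- upd
    }
    if (settings$track_loglik) {
      ll <- 0
      for (a in seq_len(n_ang)) {
        fp <- project_one(est, ops[[a]], n, nz, atts[[a]])
        ll <- ll + sum(proj$counts[, , a] * log(pmax(fp, eps)) - fp)
      }
      loglik <- c(loglik, ll)
    }
  }
  dim(est) <- c(n, n, nz)
  out <- activity_volume(est, pitch_mm = geom$pitch_mm,
                         provenance = "reconstruction")
  attr(out, "masked_voxels") <- masked
  if (settings$track_loglik) attr(out, "loglik") <- loglik
  attr(out, "settings") <- settings
  out
}

#' 3D Butterworth post-filter
#'
#' Applies a radially symmetric frequency-domain Butterworth filter with
#' gain `|H(f)| = (1 + (f/fc)^(2n))^(-1/2)`, the standard nuclear-medicine
#' convention: the gain at the cut-off frequency is `1/sqrt(2)` and the DC
#' component (the volume mean) is preserved. Frequencies are physical
#' (cm^-1), derived from the voxel pitch. Real input gives real output.
#'
#' @param vol an [activity_volume()].
#' @param cutoff_cm cut-off frequency fc in cm^-1 (> 0).
#' @param order Butterworth order n (>= 1).
#' @return The filtered [activity_volume()].
#' @export
butterworth3d <- function(vol, cutoff_cm = 0.5, order = 3L) {
  stopifnot(inherits(vol, "activity_volume"))
  if (cutoff_cm <= 0) stop("cutoff must be positive", call. = FALSE)
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  d <- dim(vol)
  pitch_cm <- voxel_pitch(vol) / 10
  freq_axis <- function(nn) {
    f <- c(0:(nn %/% 2), -((nn - nn %/% 2 - 1):1)) / (nn * pitch_cm)
    if (nn == 1) f <- 0
    f
  }
  fx <- freq_axis(d[1]); fy <- freq_axis(d[2]); fz <- freq_axis(d[3])
  f2 <- outer(outer(fx^2, fy^2, "+"), fz^2, "+")
  gain <- 1 / sqrt(1 + (sqrt(f2) / cutoff_cm)^(2 * order))
  sp <- fft(as_plain_array(vol))
  filtered <- Re(fft(sp * gain, inverse = TRUE)) / prod(d)
  out <- activity_volume(filtered, pitch_mm = voxel_pitch(vol),
                         provenance = "reconstruction")
  out
}
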