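#' Two-lung digital phantom specification
#'
#' Describes the voxel grid and the geometry of a simplified two-lung phantom:
#' two ellipsoid-like lung fields with flattened medial faces separated by a
#' mediastinal gap and a basal diaphragm dome, inside an elliptic body
#' envelope. The in-plane lung semi-axes are rescaled internally so the
#' generated lung volume matches `target_lung_volume_L` to within 2%.
#'
#' Axes: 1 = left-right, 2 = anterior-posterior, 3 = apex (high z) to
#' base (low z).
#'
#' @param grid_shape integer vector of 3 voxel counts (in-plane dims equal).
#' @param voxel_pitch_mm isotropic voxel pitch in mm.
#' @param target_lung_volume_L total lung volume (air, blood and parenchyma)
#'   in litres; default 4.2, a typical value for an elderly adult male.
#' @param lung_semiaxes_cm nominal (pre-scaling) semi-axes of each lung
#'   ellipsoid, `c(lr, ap, axial)` in cm.
#' @param lung_offset_cm left-right distance of each lung centre from the
#'   midline, in cm.
#' @param medial_gap_cm width of the mediastinal gap between the lungs, cm.
#' @param dome_height_cm,dome_width_cm height and lateral scale of the
#'   Gaussian diaphragm dome carved out of the lung base, cm.
#' @param body_margin_cm soft-tissue margin of the body envelope around the
#'   lung bounding box, cm.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_pitch_mm = 6.6,
                         target_lung_volume_L = 4.2,
                         lung_semiaxes_cm = c(5.2, 7.2, 11.5),
                         lung_offset_cm = 5.8,
                         medial_gap_cm = 2.2,
                         dome_height_cm = 4,
                         dome_width_cm = 4.5,
                         body_margin_cm = 3) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0L),
            grid_shape[1] == grid_shape[2],
            voxel_pitch_mm > 0, target_lung_volume_L > 0,
            length(lung_semiaxes_cm) == 3L, all(lung_semiaxes_cm > 0),
            medial_gap_cm >= 0, dome_height_cm >= 0)
  structure(list(grid_shape = grid_shape, voxel_pitch_mm = voxel_pitch_mm,
                 target_lung_volume_L = target_lung_volume_L,
                 lung_semiaxes_cm = lung_semiaxes_cm,
                 lung_offset_cm = lung_offset_cm,
                 medial_gap_cm = medial_gap_cm,
                 dome_height_cm = dome_height_cm,
                 dome_width_cm = dome_width_cm,
                 body_margin_cm = body_margin_cm),
            class = "phantom_spec")
}

# logical lung field for a given in-plane scale factor s (internal)
lung_field <- function(spec, s) {
  d <- spec$grid_shape
  pitch_cm <- spec$voxel_pitch_mm / 10
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2; cz <- (d[3] + 1) / 2
  x <- (seq_len(d[1]) - cx) * pitch_cm
  y <- (seq_len(d[2]) - cy) * pitch_cm
  z <- (seq_len(d[3]) - cz) * pitch_cm
  a <- spec$lung_semiaxes_cm[1] * s
  b <- spec$lung_semiaxes_cm[2] * s
  cc <- spec$lung_semiaxes_cm[3]
  X <- array(rep(x, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(z, each = d[1] * d[2]), dim = d)
  mask <- array(FALSE, dim = d)
  for (side in c(-1, 1)) {
    x0 <- side * spec$lung_offset_cm
    ell <- ((X - x0) / a)^2 + (Y / b)^2 + (Z / cc)^2 <= 1
    # diaphragm dome carved from below
    dome <- (-cc) + spec$dome_height_cm *
      exp(-(((X - x0)^2 + Y^2) / spec$dome_width_cm^2))
    mask <- mask | (ell & Z > dome)
  }
  # mediastinal gap: flattened medial faces
  mask & (abs(X) >= spec$medial_gap_cm / 2)
}

#' Build the two-lung voxel mask of a phantom
#'
#' Rasterises the phantom lung fields onto the voxel grid, rescaling the
#' in-plane lung semi-axes (by bisection) until the physical lung volume is
#' within 2% of the target. The result is deterministic for a given spec.
#'
#' @param spec a [phantom_spec()].
#' @return A [lung_mask()] with exactly two face-connected components; carries
#'   the spec and the hilum landmark points (voxel coordinates at the medial
#'   face of each lung, mid-height) as attributes.
#' @export
build_lung_mask <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vox_cm3 <- (spec$voxel_pitch_mm / 10)^3
  target_vox <- spec$target_lung_volume_L * 1000 / vox_cm3
  lo <- 0.25; hi <- 2.5
  vol_at <- function(s) sum(lung_field(spec, s))
  if (vol_at(hi) < target_vox) {
    need_cm <- 2 * (spec$lung_offset_cm + spec$lung_semiaxes_cm[1] * hi)
    stop(sprintf(paste0("grid too small for a %.2f L lung: need an in-plane ",
                        "extent of at least %.1f cm"),
                 spec$target_lung_volume_L, need_cm), call. = FALSE)
  }
  for (i in 1:48) {
    mid <- (lo + hi) / 2
    v <- vol_at(mid)
    if (abs(v - target_vox) / target_vox < 0.005) break
    if (v < target_vox) lo <- mid else hi <- mid
  }
  field <- lung_field(spec, mid)
  v <- sum(field)
  if (abs(v - target_vox) / target_vox > 0.02) {
    stop(sprintf("could not match target lung volume (achieved %.2f L)",
                 v * vox_cm3 / 1000), call. = FALSE)
  }
  mask <- lung_mask(field, pitch_mm = spec$voxel_pitch_mm)
  d <- spec$grid_shape
  pitch_cm <- spec$voxel_pitch_mm / 10
  hx <- (spec$medial_gap_cm / 2 + 0.6) / pitch_cm   # just inside medial face
  hil <- rbind(c((d[1] + 1) / 2 - hx, (d[2] + 1) / 2, (d[3] + 1) / 2),
               c((d[1] + 1) / 2 + hx, (d[2] + 1) / 2, (d[3] + 1) / 2))
  attr(mask, "spec") <- spec
  attr(mask, "scale") <- mid
  attr(mask, "hilum") <- hil
  mask
}

#' Spherical lesion specification
#'
#' Describes a population of identical spherical hypo-ventilated lesions:
#' diameter, activity concentration relative to the surrounding lung
#' (0 = no ventilation, 1 = normal), the fraction of the lung volume the
#' lesions should occupy, and how they are placed (`"even"`: quasi-uniform
#' over the whole lung; `"clustered"`: packed into a compact central-medial
#' region around the hilum, where the large bronchi enter the lung).
#'
#' @param diameter_cm lesion diameter in cm (> 0).
#' @param activity_fraction relative activity concentration in the lesion,
#'   in `[0, 1]`.
#' @param occupancy_fraction fraction of the total lung volume occupied by
#'   lesions, in `[0, 1)`.
#' @param placement `"even"` or `"clustered"`.
#' @param seed integer seed controlling the random placement.
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(diameter_cm, activity_fraction, occupancy_fraction,
                        placement = c("even", "clustered"), seed = 1L) {
  placement <- match.arg(placement)
  stopifnot(diameter_cm > 0,
            activity_fraction >= 0, activity_fraction <= 1,
            occupancy_fraction >= 0, occupancy_fraction < 1)
  structure(list(diameter_cm = diameter_cm,
                 activity_fraction = activity_fraction,
                 occupancy_fraction = occupancy_fraction,
                 placement = placement, seed = as.integer(seed)),
            class = "lesion_spec")
}

# voxel linear indices whose centres lie inside the sphere at `centre`
# (continuous voxel coordinates) of radius r_vox; restricted to the grid
sphere_voxels <- function(centre, r_vox, d) {
  i <- max(1L, ceiling(centre[1] - r_vox)):min(d[1], floor(centre[1] + r_vox))
  j <- max(1L, ceiling(centre[2] - r_vox)):min(d[2], floor(centre[2] + r_vox))
  k <- max(1L, ceiling(centre[3] - r_vox)):min(d[3], floor(centre[3] + r_vox))
  if (centre[1] + r_vox < 1 || centre[1] - r_vox > d[1] ||
      centre[2] + r_vox < 1 || centre[2] - r_vox > d[2] ||
      centre[3] + r_vox < 1 || centre[3] - r_vox > d[3]) return(integer(0))
  g <- expand.grid(i = i, j = j, k = k)
  keep <- (g$i - centre[1])^2 + (g$j - centre[2])^2 + (g$k - centre[3])^2 <=
    r_vox^2
  g <- g[keep, , drop = FALSE]
  g$i + (g$j - 1L) * d[1] + (g$k - 1L) * d[1] * d[2]
}

# face-centred-cubic lattice with nearest-neighbour distance `nn` (voxel
# units) covering the bounding box, with a random in-cell offset
fcc_sites <- function(bbox, nn, offset) {
  a <- nn * sqrt(2)
  basis <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5)) * a
  rng <- lapply(1:3, function(ax) {
    seq(floor((bbox[1, ax] - a) / a), ceiling((bbox[2, ax] + a) / a)) * a
  })
  cells <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  sites <- do.call(rbind, lapply(1:4, function(b) {
    sweep(cells, 2L, basis[b, ] + offset, "+")
  }))
  sites
}

#' Place non-overlapping spherical lesions in a lung mask
#'
#' Draws lesion centres so that pairwise centre distances are at least one
#' lesion diameter (no overlap) and the rasterised lesion voxels occupy the
#' requested fraction of the lung to within 0.5 percentage points. Even
#' placement uses seeded rejection sampling of centres uniform over the lung
#' up to 30% occupancy and a randomly thinned jittered face-centred-cubic
#' lattice above (random sequential packing jams well below 48%); clustered
#' placement packs discrete lesions by rejection sampling into the smallest
#' spherical region around the medial hilum landmarks that accommodates the
#' requested occupancy, growing the region when packing stalls.
#'
#' A lesion's voxels are the in-lung voxels whose centres fall inside the
#' sphere; spheres may be clipped by the lung boundary, in which case only
#' the in-lung part counts towards occupancy.
#'
#' @param mask a [lung_mask()] from [build_lung_mask()] (clustered placement
#'   requires its hilum attribute).
#' @param lesions a [lesion_spec()].
#' @return A numeric matrix of lesion centres (columns `x`, `y`, `z`,
#'   continuous 1-based voxel coordinates), with attributes
#'   `achieved_occupancy` (fraction), `lesion_voxels` (count) and `seed`.
#' @export
place_lesions <- function(mask, lesions) {
  stopifnot(inherits(mask, "lung_mask"), inherits(lesions, "lesion_spec"))
  d <- dim(mask)
  empty <- matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z")))
  if (lesions$occupancy_fraction == 0) {
    attr(empty, "achieved_occupancy") <- 0
    attr(empty, "lesion_voxels") <- 0L
    attr(empty, "seed") <- lesions$seed
    return(empty)
  }
  pitch <- voxel_pitch(mask)
  d_vox <- lesions$diameter_cm * 10 / pitch
  r_vox <- d_vox / 2
  lin <- which(as_plain_array(mask))
  n_lung <- length(lin)
  idx <- arrayInd(lin, d)
  bbox <- rbind(apply(idx, 2, min), apply(idx, 2, max))
  if (d_vox > min(bbox[2, ] - bbox[1, ] + 1)) {
    stop("lesion diameter exceeds the smallest lung-field extent",
         call. = FALSE)
  }
  target_vox <- lesions$occupancy_fraction * n_lung
  tol_vox <- 0.005 * n_lung                 # 0.5 percentage points

  occupied <- logical(prod(d))              # lesion voxels so far
  centres <- list(); counts <- 0L
  accepted <- matrix(numeric(0), ncol = 3)

  add_if_better <- function(vox) {
    # add the lesion unless overshooting by more than stopping short
    (counts + length(vox) - target_vox) < (target_vox - counts)
  }

  set.seed(derive_seed(lesions$seed, paste("lesion", lesions$placement)))

  if (lesions$occupancy_fraction > 0.30 && lesions$placement == "even") {
    # random sequential packing jams near 38%; thin a jittered FCC lattice
    offset <- runif(3, 0, d_vox * sqrt(2))
    sites <- fcc_sites(bbox, d_vox, offset)
    svox <- pmin(pmax(round(sites), 1), rep(d, each = nrow(sites)))
    inside <- as_plain_array(mask)[cbind(svox[, 1], svox[, 2], svox[, 3])]
    sites <- sites[inside, , drop = FALSE]
    for (s in sample.int(nrow(sites))) {
      if (counts >= target_vox - tol_vox / 2) break
      vox <- sphere_voxels(sites[s, ], r_vox, d)
      vox <- vox[as_plain_array(mask)[vox] & !occupied[vox]]
      if (length(vox) == 0L) next
      if (counts + length(vox) > target_vox && !add_if_better(vox)) break
      occupied[vox] <- TRUE
      counts <- counts + length(vox)
      centres[[length(centres) + 1L]] <- sites[s, ]
    }
  } else if (lesions$placement == "clustered") {
    # discrete lesions packed by rejection sampling into the smallest
    # spherical region around the hilum landmarks that holds the occupancy
    hil <- attr(mask, "hilum")
    if (is.null(hil)) stop("mask carries no hilum landmark", call. = FALSE)
    dmin <- rep(Inf, n_lung)
    for (h in seq_len(nrow(hil))) {
      dh <- sqrt((idx[, 1] - hil[h, 1])^2 + (idx[, 2] - hil[h, 2])^2 +
                   (idx[, 3] - hil[h, 3])^2)
      dmin <- pmin(dmin, dh)
    }
    ord_lung <- order(dmin)
    # initial region sized for random packing (~30% local density)
    n_region <- min(n_lung, ceiling(target_vox / 0.30))
    repeat {
      region <- lin[ord_lung[seq_len(n_region)]]
      in_region <- logical(prod(d)); in_region[region] <- TRUE
      stall <- 0L
      while (counts < target_vox - tol_vox / 2 && stall < 5000L) {
        pick <- region[sample.int(length(region), 1L)]
        p <- arrayInd(pick, d) + runif(3, -0.5, 0.5)
        if (nrow(accepted) > 0) {
          dd <- (accepted[, 1] - p[1])^2 + (accepted[, 2] - p[2])^2 +
            (accepted[, 3] - p[3])^2
          if (min(dd) < d_vox^2) { stall <- stall + 1L; next }
        }
        vox <- sphere_voxels(p, r_vox, d)
        vox <- vox[as_plain_array(mask)[vox] & !occupied[vox]]
        if (length(vox) == 0L) { stall <- stall + 1L; next }
        if (counts + length(vox) > target_vox && !add_if_better(vox)) break
        occupied[vox] <- TRUE
        counts <- counts + length(vox)
        accepted <- rbind(accepted, p)
        centres[[length(centres) + 1L]] <- p
        stall <- 0L
      }
      if (counts >= target_vox - tol_vox / 2 || n_region >= n_lung) break
      n_region <- min(n_lung, ceiling(n_region * 1.15))   # grow the region
    }
  } else {
    n_expected <- max(1, ceiling(target_vox /
                                   max(1, (4 / 3) * pi * r_vox^3)))
    budget <- 500L * n_expected + 20000L
    attempt <- 0L
    while (counts < target_vox - tol_vox / 2 && attempt < budget) {
      attempt <- attempt + 1L
      pick <- lin[sample.int(n_lung, 1L)]
      p <- arrayInd(pick, d) + runif(3, -0.5, 0.5)
      if (nrow(accepted) > 0) {
        dd <- (accepted[, 1] - p[1])^2 + (accepted[, 2] - p[2])^2 +
          (accepted[, 3] - p[3])^2
        if (min(dd) < d_vox^2) next
      }
      vox <- sphere_voxels(p, r_vox, d)
      vox <- vox[as_plain_array(mask)[vox]]
      if (length(vox) == 0L) next
      if (counts + length(vox) > target_vox && !add_if_better(vox)) break
      occupied[vox] <- TRUE
      counts <- counts + length(vox)
      accepted <- rbind(accepted, p)
      centres[[length(centres) + 1L]] <- p
    }
  }
  achieved <- counts / n_lung
  if (abs(achieved - lesions$occupancy_fraction) > 0.005) {
    stop(sprintf(paste0("lesion packing failed: achieved occupancy %.2f%% ",
                        "versus requested %.2f%%"),
                 100 * achieved, 100 * lesions$occupancy_fraction),
         call. = FALSE)
  }
  out <- do.call(rbind, centres)
  colnames(out) <- c("x", "y", "z")
  attr(out, "achieved_occupancy") <- achieved
  attr(out, "lesion_voxels") <- counts
  attr(out, "seed") <- lesions$seed
  out
}

#' Build a phantom activity distribution
#'
#' Background lung voxels get concentration 1 (arbitrary units), lesion
#' voxels get `activity_fraction`, and voxels outside the lung get 0. A voxel
#' belongs to a lesion iff its centre lies inside one of the lesion spheres.
#'
#' @param mask a [lung_mask()].
#' @param centres lesion centres from [place_lesions()] on the same mask.
#' @param lesions the [lesion_spec()] used for placement.
#' @return An [activity_volume()] (provenance `"phantom"`) with attributes
#'   `achieved_occupancy` (fraction) and `achieved_reduction_percent`, the
#'   total reduction of ventilation actually realised on the grid.
#' @export
build_activity <- function(mask, centres, lesions) {
  stopifnot(inherits(mask, "lung_mask"), inherits(lesions, "lesion_spec"))
  d <- dim(mask)
  vol <- array(0, dim = d)
  m <- as_plain_array(mask)
  vol[m] <- 1
  r_vox <- lesions$diameter_cm * 10 / voxel_pitch(mask) / 2
  n_lesion_vox <- 0L
  if (length(centres) > 0) {
    for (i in seq_len(nrow(centres))) {
      p <- centres[i, ]
      cv <- pmax(1, pmin(round(p), d))
      if (!m[matrix(cv, 1)]) {
        stop("lesion centre outside the lung mask", call. = FALSE)
      }
      vox <- sphere_voxels(p, r_vox, d)
      vox <- vox[m[vox]]
      n_lesion_vox <- n_lesion_vox + length(vox)
      vol[vox] <- lesions$activity_fraction
    }
  }
  occ <- n_lesion_vox / sum(m)
  out <- activity_volume(vol, pitch_mm = voxel_pitch(mask),
                         provenance = "phantom")
  attr(out, "achieved_occupancy") <- occ
  attr(out, "achieved_reduction_percent") <-
    100 * occ * (1 - lesions$activity_fraction)
  out
}

#' Total reduction of ventilation
#'
#' The fraction of functioning lung lost to lesions: lesions occupying a
#' fraction `occupancy_fraction` of the lung at relative activity
#' `activity_fraction` remove `occupancy * (1 - activity)` of the total
#' ventilation. For example, lesions at 50% activity in 10% of the lung give
#' a 5% total reduction.
#'
#' @param occupancy_fraction fraction of lung volume occupied, in `[0, 1]`.
#' @param activity_fraction relative lesion activity, in `[0, 1]`.
#' @return Total ventilation reduction in percent.
#' @export
total_ventilation_reduction <- function(occupancy_fraction,
                                        activity_fraction) {
  if (any(occupancy_fraction < 0 | occupancy_fraction > 1) ||
      any(activity_fraction < 0 | activity_fraction > 1)) {
    stop("occupancy_fraction and activity_fraction must lie in [0, 1]",
         call. = FALSE)
  }
  100 * occupancy_fraction * (1 - activity_fraction)
}

#' Respiratory motion surrogate: axial time-averaged displacement
#'
#' Emulates the blurring a breathing cycle imprints on a time-averaged
#' acquisition: each axial slice is displaced by `A(z) * sin(phase)` and the
#' volume is averaged over a full cycle, where the amplitude `A(z)`
#' interpolates linearly from `apical_amplitude_mm` at the apex (top slice)
#' to `basal_amplitude_mm` at the base (bottom slice). Displaced mass is
#' redistributed conservatively (linear splitting between neighbouring
#' slices, with axial padding), so total activity is conserved.
#'
#' @param activity an [activity_volume()].
#' @param basal_amplitude_mm peak axial displacement at the lung base (mm).
#' @param apical_amplitude_mm peak axial displacement at the apex (mm);
#'   must not exceed the basal amplitude.
#' @param n_phases number of phase samples over the cycle.
#' @return The time-averaged [activity_volume()].
#' @export
apply_motion_blur <- function(activity, basal_amplitude_mm,
                              apical_amplitude_mm, n_phases = 36L) {
  stopifnot(inherits(activity, "activity_volume"),
            basal_amplitude_mm >= 0, apical_amplitude_mm >= 0,
            basal_amplitude_mm >= apical_amplitude_mm)
  if (basal_amplitude_mm == 0 && apical_amplitude_mm == 0) return(activity)
  pitch <- voxel_pitch(activity)
  d <- dim(activity)
  nz <- d[3]
  # base at low z, apex at high z
  amp_vox <- (basal_amplitude_mm +
                (apical_amplitude_mm - basal_amplitude_mm) *
                (seq_len(nz) - 1) / (nz - 1)) / pitch
  pad <- ceiling(max(amp_vox)) + 1L
  acc <- array(0, dim = c(d[1], d[2], nz + 2L * pad))
  phases <- 2 * pi * (seq_len(n_phases) - 0.5) / n_phases
  a <- as_plain_array(activity)
  for (ph in phases) {
    dz <- amp_vox * sin(ph)
    zf <- floor(dz); fr <- dz - zf
    for (z in seq_len(nz)) {
      zt <- z + pad + zf[z]
      acc[, , zt] <- acc[, , zt] + a[, , z] * (1 - fr[z])
      acc[, , zt + 1L] <- acc[, , zt + 1L] + a[, , z] * fr[z]
    }
  }
  out <- acc[, , (pad + 1L):(pad + nz), drop = FALSE] / n_phases
  res <- activity_volume(array(out, dim = d), pitch_mm = pitch,
                         provenance = attr(activity, "provenance"))
  for (at in c("achieved_occupancy", "achieved_reduction_percent")) {
    attr(res, at) <- attr(activity, at)
  }
  res
}

#' Build the attenuation map of a phantom
#'
#' Assigns linear attenuation coefficients (140 keV regime): 0.04 cm^-1 in
#' the lung, 0.16 cm^-1 in the soft tissue of the body envelope, 0 outside
#' the body. Lesions share the lung coefficient (their density is taken equal
#' to lung tissue).
#'
#' @param spec the [phantom_spec()].
#' @param mask the corresponding [lung_mask()].
#' @param mu_lung,mu_soft linear attenuation coefficients in cm^-1.
#' @return A 3D array (class `attenuation_map`) of coefficients in cm^-1,
#'   with the voxel pitch attached.
#' @export
build_attenuation <- function(spec, mask, mu_lung = 0.04, mu_soft = 0.16) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(mask, "lung_mask"),
            all(dim(mask) == spec$grid_shape))
  d <- spec$grid_shape
  pitch_cm <- spec$voxel_pitch_mm / 10
  lin <- which(as_plain_array(mask))
  idx <- arrayInd(lin, d)
  ctr <- (d + 1) / 2
  half_x <- (max(abs(idx[, 1] - ctr[1]))) * pitch_cm + spec$body_margin_cm
  half_y <- (max(abs(idx[, 2] - ctr[2]))) * pitch_cm + spec$body_margin_cm
  zr <- range(idx[, 3])
  x <- (seq_len(d[1]) - ctr[1]) * pitch_cm
  y <- (seq_len(d[2]) - ctr[2]) * pitch_cm
  body2d <- outer(x^2 / half_x^2, y^2 / half_y^2, "+") <= 1
  mu <- array(0, dim = d)
  zlo <- max(1L, zr[1] - round(2 / pitch_cm))
  zhi <- min(d[3], zr[2] + round(2 / pitch_cm))
  for (z in zlo:zhi) mu[, , z][body2d] <- mu_soft
  mu[as_plain_array(mask)] <- mu_lung
  structure(mu, pitch_mm = spec$voxel_pitch_mm,
            class = c("attenuation_map", "array"))
}

#' The nine simulated activity distributions
#'
#' The standard set of activity distributions used in the simulated COPD
#' discrimination experiment: one homogeneous (normal) lung and eight
#' lesioned variants spanning lesion diameters of 1 and 2 cm, relative lesion
#' activities of 50%, 25% and 0%, occupancies of 10-48% and even or clustered
#' placement. Nominal total ventilation reductions for the lesioned rows are
#' 5, 6, 10, 12, 5, 10, 24 and 36 percent.
#'
#' @param seed base seed for lesion placement; each distribution derives its
#'   own placement seed from it.
#' @return A named list of entries, each with `label`, `number` and a
#'   [lesion_spec()] (`NULL` for the uniform distribution).
#' @export
copd_distributions <- function(seed = 1L) {
  rows <- list(
    list("uniform",           1L, NA,  NA,  0,    NA),
    list("1cm_50pct_10_even", 2L, 1, 0.50, 0.10, "even"),
    list("1cm_50pct_12_clus", 3L, 1, 0.50, 0.12, "clustered"),
    list("1cm_0pct_10_even",  4L, 1, 0.00, 0.10, "even"),
    list("1cm_0pct_12_clus",  5L, 1, 0.00, 0.12, "clustered"),
    list("2cm_50pct_10_even", 6L, 2, 0.50, 0.10, "even"),
    list("2cm_0pct_10_even",  7L, 2, 0.00, 0.10, "even"),
    list("2cm_50pct_48_even", 8L, 2, 0.50, 0.48, "even"),
    list("2cm_25pct_48_even", 9L, 2, 0.25, 0.48, "even"))
  out <- lapply(rows, function(r) {
    les <- if (r[[5]] > 0) {
      lesion_spec(diameter_cm = r[[3]], activity_fraction = r[[4]],
                  occupancy_fraction = r[[5]], placement = r[[6]],
                  seed = derive_seed(seed, r[[1]]))
    }
    list(label = r[[1]], number = r[[2]], lesions = les)
  })
  names(out) <- vapply(out, `[[`, "", "label")
  out
}
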