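#' Plan for a simulated normal-versus-COPD discrimination experiment
#'
#' Bundles everything needed to reproduce the simulated discrimination
#' study: a phantom, a set of activity distributions, the acquisition
#' geometry, reconstruction and CV-analysis settings, the number of Poisson
#' noise realisations per distribution, and a master seed. Defaults run a
#' desk-scale chain: a 64^3 grid at 6.6 mm pitch, 64 projection angles, and
#' a total count budget scaled from the clinical 3.635e6 counts (128 angles)
#' in proportion to the angle count, which keeps the per-projection count
#' density, and hence the pixel-level noise, at the clinical level.
#'
#' @param phantom a [phantom_spec()].
#' @param distributions a list as returned by [copd_distributions()]; may be
#'   a subset, but [run_experiment()] requires the `"uniform"` entry.
#' @param geometry an [acquisition_geometry()]; `pitch_mm` is taken from the
#'   phantom when `NULL`.
#' @param recon a [recon_settings()].
#' @param cv a [cv_settings()].
#' @param realisations Poisson noise realisations per distribution (>= 2).
#' @param total_counts grand total mean counts per acquisition; default
#'   `3.635e6 * n_angles / 128`.
#' @param seed master seed; per-realisation seeds are derived from it and
#'   the distribution label.
#' @param motion_mm `c(basal, apical)` amplitudes for the respiratory-motion
#'   surrogate, in mm; `c(0, 0)` disables motion blurring.
#' @param peel_layers edge layers peeled off the analysis mask.
#' @return An `experiment_plan` list.
#' @export
experiment_plan <- function(phantom = phantom_spec(),
                            distributions = copd_distributions(),
                            geometry = NULL,
                            recon = recon_settings(),
                            cv = cv_settings(),
                            realisations = 20L,
                            total_counts = NULL,
                            seed = 1L,
                            motion_mm = c(0, 0),
                            peel_layers = 1L) {
  if (is.null(geometry)) {
    geometry <- acquisition_geometry(n_angles = 64L,
                                     pitch_mm = phantom$voxel_pitch_mm)
  }
  if (is.null(total_counts)) {
    total_counts <- 3.635e6 * geometry$n_angles / 128
  }
  labels <- vapply(distributions, `[[`, "", "label")
  stopifnot(realisations >= 2L, !anyDuplicated(labels))
  structure(list(phantom = phantom, distributions = distributions,
                 geometry = geometry, recon = recon, cv = cv,
                 realisations = as.integer(realisations),
                 total_counts = total_counts, seed = as.integer(seed),
                 motion_mm = motion_mm,
                 peel_layers = as.integer(peel_layers)),
            class = "experiment_plan")
}

#' Run the simulated discrimination experiment
#'
#' For every distribution in the plan: builds the phantom activity
#' distribution, forward-projects it once (noiseless), scales it to the
#' count budget, draws the planned number of Poisson realisations with
#' derived seeds, reconstructs each with OSEM plus the Butterworth
#' post-filter, and computes its CV matrix on the peeled analysis lung.
#' The analysis lung is segmented by the half-maximum rule from the
#' reconstruction of the noiseless normal projections. The CV threshold
#' CV_T is the modal value of the mean CV frequency function of the normal
#' group's realisations, and is applied to every distribution to produce
#' per-realisation AUC(CV_T) scores. Each lesioned group is then compared
#' with the normal group by the Mann-Whitney U test. Fully reproducible
#' from the plan.
#'
#' @param plan an [experiment_plan()]; its distributions must include
#'   `"uniform"`.
#' @param verbose print per-stage progress.
#' @return An `experiment_result` list: `auc` (data frame with columns
#'   `label`, `realisation`, `seed`, `auc`), `cvt`, `comparisons` (named
#'   list of [mann_whitney_u()] results versus the normal group),
#'   `summaries` (per-group [group_summary()]), `mask_full`, `mask_peeled`,
#'   `achieved` (per-distribution occupancy and ventilation reduction),
#'   and the `plan`.
#' @export
run_experiment <- function(plan, verbose = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  labels <- vapply(plan$distributions, `[[`, "", "label")
  if (!"uniform" %in% labels) {
    stop("the plan must include the 'uniform' (normal) distribution",
         call. = FALSE)
  }
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]

  say("building phantom lung mask")
  mask <- build_lung_mask(plan$phantom)
  moving <- any(plan$motion_mm > 0)

  # noiseless projections per distribution
  projections <- list()
  achieved <- list()
  for (dist in plan$distributions) {
    say("projecting '%s' [%.1f s]", dist$label, proc.time()[3] - t0)
    if (is.null(dist$lesions)) {
      act <- build_activity(mask, NULL,
                            lesion_spec(1, 1, 0, seed = plan$seed))
    } else {
      centres <- place_lesions(mask, dist$lesions)
      act <- build_activity(mask, centres, dist$lesions)
    }
    achieved[[dist$label]] <-
      list(occupancy = attr(act, "achieved_occupancy"),
           reduction_percent = attr(act, "achieved_reduction_percent"))
    if (moving) {
      act <- apply_motion_blur(act, plan$motion_mm[1], plan$motion_mm[2])
    }
    proj <- forward_project(act, plan$geometry)
    projections[[dist$label]] <- scale_to_counts(proj, plan$total_counts)
  }

  say("segmenting the analysis lung [%.1f s]", proc.time()[3] - t0)
  recon_normal <- butterworth3d(
    osem(projections[["uniform"]], plan$geometry, plan$recon),
    plan$recon$cutoff_cm, plan$recon$order)
  mask_full <- lung_from_reconstruction(recon_normal)
  mask_peeled <- peel(mask_full, plan$peel_layers)

  reconstruct_one <- function(label, i) {
    sd_i <- derive_seed(plan$seed, label, i)
    noisy <- poisson_realise(projections[[label]], sd_i)
    rec <- butterworth3d(osem(noisy, plan$geometry, plan$recon),
                         plan$recon$cutoff_cm, plan$recon$order)
    list(seed = sd_i, cvm = cv_kernel(rec, mask_peeled, plan$cv))
  }

  cv_values <- list()
  seeds <- list()
  for (label in labels) {
    say("reconstructing %d realisations of '%s' [%.1f s]",
        plan$realisations, label, proc.time()[3] - t0)
    res <- lapply(seq_len(plan$realisations), function(i) {
      reconstruct_one(label, i)
    })
    cv_values[[label]] <- lapply(res, function(r) r$cvm$values[r$cvm$valid])
    seeds[[label]] <- vapply(res, `[[`, 1, "seed")
  }

  ffs <- lapply(cv_values[["uniform"]], frequency_function,
                settings = plan$cv)
  cvt <- modal_cvt(ffs)
  say("CV_T = %.1f%% [%.1f s]", cvt, proc.time()[3] - t0)

  auc <- do.call(rbind, lapply(labels, function(label) {
    data.frame(label = label,
               realisation = seq_len(plan$realisations),
               seed = seeds[[label]],
               auc = vapply(cv_values[[label]], auc_above, 1, cvt = cvt))
  }))
  rownames(auc) <- NULL

  normal_auc <- auc$auc[auc$label == "uniform"]
  comparisons <- list()
  for (label in setdiff(labels, "uniform")) {
    comparisons[[label]] <- mann_whitney_u(normal_auc,
                                           auc$auc[auc$label == label])
  }
  summaries <- lapply(labels, function(l) group_summary(auc$auc[auc$label == l]))
  names(summaries) <- labels
  say("done [%.1f s]", proc.time()[3] - t0)
  structure(list(auc = auc, cvt = cvt, comparisons = comparisons,
                 summaries = summaries, mask_full = mask_full,
                 mask_peeled = mask_peeled, achieved = achieved,
                 plan = plan),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> CV_T = %.1f%%, %d realisations\n",
              x$cvt, x$plan$realisations))
  for (l in names(x$summaries)) {
    s <- x$summaries[[l]]
    p <- if (l %in% names(x$comparisons)) {
      sprintf(", p vs normal = %.3g", x$comparisons[[l]]$p_value)
    } else ""
    cat(sprintf("  %-20s mean AUC %.1f%% +/- %.1f (95%% CI)%s\n",
                l, s$mean, s$ci_halfwidth, p))
  }
  invisible(x)
}

#' Write an experiment result to a run directory
#'
#' Stores the AUC table as CSV, the comparisons and a manifest (seeds,
#' settings, CV_T, achieved occupancies) as JSON, and the analysis masks as
#' NIfTI.
#'
#' @param result an `experiment_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$auc, file.path(dir, "auc.csv"), row.names = FALSE)
  manifest <- list(
    cvt_percent = result$cvt,
    master_seed = result$plan$seed,
    realisations = result$plan$realisations,
    total_counts = result$plan$total_counts,
    n_angles = result$plan$geometry$n_angles,
    achieved = result$achieved,
    comparisons = lapply(result$comparisons, function(cmp) {
      list(U = cmp$U, p_value = cmp$p_value, method = cmp$method)
    }),
    summaries = result$summaries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  as_vol <- function(m) {
    activity_volume(array(as.numeric(m), dim = dim(m)),
                    pitch_mm = voxel_pitch(m), provenance = "phantom")
  }
  write_volume(as_vol(result$mask_full), file.path(dir, "lung_full.nii.gz"))
  write_volume(as_vol(result$mask_peeled),
               file.path(dir, "lung_peeled.nii.gz"))
  invisible(dir)
}
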