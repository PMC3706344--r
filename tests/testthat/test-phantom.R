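test_that("lung mask hits the target volume with two connected components", {
  expect_equal(mask_volume_L(desk_mask), 4.2, tolerance = 0.02)
  vox_cm3 <- (voxel_pitch(desk_mask) / 10)^3
  expect_equal(sum(desk_mask), 4200 / vox_cm3, tolerance = 0.02)
  expect_identical(lungcv:::n_components(lungcv:::as_plain_array(desk_mask)),
                   2L)
})

test_that("fine-pitch mask voxel count follows volume arithmetic", {
  m <- build_lung_mask(phantom_spec(grid_shape = c(128L, 128L, 128L),
                                    voxel_pitch_mm = 3.3))
  # 4200 cm^3 / 0.0359 cm^3 per voxel
  expect_equal(sum(m), 4200 / 0.33^3, tolerance = 0.02)
  expect_identical(lungcv:::n_components(lungcv:::as_plain_array(m)), 2L)
})

test_that("a too-small grid raises a sizing error", {
  expect_error(build_lung_mask(phantom_spec(grid_shape = c(24L, 24L, 24L))),
               "grid too small")
})

test_that("ventilation-reduction arithmetic and domain checks", {
  expect_identical(total_ventilation_reduction(0.10, 0.50), 5)
  expect_identical(total_ventilation_reduction(0.48, 0.25), 36)
  expect_identical(total_ventilation_reduction(0, 0.7), 0)
  expect_error(total_ventilation_reduction(1.2, 0.5), "must lie in")
  expect_error(total_ventilation_reduction(0.5, -0.1), "must lie in")
})

test_that("zero occupancy yields no lesions and a uniform lung", {
  les <- lesion_spec(1, 0.5, 0)
  cen <- place_lesions(desk_mask, les)
  expect_identical(nrow(cen), 0L)
  act <- build_activity(desk_mask, cen, les)
  expect_true(all(act[as.logical(desk_mask)] == 1))
  expect_true(all(act[!as.logical(desk_mask)] == 0))
  expect_identical(attr(act, "achieved_reduction_percent"), 0)
})

test_that("all nine standard distributions achieve their occupancy", {
  for (d in copd_distributions(seed = 5L)) {
    if (is.null(d$lesions)) next
    cen <- place_lesions(desk_mask, d$lesions)
    occ <- attr(cen, "achieved_occupancy")
    expect_lt(abs(occ - d$lesions$occupancy_fraction), 0.005,
              label = sprintf("occupancy gap for %s", d$label))
  }
})

test_that("lesions never overlap and stay inside the lung", {
  for (les in list(lesion_spec(1, 0.5, 0.10, "even", seed = 3L),
                   lesion_spec(2, 0.5, 0.48, "even", seed = 3L),
                   lesion_spec(1, 0, 0.12, "clustered", seed = 3L))) {
    cen <- place_lesions(desk_mask, les)
    d_vox <- les$diameter_cm * 10 / voxel_pitch(desk_mask)
    dm <- as.matrix(dist(cen))
    expect_gte(min(dm[upper.tri(dm)]), d_vox - 1e-9)
    act <- build_activity(desk_mask, cen, les)
    # lesion voxels only inside the lung: outside stays exactly 0
    expect_true(all(act[!as.logical(desk_mask)] == 0))
    expect_true(all(act[as.logical(desk_mask)] %in%
                      c(les$activity_fraction, 1)))
  }
})

test_that("clustered lesions form a compact medial region", {
  les <- lesion_spec(1, 0.5, 0.12, "clustered", seed = 2L)
  cen <- place_lesions(desk_mask, les)
  hil <- attr(desk_mask, "hilum")
  dmin <- pmin(sqrt(colSums((t(cen) - hil[1, ])^2)),
               sqrt(colSums((t(cen) - hil[2, ])^2)))
  expect_lt(max(dmin), 20)           # voxels; compact around the hilum
  ev <- place_lesions(desk_mask, lesion_spec(1, 0.5, 0.12, "even", seed = 2L))
  dmin_ev <- pmin(sqrt(colSums((t(ev) - hil[1, ])^2)),
                  sqrt(colSums((t(ev) - hil[2, ])^2)))
  expect_gt(max(dmin_ev), max(dmin)) # even placement reaches further out
})

test_that("placement is reproducible under a fixed seed", {
  les1 <- lesion_spec(1, 0.5, 0.10, "even", seed = 7L)
  a <- place_lesions(desk_mask, les1)
  b <- place_lesions(desk_mask, les1)
  expect_identical(a, b)
  c2 <- place_lesions(desk_mask, lesion_spec(1, 0.5, 0.10, "even", seed = 8L))
  expect_true(nrow(a) != nrow(c2) || any(a != c2))
  expect_lt(abs(attr(c2, "achieved_occupancy") -
                  attr(a, "achieved_occupancy")), 0.005)
})

test_that("distribution 8 realises a 24% total ventilation reduction", {
  les <- lesion_spec(2, 0.5, 0.48, "even", seed = 1L)
  cen <- place_lesions(desk_mask, les)
  act <- build_activity(desk_mask, cen, les)
  expect_lt(abs(attr(act, "achieved_reduction_percent") - 24), 0.5)
  # zero-activity lesions are exactly zero
  les0 <- lesion_spec(1, 0, 0.10, "even", seed = 1L)
  act0 <- build_activity(desk_mask, place_lesions(desk_mask, les0), les0)
  expect_true(any(act0[as.logical(desk_mask)] == 0))
})

test_that("a lesion centre outside the mask is rejected", {
  les <- lesion_spec(1, 0.5, 0.1)
  out <- matrix(c(1.2, 1.2, 1.2), 1, dimnames = list(NULL, c("x", "y", "z")))
  expect_error(build_activity(desk_mask, out, les), "outside the lung")
})

test_that("motion blur conserves activity and widens a delta axially", {
  act <- uniform_activity(toy_ellipsoid())
  expect_identical(apply_motion_blur(act, 0, 0), act)
  blurred <- apply_motion_blur(act, 10, 1)
  expect_lt(abs(sum(blurred) - sum(act)) / sum(act), 0.001)
  # under constant amplitude (pure translation) the deep interior of a
  # uniform field is unchanged; depth-varying amplitude compresses tissue,
  # so translation invariance only holds for basal == apical
  shifted <- apply_motion_blur(act, 6.6, 6.6)
  expect_lt(abs(sum(shifted) - sum(act)) / sum(act), 0.001)
  expect_equal(shifted[13:20, 13:20, 14:19], act[13:20, 13:20, 14:19],
               tolerance = 1e-9)
  # a delta spreads over about twice the local amplitude
  arr <- array(0, dim = c(9, 9, 41)); arr[5, 5, 21] <- 1
  dl <- activity_volume(arr, 6.6, "phantom")
  A_mm <- 26.4                        # 4 voxels
  bl <- apply_motion_blur(dl, A_mm, A_mm)
  support <- range(which(bl[5, 5, ] > 1e-6))
  expect_equal(diff(support) * 6.6, 2 * A_mm, tolerance = 0.3)
  expect_lt(abs(sum(bl) - 1), 0.001)
})

test_that("attenuation map assigns lung, soft-tissue and air coefficients", {
  mu <- build_attenuation(desk_spec, desk_mask)
  expect_true(all(mu[as.logical(desk_mask)] == 0.04))
  expect_identical(mu[1, 1, 1], 0)
  expect_true(any(mu == 0.16))
  vals <- sort(unique(as.numeric(mu)))
  expect_identical(vals, c(0, 0.04, 0.16))
})
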