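test_that("OSEM localises a point source and stays nonnegative", {
  n <- 24L
  arr <- array(0, dim = c(n, n, n)); arr[13, 15, 11] <- 10
  act <- activity_volume(arr, 6.6, "phantom")
  geom <- acquisition_geometry(n_angles = 16L, pitch_mm = 6.6, fwhm_mm = 0)
  proj <- forward_project(act, geom)
  rec <- osem(proj, geom, recon_settings(iterations = 4L, subsets = 4L))
  expect_true(all(rec >= 0))
  expect_equal(which(rec == max(rec), arr.ind = TRUE)[1, ],
               c(dim1 = 13, dim2 = 15, dim3 = 11), ignore_attr = TRUE)
})

test_that("all-zero projections reconstruct to zero", {
  geom <- acquisition_geometry(n_angles = 8L, pitch_mm = 6.6, fwhm_mm = 0)
  proj <- structure(list(counts = array(0, dim = c(16, 16, 8)),
                         angles_deg = geom$angles_deg, pitch_mm = 6.6,
                         fwhm_mm = 0, total_counts = 0, poisson = FALSE),
                    class = "projection_set")
  rec <- osem(proj, geom, recon_settings(iterations = 1L, subsets = 2L))
  expect_true(all(rec == 0))
})

test_that("iterating OSEM reduces the reconstruction error monotonically
           in likelihood and improves on one iteration", {
  act <- uniform_activity(toy_ellipsoid(32L, semi = c(8, 10, 11)))
  geom <- acquisition_geometry(n_angles = 16L, pitch_mm = 6.6, fwhm_mm = 0)
  proj <- forward_project(act, geom)
  nrmse <- function(rec) {
    sqrt(mean((lungcv:::as_plain_array(rec) -
                 lungcv:::as_plain_array(act))^2)) / mean(act[act > 0])
  }
  r1 <- osem(proj, geom, recon_settings(iterations = 1L, subsets = 8L))
  r10 <- osem(proj, geom, recon_settings(iterations = 10L, subsets = 8L,
                                         track_loglik = TRUE))
  expect_lt(nrmse(r10), nrmse(r1))
  ll <- attr(r10, "loglik")
  expect_identical(length(ll), 10L)
  expect_true(all(diff(ll) > -1e-6 * abs(ll[-length(ll)])))
})

test_that("forward-projecting a converged reconstruction matches the data", {
  act <- uniform_activity(toy_ellipsoid(32L, semi = c(8, 10, 11)))
  geom <- acquisition_geometry(n_angles = 16L, pitch_mm = 6.6, fwhm_mm = 0)
  proj <- forward_project(act, geom)
  rec <- osem(proj, geom, recon_settings(iterations = 10L, subsets = 8L))
  refit <- forward_project(rec, geom)
  expect_lt(abs(sum(refit$counts) - sum(proj$counts)) / sum(proj$counts),
            0.01)
})

test_that("subsets must divide the angle count", {
  geom <- acquisition_geometry(n_angles = 10L, pitch_mm = 6.6, fwhm_mm = 0)
  proj <- structure(list(counts = array(1, dim = c(8, 8, 10)),
                         angles_deg = geom$angles_deg, pitch_mm = 6.6,
                         fwhm_mm = 0, total_counts = 640, poisson = FALSE),
                    class = "projection_set")
  expect_error(osem(proj, geom, recon_settings(subsets = 4L)),
               "divide")
})

test_that("Butterworth gain matches the closed form at f = 0, fc and 2fc", {
  n <- 32L
  pitch_mm <- 3.125                       # grid frequencies at k/10 cm^-1
  arr <- array(0, dim = c(n, n, n)); arr[1, 1, 1] <- 1
  vol <- activity_volume(arr, pitch_mm, "phantom")
  filt <- butterworth3d(vol, cutoff_cm = 0.5, order = 3L)
  H <- Re(fft(lungcv:::as_plain_array(filt)))
  expect_equal(H[1, 1, 1], 1, tolerance = 1e-9)              # DC
  expect_equal(H[6, 1, 1], 1 / sqrt(2), tolerance = 1e-9)    # f = fc
  expect_equal(H[11, 1, 1], (1 + 2^6)^(-1 / 2), tolerance = 1e-9)  # f = 2fc
  # numeric values frozen from the filter equation
  expect_equal(H[6, 1, 1], 0.7071068, tolerance = 1e-6)
  expect_equal(H[11, 1, 1], 0.1240347, tolerance = 1e-6)
})

test_that("filtering preserves the mean and composes as squared gain", {
  set.seed(7)
  arr <- array(rpois(16^3, 50), dim = c(16, 16, 16))
  vol <- activity_volume(arr, 6.6, "phantom")
  f1 <- butterworth3d(vol, 0.5, 3L)
  expect_equal(mean(f1), mean(vol), tolerance = 1e-9)
  f2 <- butterworth3d(f1, 0.5, 3L)
  sp_in <- fft(lungcv:::as_plain_array(vol))
  sp_out <- fft(lungcv:::as_plain_array(f2))
  gain1 <- fft(lungcv:::as_plain_array(
    butterworth3d(activity_volume(
      array(c(1, rep(0, 16^3 - 1)), dim = c(16, 16, 16)), 6.6, "phantom"),
      0.5, 3L)))
  expect_equal(sp_out, sp_in * gain1^2, tolerance = 1e-8)
  expect_error(butterworth3d(vol, -1, 3L), "positive")
})

test_that("the reconstructed point source width tracks the system blur", {
  n <- 64L
  arr <- array(0, dim = c(n, n, n)); arr[33, 33, 33] <- 100
  act <- activity_volume(arr, 6.6, "phantom")
  geom <- acquisition_geometry(n_angles = 32L, pitch_mm = 6.6, fwhm_mm = 12)
  proj <- forward_project(act, geom)
  rec <- butterworth3d(osem(proj, geom, recon_settings()), 0.5, 3L)
  prof <- rec[, 33, 33]
  pk <- which.max(prof); half <- prof[pk] / 2
  l <- pk; while (prof[l] > half) l <- l - 1
  r <- pk; while (prof[r] > half) r <- r + 1
  xl <- l + (half - prof[l]) / (prof[l + 1] - prof[l])
  xr <- r - (half - prof[r]) / (prof[r - 1] - prof[r])
  fwhm_mm <- (xr - xl) * 6.6
  expect_equal(which(rec == max(rec), arr.ind = TRUE)[1, ],
               c(dim1 = 33, dim2 = 33, dim3 = 33), ignore_attr = TRUE)
  expect_lt(abs(fwhm_mm - 12) / 12, 0.25)
})
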