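geom_sharp <- function(n_angles, pitch = 6.6) {
  acquisition_geometry(n_angles = n_angles, pitch_mm = pitch, fwhm_mm = 0)
}

test_that("every projection of a point source carries its full activity", {
  arr <- array(0, dim = c(16, 16, 16)); arr[9, 8, 8] <- 5
  act <- activity_volume(arr, 6.6, "phantom")
  proj <- forward_project(act, geom_sharp(8L))
  totals <- apply(proj$counts, 3, sum)
  expect_equal(totals, rep(5, 8), tolerance = 1e-9)
})

test_that("projection is linear and conserves counts per view under blur", {
  act <- uniform_activity(toy_ellipsoid(24L, semi = c(6, 7, 8)))
  geom <- acquisition_geometry(n_angles = 12L, pitch_mm = 6.6, fwhm_mm = 12)
  p1 <- forward_project(act, geom)
  p2 <- forward_project(activity_volume(3.5 * lungcv:::as_plain_array(act),
                                        6.6, "phantom"), geom)
  expect_equal(p2$counts, 3.5 * p1$counts, tolerance = 1e-12)
  totals <- apply(p1$counts, 3, sum)
  expect_lt(diff(range(totals)) / mean(totals), 2e-3)
})

test_that("projections of a uniform sphere follow the chord-length profile", {
  mask <- digital_sphere(32L, r_vox = 9, pitch_mm = 10)
  act <- uniform_activity(mask)
  proj <- forward_project(act, geom_sharp(4L, pitch = 10))
  prof <- proj$counts[, 17, 1]                 # central row of the 0-deg view
  u <- seq_len(32) - 16.5
  chord <- ifelse(abs(u) < 9, 2 * sqrt(pmax(9^2 - u^2, 0)), 0)
  inner <- abs(u) < 0.7 * 9
  expect_lt(max(abs(prof[inner] - chord[inner]) / chord[inner]), 0.12)
  expect_equal(prof[16], max(prof), tolerance = 1e-12)  # max at the centre
  expect_equal(prof, rev(prof), tolerance = 1e-12)      # symmetric profile
})

test_that("attenuated rays match the closed-form line integral", {
  n <- 32L
  arr <- array(0, dim = c(n, n, n))
  arr[8:24, 12:20, 12:20] <- 1                 # slab along the ray axis
  act <- activity_volume(arr, 6.6, "phantom")
  mu <- array(0, dim = c(n, n, n))
  mu[8:24, 12:20, 12:20] <- 0.16
  mu <- structure(mu, pitch_mm = 6.6)
  geom <- acquisition_geometry(n_angles = 1L, pitch_mm = 6.6, fwhm_mm = 0)
  proj <- forward_project(act, geom, attenuation = mu)
  # analytic: integral of exp(-mu x) over the slab, in voxel-value units
  T_cm <- 17 * 0.66
  expected <- (1 - exp(-0.16 * T_cm)) / 0.16 / 0.66
  expect_equal(proj$counts[16, 16, 1], expected, tolerance = 0.02)
  # unattenuated ray sums the chord exactly
  p0 <- forward_project(act, geom)
  expect_equal(p0$counts[16, 16, 1], 17, tolerance = 1e-9)
})

test_that("count scaling is global, exact and linear", {
  act <- uniform_activity(toy_ellipsoid(24L, semi = c(6, 7, 8)))
  proj <- forward_project(act, geom_sharp(8L))
  sc <- scale_to_counts(proj, 3.635e6)
  expect_lt(abs(sum(sc$counts) - 3.635e6) / 3.635e6, 1e-9)
  same <- scale_to_counts(proj, sum(proj$counts))
  expect_equal(same$counts, proj$counts, tolerance = 1e-12)
  half <- scale_to_counts(sc, 3.635e6 / 2)
  expect_equal(half$counts, sc$counts / 2, tolerance = 1e-12)
  zero <- proj; zero$counts[] <- 0
  expect_error(scale_to_counts(zero, 10), "all-zero")
})

test_that("Poisson realisations have the right moments and reproducibility", {
  base <- structure(list(counts = array(100, dim = c(1, 1, 1000)),
                         angles_deg = 0, pitch_mm = 1, fwhm_mm = 0,
                         total_counts = 1e5, poisson = FALSE),
                    class = "projection_set")
  draws <- poisson_realise(base, 99L)$counts
  expect_lt(abs(mean(draws) - 100), 1)
  expect_lt(abs(var(as.numeric(draws)) - 100), 10)
  expect_identical(poisson_realise(base, 99L)$counts, draws)
  expect_false(identical(poisson_realise(base, 100L)$counts, draws))
  zero <- base; zero$counts[] <- 0
  expect_true(all(poisson_realise(zero, 1L)$counts == 0))
  neg <- base; neg$counts[1] <- -1
  expect_error(poisson_realise(neg, 1L), "nonnegative")
})

test_that("pixelwise means of many realisations converge to the set means", {
  set.seed(314)
  means <- matrix(runif(256, 20, 80), 16, 16)
  base <- structure(list(counts = array(means, dim = c(16, 16, 1)),
                         angles_deg = 0, pitch_mm = 1, fwhm_mm = 0,
                         total_counts = sum(means), poisson = FALSE),
                    class = "projection_set")
  acc <- array(0, dim = c(16, 16, 1))
  nreal <- 1000L
  for (i in seq_len(nreal)) {
    acc <- acc + poisson_realise(base, 1000L + i)$counts
  }
  emp <- acc[, , 1] / nreal
  se <- sqrt(means / nreal)
  expect_true(all(abs(emp - means) < 6 * se))
})

test_that("high-count pixel CV across 20 realisations is about 1/sqrt(mean)", {
  mu <- 44
  base <- structure(list(counts = array(mu, dim = c(1, 1, 1)),
                         angles_deg = 0, pitch_mm = 1, fwhm_mm = 0,
                         total_counts = mu, poisson = FALSE),
                    class = "projection_set")
  vals <- vapply(1:20, function(i) poisson_realise(base, 40L + i)$counts[1],
                 1)
  cv <- 100 * sd(vals) / mean(vals)
  # Poisson predicts 100/sqrt(44) ~ 15%; 20 samples estimate it coarsely
  expect_lt(abs(cv - 100 / sqrt(mu)), 7)
})
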