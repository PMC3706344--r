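# Shared fixtures. Everything is generated in code; sizes are kept small so
# the default suite runs in minutes.

# desk phantom used by several module tests (built once per test run)
desk_spec <- phantom_spec()

desk_mask <- local({
  build_lung_mask(desk_spec)
})

# a small solid digital ellipsoid mask for projector/recon toys
toy_ellipsoid <- function(n = 32L, pitch_mm = 6.6, semi = c(8, 10, 11)) {
  ctr <- (n + 1) / 2
  x <- seq_len(n) - ctr
  arr <- array(FALSE, dim = c(n, n, n))
  X <- array(rep(x, times = n * n), dim = c(n, n, n))
  Y <- array(rep(rep(x, each = n), times = n), dim = c(n, n, n))
  Z <- array(rep(x, each = n * n), dim = c(n, n, n))
  arr <- (X / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2 <= 1
  lung_mask(arr, pitch_mm = pitch_mm)
}

uniform_activity <- function(mask) {
  arr <- array(0, dim = dim(mask))
  arr[as.logical(mask)] <- 1
  activity_volume(arr, pitch_mm = voxel_pitch(mask), provenance = "phantom")
}

# solid digital sphere mask
digital_sphere <- function(n, r_vox, pitch_mm = 10) {
  ctr <- (n + 1) / 2
  x <- seq_len(n) - ctr
  X <- array(rep(x, times = n * n), dim = c(n, n, n))
  Y <- array(rep(rep(x, each = n), times = n), dim = c(n, n, n))
  Z <- array(rep(x, each = n * n), dim = c(n, n, n))
  lung_mask(X^2 + Y^2 + Z^2 <= r_vox^2, pitch_mm = pitch_mm)
}
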