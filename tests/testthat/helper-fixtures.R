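## Small, fast synthetic worlds used across the unit tests. The full-size
## presets are exercised in test-acceptance.R.

small_tissue <- function(seed = 1L, fold_depth_px = 8, nx = 200L, ny = 3L,
                         nz = 48L, roi_height_um = 6) {
  tissue_spec(nx = nx, ny = ny, nz = nz, surface_base_z = 10,
              fold_center_x = 80, fold_depth_px = fold_depth_px,
              fold_sigma_px = 8, roi_height_um = roi_height_um, seed = seed)
}

small_signal <- function(noise_sigma = 0.05, decay_rate_mu = 0.15,
                         source_boundary_l = 16.8, ...) {
  signal_spec(decay_rate_mu = decay_rate_mu,
              source_boundary_l = source_boundary_l,
              sigmoid_steepness = 0.6, noise_sigma = noise_sigma, ...)
}

## band-mean of a channel over the ground-truth band rows (the generator's
## own band definition), per column
truth_band_mean <- function(stack, truth, channel, y = 0) {
  pl <- xz_plane(stack, y, channel)
  vapply(seq_len(ncol(pl)), function(x) {
    rows <- (truth$band_rows[x, "start"]:truth$band_rows[x, "end"]) + 1L
    mean(pl[rows, x])
  }, 0)
}

## junctional-channel-only stack with an arbitrary per-plane surface,
## for fold-tracking tests: surface_fun(y) returns a(x) (0-based z)
junctional_stack <- function(surface_fun, nx = 200L, ny = 5L, nz = 48L,
                             noise_sigma = 0, seed = 1L) {
  set.seed(seed)
  zc <- seq_len(nz) - 1
  data <- array(0, dim = c(nz, nx, ny, 1L))
  for (y in seq_len(ny)) {
    a <- surface_fun(y - 1)
    pl <- 0.05 + 0.9 * exp(-outer(zc, a, "-")^2 / (2 * 1.6^2))
    if (noise_sigma > 0)
      pl <- pl + matrix(rnorm(nz * nx, 0, noise_sigma), nz, nx)
    data[, , y, 1] <- pl
  }
  image_stack(data, channels = "junctional")
}

gaussian_bump <- function(x, center, depth, sigma) {
  depth * exp(-(x - center)^2 / (2 * sigma^2))
}
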