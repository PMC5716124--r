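# Small, fast fixtures used across test files.

# coarse scan geometry: same fan field of view as the desk geometry
# (409.6 mm active width) but 128 detector pixels, no detector blur
tiny_geometry <- function(psf = 0) {
  scan_geometry(detector_pixels = 128L, pixel_pitch = 3.2, psf_sigma_mm = psf)
}

tiny_settings <- function(...) {
  recon_settings(grid_size = 128L, pixel_size_mm = 2.2, ...)
}

tiny_water <- function(spacing = 2) make_cylinder_phantom(spacing = spacing)

full_protocol <- function(n = 60, mu = 13.5)
  acquisition_protocol("full", 180, 180, 360, n, mu)

short_protocol <- function(n = 50, mu = 13.5)
  acquisition_protocol("short", 270, 110, 200, n, mu)

# synthetic erf-blurred horizontal edge image (water below y = 0),
# grid centered, returns matrix [x index, y index]
erf_edge_slice <- function(n = 121, pixel = 1, sigma = 1.2, height = 0.005,
                           noise_sd = 0) {
  ys <- (seq_len(n) - (n + 1) / 2) * pixel
  sl <- matrix(rep(height * stats::pnorm(-ys / sigma), each = n), n, n)
  if (noise_sd > 0) sl <- sl + matrix(rnorm(n * n, sd = noise_sd), n, n)
  sl
}

# closed-form f50 of a Gaussian LSF with width sigma
f50_closed_form <- function(sigma) sqrt(log(2) / 2) / (pi * sigma)

# brute-force per-pixel ROI statistics (independent oracle): explicit loops
# collect every masked pixel; sums use base sum() so the accumulator
# precision matches the tested implementation
brute_stats <- function(slice, mask) {
  v <- c()
  for (i in seq_len(nrow(slice))) for (j in seq_len(ncol(slice)))
    if (mask[i, j]) v <- c(v, slice[i, j])
  n <- length(v)
  m <- sum(v) / n
  dev <- numeric(n)
  for (k in seq_len(n)) dev[k] <- (v[k] - m)^2
  list(mean = m, stdev = sqrt(sum(dev) / (n - 1)), n = n)
}
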