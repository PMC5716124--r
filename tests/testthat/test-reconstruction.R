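test_that("full-scan redundancy weights are uniform 1/2", {
  ang <- seq(0, 359, by = 1)
  W <- parker_weights(ang, 20, seq(-10, 10, length.out = 11))
  expect_true(all(W == 0.5))
})

test_that("an arc shorter than 180 + fan is refused", {
  ang <- seq(270, by = 0.5, length.out = 380)  # 190 deg
  expect_error(parker_weights(ang, 20, c(-5, 0, 5)), "insufficient")
})

test_that("short-scan weights taper only inside the redundancy wedges", {
  # 200 deg arc, 20 deg fan: wedges are 2*(gm + g) wide at the start and end
  ang <- seq(270, by = 0.1, length.out = 2000)
  gamma <- c(-8, -3, 0, 3, 8)
  W <- parker_weights(ang, 20, gamma)
  expect_true(all(W >= 0 & W <= 1))
  bprog <- (seq_along(ang) - 1) * 0.1  # degrees along the arc
  for (j in seq_along(gamma)) {
    # gantry-increasing scan: effective fan angle is -gamma
    ge <- -gamma[j]
    interior <- bprog > 2 * (10 + ge) + 0.2 & bprog < 180 + 2 * ge - 0.2
    expect_true(all(W[interior, j] == 1))
    wedge <- bprog < 2 * (10 + ge) - 0.2 | bprog > 180 + 2 * ge + 0.2
    expect_true(all(W[wedge, j] < 1))
  }
  # wedge samples are strictly inside (0, 1)
  expect_true(any(W < 1 & W > 0))
})

test_that("complementary ray pairs carry unit total weight", {
  # CCW scan so the progression variable and the fan angle share sign
  step <- 0.05
  ang <- seq(270, by = -step, length.out = 200 / step)
  gammas <- c(1, 2.5, 4, 6, 8.75)
  W <- parker_weights(ang, 20, c(gammas, -gammas))
  n <- length(ang)
  for (j in seq_along(gammas)) {
    g <- gammas[j]
    off <- round((180 - 2 * g) / step)   # complement: beta + 180 - 2*gamma
    i <- seq_len(n - off)
    sums <- W[i, j] + W[i + off, j + length(gammas)]
    expect_lt(max(abs(sums - 1)), 1e-10)
  }
})

test_that("ramp filtering kills DC and is linear", {
  st <- tiny_settings(filter_window = "ramp", filter_cutoff = 1)
  const <- matrix(3.7, 64, 5)
  q <- filter_projections(const, st, du = 1)
  # a constant has no frequency content away from DC: the response is
  # near zero everywhere except the aperture edges of the finite profile
  expect_lt(max(abs(q[17:48, ])), 3.7 * 0.005)
  set.seed(2)
  p <- matrix(rnorm(64 * 5), 64, 5)
  expect_equal(filter_projections(3 * p, st, du = 1),
               3 * filter_projections(p, st, du = 1))
})

test_that("an impulse is filtered to the discrete ramp kernel", {
  st <- tiny_settings(filter_window = "ramp", filter_cutoff = 1)
  n <- 64
  p <- matrix(0, n, 1); p[33, 1] <- 1
  q <- filter_projections(p, st, du = 1)
  expect_equal(q[33, 1], 0.25, tolerance = 1e-10)
  expect_equal(q[34, 1], -1 / pi^2, tolerance = 1e-10)
  expect_equal(q[32, 1], -1 / pi^2, tolerance = 1e-10)
  expect_equal(q[35, 1], 0, tolerance = 1e-12)
})

test_that("noiseless full-scan reconstruction recovers water attenuation", {
  ph <- tiny_water()
  st <- tiny_settings()
  scn <- simulate_scan(ph, full_protocol(180), tiny_geometry(),
                       noiseless = TRUE)
  vol <- fbp_reconstruct(scn, st)
  sl <- vol$slices
  ctr <- sl[60:70, 60:70]
  expect_equal(mean(ctr), 0.005, tolerance = 0.03)
  # ideal uniform cylinder passes the uniformity metric comfortably
  rois <- water_phantom_rois(220)
  expect_gte(uniformity(sl, rois, st$pixel_size_mm), 98)
})

test_that("short-scan and full-scan reconstructions agree (small scale)", {
  ph <- tiny_water()
  st <- tiny_settings()
  geo <- tiny_geometry()
  slf <- fbp_reconstruct(simulate_scan(ph, full_protocol(180), geo,
                                       noiseless = TRUE), st)$slices
  sls <- fbp_reconstruct(simulate_scan(ph, short_protocol(100), geo,
                                       noiseless = TRUE), st)$slices
  wmask <- roi_mask(circle_roi(c(0, 0), 190), dim(slf), st$pixel_size_mm)
  rmse <- sqrt(mean((sls[wmask] - slf[wmask])^2))
  expect_lt(rmse / 0.005, 0.02)
})

test_that("reconstruction is linear in the line integrals", {
  ph <- tiny_water()
  geo <- tiny_geometry()
  pr <- full_protocol(60)
  ang <- protocol_angles(pr)
  p <- cbctiq:::forward_project_all(ph, geo, ang)
  st <- tiny_settings()
  v1 <- fbp_reconstruct(p, st, geometry = geo, angles = ang,
                        line_integrals = TRUE)$slices
  v2 <- fbp_reconstruct(2 * p, st, geometry = geo, angles = ang,
                        line_integrals = TRUE)$slices
  expect_equal(v2, 2 * v1, tolerance = 1e-12)
  v0 <- fbp_reconstruct(0 * p, st, geometry = geo, angles = ang,
                        line_integrals = TRUE)$slices
  expect_true(all(v0 == 0))
})

test_that("reconstructed noise scales as one over sqrt(total MU)", {
  ph <- tiny_water()
  geo <- tiny_geometry()
  st <- tiny_settings()
  rois <- water_phantom_rois(220)
  ang <- protocol_angles(full_protocol(90))
  ideal <- cbctiq:::forward_project_all(ph, geo, ang)
  noise_at <- function(mu, seeds) {
    pr <- full_protocol(90, mu = mu)
    vapply(seeds, function(s) {
      scn <- add_exposure_noise(ideal, pr, geo, ang, fluence_per_mu = 2e4,
                                seed = s)
      noise_metric(fbp_reconstruct(scn, st)$slices, rois, st$pixel_size_mm)
    }, 0)
  }
  r <- mean(noise_at(6.75, 1:10)) / mean(noise_at(13.5, 1:10))
  expect_equal(r, sqrt(2), tolerance = 0.1)
})

test_that("display binning averages groups of round(display/native) slices", {
  sl <- array(rep(1:30, each = 4), dim = c(2, 2, 30))
  vol <- cbctiq:::new_recon_volume(sl, 1, 1)
  out <- bin_average_slices(vol, 4.8)
  expect_equal(dim(out$slices)[3], 6L)
  expect_equal(out$slice_thickness_mm, 5)
  expect_equal(out$slices[1, 1, ], c(3, 8, 13, 18, 23, 28))
  # identity when display equals native thickness
  idp <- bin_average_slices(vol, 1)
  expect_equal(idp$slices, sl)
  expect_error(bin_average_slices(vol, 0.5), ">=")
})

test_that("volumes round-trip through TIFF + YAML", {
  ph <- tiny_water()
  st <- tiny_settings()
  vol <- fbp_reconstruct(simulate_scan(ph, full_protocol(30), tiny_geometry(),
                                       noiseless = TRUE), st)
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume_tiff(vol, path)
  back <- read_volume_tiff(path)
  expect_equal(back$slices, vol$slices, tolerance = 1e-5)
  expect_equal(back$pixel_size_mm, vol$pixel_size_mm)
})
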