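# constant-block helper: 25 values with exact sample mean m and SD s
block25 <- function(m, s) c(rep(m + s, 12), rep(m - s, 12), m)

test_that("ROI masks match analytic areas", {
  m <- roi_mask(circle_roi(c(0, 0), 25), c(256, 256), 1)
  expect_lt(abs(sum(m) - pi * 12.5^2) / (pi * 12.5^2), 0.02)
  r <- roi_mask(ring_roi(c(0, 0), 100, 20), c(256, 256), 1)
  a <- pi * (70^2 - 50^2)
  expect_lt(abs(sum(r) - a) / a, 0.02)
  expect_error(ring_roi(c(0, 0), 100, 0), "thickness")
  expect_error(roi_mask(circle_roi(c(500, 0), 10), c(64, 64), 1), "empty")
})

test_that("the standard water-phantom ROI set has the published geometry", {
  rois <- water_phantom_rois(220)
  expect_equal(rois$center$diameter, 25)
  expect_equal(rois$water$diameter, 190)
  expect_equal(rois$periphery$thickness, 20)
  expect_equal(rois$air$inner_diameter, 230)
  # periphery stays inside the phantom; air ring outside it
  expect_lte(rois$periphery$inner_diameter / 2 + rois$periphery$thickness, 110)
  expect_gte(rois$air$inner_diameter / 2, 110)
})

test_that("roi_stats refuses tiny ROIs", {
  sl <- matrix(1, 16, 16)
  m <- matrix(FALSE, 16, 16); m[1:4, 1:4] <- TRUE
  expect_error(roi_stats(sl, m), "25")
})

test_that("metrics agree with brute-force per-pixel recomputation", {
  set.seed(401)
  for (rep in 1:5) {
    sl <- matrix(rnorm(256, mean = 10), 16, 16)
    masks <- lapply(1:4, function(i) {
      m <- matrix(FALSE, 16, 16)
      m[sample(256, 40)] <- TRUE
      m
    })
    names(masks) <- c("center", "periphery", "water", "air")
    ref <- lapply(masks, function(m) brute_stats(sl, m))
    u_ref <- (1 - abs(ref$center$mean - ref$periphery$mean) /
                (ref$water$mean - ref$air$mean)) * 100
    n_ref <- ref$water$stdev / (ref$water$mean - ref$air$mean) * 100
    c_ref <- abs(ref$center$mean - ref$periphery$mean) /
      (0.5 * (ref$center$stdev + ref$periphery$stdev))
    if (ref$water$mean - ref$air$mean > 0) {
      expect_equal(uniformity(sl, masks, 1), u_ref, tolerance = 1e-12)
      expect_equal(noise_metric(sl, masks, 1), n_ref, tolerance = 1e-12)
    }
    expect_equal(cnr(sl, masks$center, masks$periphery, 1), c_ref,
                 tolerance = 1e-12)
  }
})

test_that("uniformity follows the normalized center-periphery difference", {
  sl <- matrix(0, 30, 30)
  masks <- list(center = matrix(FALSE, 30, 30), periphery = matrix(FALSE, 30, 30),
                water = matrix(FALSE, 30, 30), air = matrix(FALSE, 30, 30))
  masks$center[1:5, 1:5] <- TRUE;      sl[1:5, 1:5] <- 90
  masks$periphery[1:5, 6:10] <- TRUE;  sl[1:5, 6:10] <- 100
  masks$water[6:10, 1:5] <- TRUE;      sl[6:10, 1:5] <- 95
  masks$air[6:10, 6:10] <- TRUE;       sl[6:10, 6:10] <- 5
  expect_equal(uniformity(sl, masks, 1), (1 - 10 / 90) * 100,
               tolerance = 1e-12)
  # perfectly uniform slice scores 100
  sl2 <- sl; sl2[masks$center] <- 95; sl2[masks$periphery] <- 95
  expect_equal(uniformity(sl2, masks, 1), 100)
  # equal water and air means break the normalization
  sl3 <- sl; sl3[masks$air] <- 95
  expect_error(uniformity(sl3, masks, 1), "contrast")
})

test_that("noise metric is the water SD over the water-air contrast", {
  sl <- matrix(0, 30, 30)
  masks <- list(water = matrix(FALSE, 30, 30), air = matrix(FALSE, 30, 30))
  masks$water[1, 1:25] <- TRUE; sl[1, 1:25] <- block25(105, 2)
  masks$air[2, 1:25] <- TRUE;   sl[2, 1:25] <- 5
  expect_equal(noise_metric(sl, masks, 1), 2.0, tolerance = 1e-12)
  # constant water region has zero noise
  sl[1, 1:25] <- 105
  expect_equal(noise_metric(sl, masks, 1), 0)
  # invariant under a positive gain
  sl[1, 1:25] <- block25(105, 2)
  expect_equal(noise_metric(3.5 * sl, masks, 1),
               noise_metric(sl, masks, 1), tolerance = 1e-12)
})

test_that("CNR divides the contrast by the averaged ROI SDs", {
  sl <- matrix(0, 30, 30)
  ins <- matrix(FALSE, 30, 30); ins[1, 1:25] <- TRUE
  bg <- matrix(FALSE, 30, 30);  bg[2, 1:25] <- TRUE
  sl[1, 1:25] <- block25(120, 4)
  sl[2, 1:25] <- block25(100, 6)
  expect_equal(cnr(sl, ins, bg, 1), 20 / 5, tolerance = 1e-12)
  # translation invariance
  expect_equal(cnr(sl + 42, ins, bg, 1), cnr(sl, ins, bg, 1),
               tolerance = 1e-12)
  # equal means give zero
  sl[2, 1:25] <- block25(120, 6)
  expect_equal(cnr(sl, ins, bg, 1), 0, tolerance = 1e-12)
  # noiseless input with contrast is flagged
  sl[1, 1:25] <- 120; sl[2, 1:25] <- 100
  expect_error(cnr(sl, ins, bg, 1), "noiseless")
})

test_that("slice aggregation reports mean and sample SD", {
  a <- aggregate_slices(1:6)
  expect_equal(a$mean, 3.5)
  expect_equal(a$sd, 1.8708287, tolerance = 1e-6)
  b <- aggregate_slices(rep(4.2, 6))
  expect_equal(b$sd, 0)
  expect_warning(c1 <- aggregate_slices(5, n_slices = 1), "SD")
  expect_equal(c1$sd, 0)
  expect_error(aggregate_slices(1:3, n_slices = 6), "need 6")
})

test_that("CNR rises with electron-density contrast on the pelvis phantom", {
  # seed-averaged CNR ordered by |rED - 1| at a fixed protocol
  ph <- make_pelvis_phantom(spacing = 2, semi_axes = c(130, 95),
                            start_angle_deg = 45)
  geo <- tiny_geometry(psf = 2)
  st <- tiny_settings()
  pr <- short_protocol(100)
  ang <- protocol_angles(pr)
  ideal <- cbctiq:::forward_project_all(ph, geo, ang)
  centers <- ph$meta$insert_centers
  per_seed <- sapply(1:10, function(s) {
    scn <- add_exposure_noise(ideal, pr, geo, ang, seed = 1000 + s,
                              n_binned = 5L)
    sl <- fbp_reconstruct(scn, st)$slices
    vapply(names(centers), function(nm) {
      rois <- insert_rois(centers[[nm]], roi_diameter = 25)
      cnr(sl, rois$insert, rois$background, st$pixel_size_mm)
    }, 0)
  })
  vals <- rowMeans(per_seed)
  red <- c(muscle = 1.043, trabecular_bone = 1.117, dense_bone = 1.513,
           lung_exhale = 0.459)
  contrast <- abs(red[names(vals)] - 1)
  expect_equal(order(vals), order(contrast))
})
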