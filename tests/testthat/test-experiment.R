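# small phantom/geometry set shared by the driver tests
driver_fixture <- function() {
  list(
    phantoms = list(
      water  = make_cylinder_phantom(spacing = 2),
      half   = make_cylinder_phantom(spacing = 2, fill = "half"),
      # no dense-bone insert: its 8 mm CNR ROI needs finer pixels than this
      # coarse fixture provides
      pelvis = make_pelvis_phantom(spacing = 2, semi_axes = c(130, 95),
                                   start_angle_deg = 45,
                                   inserts = default_inserts()[c(1, 4)])
    ),
    geometry = tiny_geometry(psf = 2),
    settings = tiny_settings(),
    protocols = list(full_protocol(40), short_protocol(30, mu = 13.5))
  )
}

test_that("a sweep produces one report per protocol with all metrics", {
  fx <- driver_fixture()
  reps <- run_protocol_sweep(fx$protocols, fx$phantoms, fx$geometry,
                             fx$settings, n_seeds = 2L, n_slices = 2L)
  expect_length(reps, 2)
  expect_named(reps, c("full", "short"))
  r <- reps$full
  expect_null(r$error)
  expect_true(all(c("uniformity", "noise", "cnr", "f50") %in% names(r)))
  expect_equal(dim(r$noise$values), c(2, 2))
  expect_named(r$cnr, c("muscle", "lung_exhale"))
  expect_true(r$uniformity$mean > 90 && r$uniformity$mean <= 100)
  expect_true(r$noise$mean > 0)
  expect_true(r$f50$mean > 0)
  # summary and tidy tables agree with the stored values
  s <- sweep_summary(reps)
  expect_equal(s[s$protocol == "full" & s$metric == "noise", "mean"],
               r$noise$mean)
  tbl <- sweep_metrics_table(reps)
  expect_equal(mean(tbl[tbl$protocol == "full" & tbl$metric == "noise",
                        "value"]),
               r$noise$mean)
})

test_that("sweeps are deterministic given the base seed", {
  fx <- driver_fixture()
  a <- run_protocol_sweep(fx$protocols[1], fx$phantoms["water"], fx$geometry,
                          fx$settings, n_seeds = 2L, n_slices = 2L,
                          measures = "noise")
  b <- run_protocol_sweep(fx$protocols[1], fx$phantoms["water"], fx$geometry,
                          fx$settings, n_seeds = 2L, n_slices = 2L,
                          measures = "noise")
  expect_identical(sweep_metrics_table(a), sweep_metrics_table(b))
  expect_identical(a$full$fingerprint, b$full$fingerprint)
})

test_that("per-protocol seed derivation is stable under list extension", {
  fx <- driver_fixture()
  alone <- run_protocol_sweep(fx$protocols[2], fx$phantoms["water"],
                              fx$geometry, fx$settings, n_seeds = 2L,
                              n_slices = 2L, measures = "noise")
  both <- run_protocol_sweep(fx$protocols, fx$phantoms["water"], fx$geometry,
                             fx$settings, n_seeds = 2L, n_slices = 2L,
                             measures = "noise")
  expect_equal(alone$short$noise$values, both$short$noise$values)
})

test_that("lower total exposure raises noise in every realization", {
  fx <- driver_fixture()
  high <- full_protocol(40, mu = 13.5)
  low <- acquisition_protocol("low", 180, 180, 360, 40, 7.2)
  reps <- run_protocol_sweep(list(high, low), fx$phantoms["water"],
                             fx$geometry, fx$settings, n_seeds = 3L,
                             n_slices = 2L, measures = "noise")
  expect_true(all(reps$low$noise$values > reps$full$noise$values))
})

test_that("one failing protocol does not abort the sweep", {
  fx <- driver_fixture()
  bad <- acquisition_protocol("bad", 270, 105, 195, 30, 13.5)  # arc < 180+fan
  expect_warning(
    reps <- run_protocol_sweep(list(bad, fx$protocols[[1]]),
                               fx$phantoms["water"], fx$geometry, fx$settings,
                               n_seeds = 1L, n_slices = 2L,
                               measures = "noise"),
    "failed")
  expect_false(is.null(reps$bad$error))
  expect_null(reps$full$error)
  expect_true(is.finite(reps$full$noise$mean))
})

test_that("render_report writes three CSVs and three figures", {
  fx <- driver_fixture()
  reps <- run_protocol_sweep(fx$protocols, fx$phantoms, fx$geometry,
                             fx$settings, n_seeds = 1L, n_slices = 2L)
  out <- withr::local_tempdir()
  paths <- render_report(reps, out)
  expect_setequal(basename(paths),
                  c("uniformity_noise.csv", "uniformity_noise.png",
                    "cnr.csv", "cnr.png", "f50.csv", "f50.png"))
  expect_true(all(file.exists(paths)))
  # the plotted CSV holds exactly the report values
  d <- read.csv(file.path(out, "cnr.csv"))
  expect_equal(
    d[d$protocol == "full" & d$roi == "lung_exhale", "mean"],
    reps$full$cnr$lung_exhale$mean)
})

test_that("a sweep without CNR results skips the CNR plot with a warning", {
  fx <- driver_fixture()
  reps <- run_protocol_sweep(fx$protocols[1], fx$phantoms["water"],
                             fx$geometry, fx$settings, n_seeds = 1L,
                             n_slices = 2L, measures = "noise")
  out <- withr::local_tempdir()
  expect_warning(paths <- render_report(reps, out), "CNR")
  expect_false(any(grepl("cnr", basename(paths))))
})

test_that("insert-averaged CNR scales roughly with sqrt(total exposure)", {
  # matched MU/projection, 13.5 vs 7.2 MU total; the paper reports the
  # low-exposure CNR as ~25% lower on average over the four inserts
  ph <- make_pelvis_phantom(spacing = 2, semi_axes = c(130, 95),
                            start_angle_deg = 45)
  geo <- tiny_geometry(psf = 2)
  st <- tiny_settings()
  centers <- ph$meta$insert_centers
  mean_cnr <- function(pr) {
    ang <- protocol_angles(pr)
    ideal <- cbctiq:::forward_project_all(ph, geo, ang)
    per_seed <- sapply(1:10, function(s) {
      scn <- add_exposure_noise(ideal, pr, geo, ang, seed = 400 + s,
                                n_binned = 5L)
      sl <- fbp_reconstruct(scn, st)$slices
      vapply(names(centers), function(nm) {
        rois <- insert_rois(centers[[nm]], roi_diameter = 25)
        cnr(sl, rois$insert, rois$background, st$pixel_size_mm)
      }, 0)
    })
    rowMeans(per_seed)
  }
  prs <- mvcbct_protocols()
  ratio <- mean(mean_cnr(prs[["5"]]) / mean_cnr(prs[["9"]]))
  expect_equal(ratio, sqrt(13.5 / 7.2), tolerance = 0.15)
})
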