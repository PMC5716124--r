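# FNV-1a string hash, kept below 2^31 so it is a valid R seed
stable_hash <- function(...) {
  s <- paste(unlist(list(...)), collapse = "|")
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(s)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h)
}

#' Desk-scale phantom set for a protocol sweep
#'
#' Water cylinder (uniformity/noise), half-filled cylinder (resolution), and
#' a pelvis contrast phantom. The pelvis outline is scaled to 130 x 95 mm
#' semi-axes so it fits the desk-scale fan field of view without truncation;
#' insert geometry (3 cm plugs on a 12 cm circle) is unchanged, with the
#' pattern rotated 45 degrees so every insert keeps the same clearance from
#' the scaled-down outline (background rings near the boundary pick up
#' edge-gradient variance otherwise).
#'
#' @param spacing voxel size, mm.
#' @param mu_water water attenuation, mm^-1.
#' @return named list: `water`, `half`, `pelvis` (`voxel_phantom`s).
#' @export
sweep_phantoms <- function(spacing = 1, mu_water = 0.005) {
  list(
    water  = make_cylinder_phantom(spacing = spacing, mu_water = mu_water),
    half   = make_cylinder_phantom(spacing = spacing, fill = "half",
                                   mu_water = mu_water),
    pelvis = make_pelvis_phantom(spacing = spacing, mu_water = mu_water,
                                 semi_axes = c(130, 95),
                                 start_angle_deg = 45)
  )
}

summarize_vals <- function(vals) {
  # vals: seeds x slices matrix of per-slice metric values
  per_seed <- apply(vals, 1, function(v) aggregate_slices(v, ncol(vals)))
  list(mean = mean(vals),
       sd = mean(vapply(per_seed, `[[`, 0, "sd")),
       seed_means = vapply(per_seed, `[[`, 0, "mean"),
       values = vals)
}

#' Run an acquisition-protocol sweep
#'
#' For each protocol: simulate the scan of each phantom (noiseless forward
#' projection computed once, then independent Poisson realizations per seed
#' and per analyzed slice), reconstruct, and measure uniformity and noise on
#' the water phantom, CNR per insert on the pelvis phantom, and f50 on the
#' half-filled phantom. Deterministic given `base_seed`; per-realization
#' seeds are derived by stable string hashing so adding protocols does not
#' shift existing results. A failing protocol is reported and skipped rather
#' than aborting the sweep.
#'
#' @param protocols list of [acquisition_protocol()].
#' @param phantoms phantom set as from [sweep_phantoms()] (entries may be
#'   omitted to skip the corresponding metrics).
#' @param geometry a [scan_geometry()].
#' @param settings a [recon_settings()].
#' @param n_seeds independent noise-realization groups per protocol.
#' @param base_seed integer master seed.
#' @param n_slices analyzed slices per group; each is an independent
#'   realization of one display slab (`round(display/native)` native slices
#'   binned, per the display-thickness convention).
#' @param fluence_per_mu detector photons per pixel per MU at zero
#'   attenuation.
#' @param measures subset of `c("noise", "cnr", "f50")` to compute.
#' @return list of `iq_report` objects (class `iq_report_list`).
#' @export
run_protocol_sweep <- function(protocols, phantoms = sweep_phantoms(),
                               geometry = desk_geometry(),
                               settings = desk_settings(),
                               n_seeds = 10L, base_seed = 20120105,
                               n_slices = 6L, fluence_per_mu = 2e4,
                               measures = c("noise", "cnr", "f50")) {
  stopifnot(length(protocols) >= 1)
  measures <- match.arg(measures, several.ok = TRUE)
  reports <- lapply(protocols, function(pr) {
    tryCatch(
      run_one_protocol(pr, phantoms, geometry, settings, n_seeds, base_seed,
                       n_slices, fluence_per_mu, measures),
      error = function(e) {
        warning(sprintf("protocol %s failed: %s", pr$name,
                        conditionMessage(e)))
        structure(list(protocol = pr, error = conditionMessage(e)),
                  class = "iq_report")
      })
  })
  names(reports) <- vapply(protocols, `[[`, "", "name")
  structure(reports, class = "iq_report_list")
}

recon_noisy_slice <- function(ideal, pr, geometry, settings, fluence, seed,
                              n_binned = 1L) {
  ps <- add_exposure_noise(ideal, pr, geometry, protocol_angles(pr),
                           fluence_per_mu = fluence, seed = seed,
                           n_binned = n_binned)
  volume_slice(fbp_reconstruct(ps, settings))
}

run_one_protocol <- function(pr, phantoms, geometry, settings, n_seeds,
                             base_seed, n_slices, fluence, measures) {
  px <- settings$pixel_size_mm
  # each analyzed slice is a display slab: round(display/native) z-uniform
  # native slices binned at the detector before reconstruction
  nbin <- max(1L, round(settings$display_thickness_mm /
                          settings$slice_thickness_mm))
  out <- list(protocol = pr, n_seeds = n_seeds, n_slices = n_slices,
              base_seed = base_seed,
              fingerprint = stable_hash(pr$name, pr$arc_length,
                                        pr$n_projections, pr$total_mu,
                                        geometry$detector_pixels,
                                        geometry$pixel_pitch,
                                        settings$grid_size, px,
                                        settings$filter_window,
                                        settings$filter_cutoff,
                                        fluence, n_seeds, n_slices, base_seed))
  if ("noise" %in% measures && !is.null(phantoms$water)) {
    ideal <- forward_project_all(phantoms$water, geometry, protocol_angles(pr))
    rois <- water_phantom_rois(phantoms$water$meta$diameter)
    u <- n <- matrix(0, n_seeds, n_slices)
    for (s in seq_len(n_seeds)) for (k in seq_len(n_slices)) {
      seed <- stable_hash(base_seed, pr$name, "water", s, k)
      sl <- recon_noisy_slice(ideal, pr, geometry, settings, fluence, seed,
                              n_binned = nbin)
      u[s, k] <- uniformity(sl, rois, px)
      n[s, k] <- noise_metric(sl, rois, px)
    }
    out$uniformity <- summarize_vals(u)
    out$noise <- summarize_vals(n)
  }
  if ("cnr" %in% measures && !is.null(phantoms$pelvis)) {
    ph <- phantoms$pelvis
    ideal <- forward_project_all(ph, geometry, protocol_angles(pr))
    centers <- ph$meta$insert_centers
    insd <- ph$meta$insert_diameter
    cnr_vals <- lapply(centers, function(.) matrix(0, n_seeds, n_slices))
    for (s in seq_len(n_seeds)) for (k in seq_len(n_slices)) {
      seed <- stable_hash(base_seed, pr$name, "pelvis", s, k)
      sl <- recon_noisy_slice(ideal, pr, geometry, settings, fluence, seed,
                              n_binned = nbin)
      for (nm in names(centers)) {
        rd <- if (nm == "dense_bone") 8 else 25
        rois <- insert_rois(centers[[nm]], insert_diameter = insd,
                            roi_diameter = rd)
        cnr_vals[[nm]][s, k] <- cnr(sl, rois$insert, rois$background, px)
      }
    }
    out$cnr <- lapply(cnr_vals, summarize_vals)
  }
  if ("f50" %in% measures && !is.null(phantoms$half)) {
    ph <- phantoms$half
    ideal <- forward_project_all(ph, geometry, protocol_angles(pr))
    f <- matrix(0, n_seeds, n_slices)
    for (s in seq_len(n_seeds)) for (k in seq_len(n_slices)) {
      seed <- stable_hash(base_seed, pr$name, "half", s, k)
      sl <- recon_noisy_slice(ideal, pr, geometry, settings, fluence, seed,
                              n_binned = nbin)
      f[s, k] <- measure_f50(sl, ph$edge, px)$f50
    }
    out$f50 <- summarize_vals(f)
  }
  structure(out, class = "iq_report")
}

#' @export
print.iq_report_list <- function(x, ...) {
  cat("protocol sweep:", length(x), "report(s)\n\n")
  for (r in x) print(r)
  invisible(x)
}

#' @export
print.iq_report <- function(x, ...) {
  cat("iq_report, protocol", x$protocol$name, "\n")
  if (!is.null(x$error)) {
    cat("  FAILED:", x$error, "\n"); return(invisible(x))
  }
  if (!is.null(x$uniformity))
    cat(sprintf("  uniformity: %.2f +/- %.2f %%\n",
                x$uniformity$mean, x$uniformity$sd))
  if (!is.null(x$noise))
    cat(sprintf("  noise:      %.3f +/- %.3f %%\n", x$noise$mean, x$noise$sd))
  if (!is.null(x$cnr))
    for (nm in names(x$cnr))
      cat(sprintf("  CNR %-16s %.2f +/- %.2f\n", paste0(nm, ":"),
                  x$cnr[[nm]]$mean, x$cnr[[nm]]$sd))
  if (!is.null(x$f50))
    cat(sprintf("  f50:        %.4f +/- %.4f mm^-1\n", x$f50$mean, x$f50$sd))
  invisible(x)
}

#' Tidy per-slice metric table from sweep reports
#'
#' @param reports an `iq_report_list` from [run_protocol_sweep()].
#' @return data.frame: protocol, metric, roi, seed, slice, value.
#' @export
sweep_metrics_table <- function(reports) {
  rows <- list()
  add <- function(pr, metric, roi, vals) {
    if (is.null(vals)) return()
    d <- expand.grid(seed = seq_len(nrow(vals$values)),
                     slice = seq_len(ncol(vals$values)))
    rows[[length(rows) + 1]] <<- data.frame(
      protocol = pr, metric = metric, roi = roi,
      seed = d$seed, slice = d$slice,
      value = as.numeric(vals$values[cbind(d$seed, d$slice)]),
      stringsAsFactors = FALSE)
  }
  for (r in reports) {
    if (!is.null(r$error)) next
    add(r$protocol$name, "uniformity", "water", r$uniformity)
    add(r$protocol$name, "noise", "water", r$noise)
    if (!is.null(r$cnr))
      for (nm in names(r$cnr)) add(r$protocol$name, "cnr", nm, r$cnr[[nm]])
    add(r$protocol$name, "f50", "edge", r$f50)
  }
  do.call(rbind, rows)
}

summary_row <- function(r, metric, roi, s) {
  data.frame(protocol = r$protocol$name,
             n_projections = r$protocol$n_projections,
             arc_length = r$protocol$arc_length,
             total_mu = r$protocol$total_mu,
             mu_per_projection = r$protocol$mu_per_projection,
             sampling_rate = r$protocol$sampling_rate,
             metric = metric, roi = roi, mean = s$mean, sd = s$sd,
             stringsAsFactors = FALSE)
}

#' Summary table of a sweep
#'
#' One row per protocol x metric (x insert for CNR) with the mean over all
#' realizations and the mean within-group (six-slice) SD.
#'
#' @param reports an `iq_report_list`.
#' @return data.frame.
#' @export
sweep_summary <- function(reports) {
  rows <- list()
  for (r in reports) {
    if (!is.null(r$error)) next
    if (!is.null(r$uniformity))
      rows[[length(rows) + 1]] <- summary_row(r, "uniformity", "water",
                                              r$uniformity)
    if (!is.null(r$noise))
      rows[[length(rows) + 1]] <- summary_row(r, "noise", "water", r$noise)
    if (!is.null(r$cnr))
      for (nm in names(r$cnr))
        rows[[length(rows) + 1]] <- summary_row(r, "cnr", nm, r$cnr[[nm]])
    if (!is.null(r$f50))
      rows[[length(rows) + 1]] <- summary_row(r, "f50", "edge", r$f50)
  }
  do.call(rbind, rows)
}

#' Render sweep tables and figures
#'
#' Writes three CSVs and three PNG figures to `out_dir`: uniformity and noise
#' versus the total number of projections, CNR versus MU/projection (full
#' versus short arc series), and f50 versus sampling rate, each with
#' within-group SD error bars. Plot CSVs contain exactly the plotted values.
#'
#' @param reports an `iq_report_list`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
render_report <- function(reports, out_dir) {
  stopifnot(length(reports) >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  smry <- sweep_summary(reports)
  paths <- character()
  wcsv <- function(d, f) {
    p <- file.path(out_dir, f); write.csv(d, p, row.names = FALSE); p
  }
  errbar <- function(x, y, s) {
    graphics::arrows(x, y - s, x, y + s, angle = 90, code = 3,
                     length = 0.03, col = "grey40")
  }
  un <- smry[smry$metric %in% c("uniformity", "noise"), ]
  if (nrow(un) > 0) {
    paths <- c(paths, wcsv(un, "uniformity_noise.csv"))
    p <- file.path(out_dir, "uniformity_noise.png")
    grDevices::png(p, width = 1200, height = 500, res = 120)
    graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    for (m in c("uniformity", "noise")) {
      d <- un[un$metric == m, ]
      if (nrow(d) == 0) next
      graphics::plot(d$n_projections, d$mean, pch = ifelse(d$arc_length < 360, 17, 1),
                     xlab = "total projections", ylab = paste(m, "(%)"),
                     main = m,
                     ylim = range(d$mean - d$sd, d$mean + d$sd))
      errbar(d$n_projections, d$mean, d$sd)
    }
    grDevices::dev.off()
    paths <- c(paths, p)
  }
  cn <- smry[smry$metric == "cnr", ]
  if (nrow(cn) == 0) {
    warning("no CNR results; CNR plot skipped")
  } else {
    paths <- c(paths, wcsv(cn, "cnr.csv"))
    p <- file.path(out_dir, "cnr.png")
    grDevices::png(p, width = 900, height = 600, res = 120)
    graphics::par(mar = c(4, 4, 2, 1))
    cols <- seq_along(unique(cn$roi))
    names(cols) <- unique(cn$roi)
    graphics::plot(cn$mu_per_projection, cn$mean,
                   pch = ifelse(cn$arc_length < 360, 17, 1),
                   col = cols[cn$roi], xlab = "MU per projection",
                   ylab = "CNR", main = "contrast-to-noise ratio",
                   ylim = range(cn$mean - cn$sd, cn$mean + cn$sd))
    errbar(cn$mu_per_projection, cn$mean, cn$sd)
    graphics::legend("topright", legend = names(cols), col = cols, pch = 1,
                     cex = 0.8)
    grDevices::dev.off()
    paths <- c(paths, p)
  }
  f5 <- smry[smry$metric == "f50", ]
  if (nrow(f5) > 0) {
    paths <- c(paths, wcsv(f5, "f50.csv"))
    p <- file.path(out_dir, "f50.png")
    grDevices::png(p, width = 900, height = 600, res = 120)
    graphics::par(mar = c(4, 4, 2, 1))
    graphics::plot(f5$sampling_rate, f5$mean,
                   pch = ifelse(f5$arc_length < 360, 17, 1),
                   xlab = "sampling rate (deg/projection)",
                   ylab = "f50 (mm^-1)", main = "50% MTF frequency",
                   ylim = range(f5$mean - f5$sd, f5$mean + f5$sd))
    errbar(f5$sampling_rate, f5$mean, f5$sd)
    grDevices::dev.off()
    paths <- c(paths, p)
  }
  invisible(paths)
}
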