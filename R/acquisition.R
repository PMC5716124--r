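#' Acquisition protocol
#'
#' Describes one cone-beam acquisition: the gantry arc, the number of
#' projections and the total exposure in monitor units (MU). When the number
#' of projections changes at fixed exposure, the MU per projection is
#' adjusted so the total stays constant.
#'
#' @param name protocol label.
#' @param arc_start,arc_stop gantry angles, degrees (IEC 61217).
#' @param arc_length arc length, degrees, in (0, 360].
#' @param n_projections number of projections (>= 2).
#' @param total_mu total exposure, MU (> 0).
#' @param direction `"CW"` (gantry angle increasing) or `"CCW"`.
#' @param inplane_field,crossplane_field field sizes, cm (metadata).
#' @return object of class `acquisition_protocol` with derived fields
#'   `mu_per_projection` and `sampling_rate` (deg/projection).
#' @examples
#' acquisition_protocol("short100", 270, 110, 200, 100, 13.5)
#' @export
acquisition_protocol <- function(name, arc_start, arc_stop, arc_length,
                                 n_projections, total_mu,
                                 direction = c("CW", "CCW"),
                                 inplane_field = 27.4, crossplane_field = 27.4) {
  direction <- match.arg(direction)
  if (arc_length <= 0 || arc_length > 360) stop("arc_length must be in (0, 360]")
  if (n_projections < 2) stop("n_projections must be >= 2")
  if (total_mu <= 0) stop("total_mu must be > 0")
  stepdir <- if (direction == "CW") 1 else -1
  implied_stop <- (arc_start + stepdir * arc_length) %% 360
  if (abs(((implied_stop - arc_stop) %% 360)) > 1e-6 &&
      abs(((arc_stop - implied_stop) %% 360)) > 1e-6)
    warning("arc_stop inconsistent with arc_start + direction * arc_length")
  structure(list(name = as.character(name), arc_start = arc_start,
                 arc_stop = arc_stop, arc_length = arc_length,
                 direction = direction,
                 n_projections = as.integer(n_projections),
                 total_mu = total_mu,
                 mu_per_projection = total_mu / n_projections,
                 sampling_rate = arc_length / n_projections,
                 inplane_field = inplane_field,
                 crossplane_field = crossplane_field),
            class = "acquisition_protocol")
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat(sprintf("protocol %s: %g deg arc (%s from %g), %d projections, %g MU (%0.4f MU/proj, %g deg/proj)\n",
              x$name, x$arc_length, x$direction, x$arc_start,
              x$n_projections, x$total_mu, x$mu_per_projection,
              x$sampling_rate))
  invisible(x)
}

#' The nine study protocols
#'
#' Full scans (360 deg starting at gantry 180) with 180/360/400/450/600
#' projections at 13.5 MU, short scans (200 deg from gantry 270 to 110) with
#' 100/200/400 projections at 13.5 MU, and a low-exposure full scan (360
#' projections, 7.2 MU).
#'
#' @return named list of nine [acquisition_protocol()] objects, `"1"`..`"9"`.
#' @export
mvcbct_protocols <- function() {
  rows <- list(
    list("1", 180, 180, 360, 180, 13.5),
    list("2", 180, 180, 360, 360, 13.5),
    list("3", 180, 180, 360, 400, 13.5),
    list("4", 180, 180, 360, 450, 13.5),
    list("5", 180, 180, 360, 600, 13.5),
    list("6", 270, 110, 200, 100, 13.5),
    list("7", 270, 110, 200, 200, 13.5),
    list("8", 270, 110, 200, 400, 13.5),
    list("9", 180, 180, 360, 360, 7.2)
  )
  out <- lapply(rows, function(r)
    acquisition_protocol(r[[1]], r[[2]], r[[3]], r[[4]], r[[5]], r[[6]]))
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Read / write protocol definitions as YAML
#'
#' The YAML file holds one entry per protocol with the arc, projection count
#' and exposure columns.
#'
#' @param protocols list of [acquisition_protocol()].
#' @param path YAML file path.
#' @export
write_protocols_yaml <- function(protocols, path) {
  entries <- lapply(protocols, function(p)
    list(name = p$name, arc_start = p$arc_start, arc_stop = p$arc_stop,
         arc_length = p$arc_length, direction = p$direction,
         n_projections = p$n_projections, total_mu = p$total_mu,
         inplane_field = p$inplane_field,
         crossplane_field = p$crossplane_field))
  yaml::write_yaml(unname(entries), path)
  invisible(path)
}

#' @rdname write_protocols_yaml
#' @export
read_protocols_yaml <- function(path) {
  entries <- yaml::read_yaml(path)
  out <- lapply(entries, function(e)
    acquisition_protocol(e$name, e$arc_start, e$arc_stop, e$arc_length,
                         e$n_projections, e$total_mu,
                         direction = e$direction %||% "CW",
                         inplane_field = e$inplane_field %||% 27.4,
                         crossplane_field = e$crossplane_field %||% 27.4))
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Scan geometry
#'
#' Source-axis and source-detector distances plus the (single-row, desk
#' scale) detector description. Full-scale default: 1024 pixels at 0.4 mm
#' pitch and no detector blur; [desk_geometry()] halves the pixel count at
#' doubled pitch (unchanged active width) and sets a 2 mm detector
#' point-spread sigma, the glare/scintillator blur typical of megavoltage
#' flat panels.
#'
#' @param sad source-axis distance, mm.
#' @param sdd source-detector distance, mm.
#' @param detector_pixels pixels per detector row.
#' @param pixel_pitch detector pixel pitch, mm.
#' @param bit_depth detector digitization depth, bits.
#' @param psf_sigma_mm optional detector blur (Gaussian sigma at the detector
#'   plane, mm; 0 = off).
#' @return object of class `scan_geometry`.
#' @export
scan_geometry <- function(sad = 1000, sdd = 1450, detector_pixels = 1024L,
                          pixel_pitch = 0.4, bit_depth = 16L,
                          psf_sigma_mm = 0) {
  if (!(sdd > sad && sad > 0)) stop("need sdd > sad > 0")
  if (detector_pixels < 8) stop("detector_pixels too small")
  structure(list(sad = sad, sdd = sdd,
                 detector_pixels = as.integer(detector_pixels),
                 pixel_pitch = pixel_pitch, bit_depth = as.integer(bit_depth),
                 psf_sigma_mm = psf_sigma_mm),
            class = "scan_geometry")
}

#' @rdname scan_geometry
#' @export
desk_geometry <- function(psf_sigma_mm = 2, ...) {
  scan_geometry(detector_pixels = 512L, pixel_pitch = 0.8,
                psf_sigma_mm = psf_sigma_mm, ...)
}

# detector coordinates (mm) at the detector plane, pixel centers
detector_u <- function(geometry) {
  n <- geometry$detector_pixels
  (seq_len(n) - (n + 1) / 2) * geometry$pixel_pitch
}

# detector coordinates rescaled to the isocenter plane
detector_u_iso <- function(geometry) detector_u(geometry) * geometry$sad / geometry$sdd

# radius (mm) of the fan-beam field of view at the isocenter
fov_radius <- function(geometry) {
  umax <- max(abs(detector_u_iso(geometry)))
  geometry$sad * umax / sqrt(geometry$sad^2 + umax^2)
}

#' Projection angles of a protocol
#'
#' `n` equally spaced gantry angles spanning the arc: spacing
#' `arc_length / n`, first angle at `arc_start`, last at
#' `arc_start + (n - 1) * spacing` along the scan direction (mod 360).
#'
#' @param protocol an [acquisition_protocol()].
#' @return numeric vector of gantry angles, degrees (modulo 360).
#' @examples
#' protocol_angles(acquisition_protocol("short", 270, 110, 200, 100, 13.5))
#' @export
protocol_angles <- function(protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  n <- protocol$n_projections
  step <- protocol$arc_length / n
  s <- if (protocol$direction == "CW") 1 else -1
  ang <- (protocol$arc_start + s * step * (seq_len(n) - 1)) %% 360
  if (protocol$arc_length < 360) {
    # short scans must not cross the gantry 180 line (couch side); the
    # simulator has no couch, so only warn
    rel <- ((ang - 180) * s) %% 360
    if (any(diff(rel) < 0))
      warning("arc crosses the gantry 180 line")
  }
  ang
}

#' Fan-beam forward projection of one view
#'
#' Line integrals of the phantom attenuation along each source-to-detector-
#' pixel ray, by equidistant sampling (step = half the voxel spacing) with
#' bilinear interpolation.
#'
#' @param phantom a `voxel_phantom` (single slice used).
#' @param geometry a [scan_geometry()].
#' @param angle gantry angle, degrees.
#' @param slice slice index for 3D phantoms.
#' @param step_mm ray sampling step; default `spacing / 2`.
#' @return numeric vector, one line integral (dimensionless) per detector
#'   pixel.
#' @export
forward_project <- function(phantom, geometry, angle, slice = 1L,
                            step_mm = NULL) {
  check_fov(phantom, geometry)
  m <- phantom_slice(phantom, slice)
  sp <- phantom$spacing[1]
  if (abs(phantom$spacing[2] - sp) > 1e-12)
    stop("in-plane voxel spacing must be isotropic")
  step <- step_mm %||% (sp / 2)
  beta <- gantry_to_math(angle)
  as.numeric(cpp_fan_forward(m, sp, phantom$origin[1], phantom$origin[2],
                             beta, geometry$sad, geometry$sdd,
                             detector_u(geometry), step))
}

# all views at once (internal; used by simulate_scan)
forward_project_all <- function(phantom, geometry, angles_deg, slice = 1L,
                                step_mm = NULL) {
  check_fov(phantom, geometry)
  m <- phantom_slice(phantom, slice)
  sp <- phantom$spacing[1]
  step <- step_mm %||% (sp / 2)
  cpp_fan_forward(m, sp, phantom$origin[1], phantom$origin[2],
                  gantry_to_math(angles_deg), geometry$sad, geometry$sdd,
                  detector_u(geometry), step)
}

check_fov <- function(phantom, geometry) {
  m <- phantom_slice(phantom, 1L)
  nz <- which(m != 0, arr.ind = TRUE)
  if (nrow(nz) == 0) return(invisible(TRUE))
  sp <- phantom$spacing[1]
  x <- phantom$origin[1] + (nz[, 1] - 1) * sp
  y <- phantom$origin[2] + (nz[, 2] - 1) * sp
  rmax <- sqrt(max(x^2 + y^2))
  rf <- fov_radius(geometry)
  if (rmax > rf)
    stop(sprintf("phantom extends to %.1f mm but the fan field of view radius is %.1f mm (truncated projections)",
                 rmax, rf))
  invisible(TRUE)
}

new_projection_set <- function(frames, angles_deg, protocol, geometry,
                               fluence_per_mu, seed = NA_integer_,
                               noiseless = FALSE, n_saturated = 0L,
                               n_binned = 1L) {
  structure(list(frames = frames, angles = angles_deg, protocol = protocol,
                 geometry = geometry, fluence_per_mu = fluence_per_mu,
                 mu_per_frame = protocol$mu_per_projection,
                 n_binned = n_binned,
                 seed = seed, noiseless = noiseless,
                 n_saturated = n_saturated),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("projection_set: %d frames x %d pixels (%s, protocol %s, seed %s)\n",
              ncol(x$frames), nrow(x$frames),
              if (x$noiseless) "noiseless" else "Poisson",
              x$protocol$name, format(x$seed)))
  invisible(x)
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Exposure noise model
#'
#' Converts ideal line integrals into detector counts: the expected count in
#' each pixel is `fluence_per_mu * mu_per_projection * exp(-line integral)`;
#' realized counts are Poisson with that mean, optionally plus zero-mean
#' Gaussian electronic noise, and are clipped to the detector bit-depth
#' ceiling (a saturation warning reports the number of clipped pixels).
#' If the geometry specifies a detector point-spread sigma, the counts are
#' blurred along the detector row afterwards (scintillator glare model).
#'
#' @param ideal matrix of line integrals, detector pixels x angles.
#' @param protocol an [acquisition_protocol()] (sets MU/projection).
#' @param geometry a [scan_geometry()] (sets the bit-depth ceiling).
#' @param angles gantry angles, degrees (one per column of `ideal`).
#' @param fluence_per_mu expected photons per detector pixel per MU at zero
#'   attenuation.
#' @param seed RNG seed (recorded in the result).
#' @param electronic_sd per-pixel Gaussian read noise SD in counts (0 = off).
#' @param noiseless if `TRUE`, return the expected counts (no sampling).
#' @param n_binned number of identical detector rows summed into each stored
#'   pixel (axial display binning of a z-uniform slab: expected counts and
#'   the saturation ceiling both scale with it).
#' @return a `projection_set` whose `frames` are counts.
#' @export
add_exposure_noise <- function(ideal, protocol, geometry, angles,
                               fluence_per_mu = 2e4, seed = 1L,
                               electronic_sd = 0, noiseless = FALSE,
                               n_binned = 1L) {
  if (fluence_per_mu <= 0) stop("fluence_per_mu must be > 0")
  stopifnot(ncol(ideal) == length(angles))
  i0 <- n_binned * fluence_per_mu * protocol$mu_per_projection
  expected <- i0 * exp(-ideal)
  ceiling_counts <- n_binned * (2^geometry$bit_depth - 1)
  nsat <- sum(expected > ceiling_counts)
  if (nsat > 0)
    warning(sprintf("detector saturation: %d pixels above the %d-count ceiling",
                    nsat, ceiling_counts))
  if (noiseless) {
    counts <- pmin(expected, ceiling_counts)
    if (geometry$psf_sigma_mm > 0) counts <- blur_frames(counts, geometry)
    return(new_projection_set(counts, angles, protocol, geometry,
                              fluence_per_mu, seed = NA_integer_,
                              noiseless = TRUE, n_saturated = nsat,
                              n_binned = n_binned))
  }
  counts <- with_seed(seed, {
    cts <- matrix(rpois(length(expected), lambda = expected),
                  nrow(expected), ncol(expected))
    if (electronic_sd > 0)
      cts <- cts + matrix(rnorm(length(cts), sd = electronic_sd),
                          nrow(cts), ncol(cts))
    cts
  })
  counts <- pmin(pmax(counts, 0), ceiling_counts)
  if (geometry$psf_sigma_mm > 0) counts <- blur_frames(counts, geometry)
  new_projection_set(counts, angles, protocol, geometry, fluence_per_mu,
                     seed = as.integer(seed), noiseless = FALSE,
                     n_saturated = nsat, n_binned = n_binned)
}

#' Simulate a scan
#'
#' Composition of [protocol_angles()], [forward_project()] per angle, and
#' [add_exposure_noise()]; deterministic for a given seed.
#'
#' @inheritParams add_exposure_noise
#' @param phantom a `voxel_phantom`.
#' @param slice slice index for 3D phantoms.
#' @param ideal optional precomputed line-integral matrix (skips the forward
#'   projection, useful when only the noise realization changes).
#' @param n_binned detector rows summed per stored pixel (display binning).
#' @return a `projection_set`.
#' @export
simulate_scan <- function(phantom, protocol, geometry = desk_geometry(),
                          fluence_per_mu = 2e4, seed = 1L,
                          electronic_sd = 0, noiseless = FALSE,
                          slice = 1L, ideal = NULL, n_binned = 1L) {
  angles <- protocol_angles(protocol)
  if (is.null(ideal))
    ideal <- forward_project_all(phantom, geometry, angles, slice = slice)
  add_exposure_noise(ideal, protocol, geometry, angles,
                     fluence_per_mu = fluence_per_mu, seed = seed,
                     electronic_sd = electronic_sd,
                     noiseless = noiseless, n_binned = n_binned)
}

# optional detector PSF: Gaussian blur along the detector row
blur_frames <- function(frames, geometry) {
  sig <- geometry$psf_sigma_mm / geometry$pixel_pitch
  hw <- max(1L, ceiling(3 * sig))
  k <- exp(-(seq(-hw, hw))^2 / (2 * sig^2))
  k <- k / sum(k)
  apply(frames, 2, function(col)
    stats::filter(c(rep(col[1], hw), col, rep(col[length(col)], hw)),
                  k, sides = 2)[(hw + 1):(hw + length(col))])
}

#' Line integrals from detector counts
#'
#' The log transform used for reconstruction: `ln(fluence * MU / counts)`,
#' with counts floored at 0.5 to avoid infinities at heavy attenuation.
#'
#' @param scan a `projection_set`.
#' @return matrix of line integrals (detector pixels x angles).
#' @export
scan_line_integrals <- function(scan) {
  i0 <- (scan$n_binned %||% 1) * scan$fluence_per_mu * scan$mu_per_frame
  counts <- pmax(scan$frames, 0.5)
  log(i0 / counts)
}

#' Write / read a projection set as float TIFF plus YAML sidecar
#'
#' Frames are stored as 32-bit float TIFF pages (one per projection); angles,
#' protocol, geometry, fluence and seed go to a YAML sidecar.
#'
#' @param scan a `projection_set`.
#' @param path TIFF path; sidecar at `<path>.yaml`.
#' @export
write_projections_tiff <- function(scan, path) {
  sc <- max(scan$frames, 1)
  pages <- lapply(seq_len(ncol(scan$frames)),
                  function(k) matrix(scan$frames[, k] / sc, nrow = 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  p <- scan$protocol
  side <- list(scale = sc, angles = as.numeric(scan$angles),
               fluence_per_mu = scan$fluence_per_mu,
               n_binned = scan$n_binned %||% 1,
               seed = if (is.na(scan$seed)) NULL else scan$seed,
               noiseless = scan$noiseless,
               protocol = list(name = p$name, arc_start = p$arc_start,
                               arc_stop = p$arc_stop,
                               arc_length = p$arc_length,
                               direction = p$direction,
                               n_projections = p$n_projections,
                               total_mu = p$total_mu),
               geometry = list(sad = scan$geometry$sad, sdd = scan$geometry$sdd,
                               detector_pixels = scan$geometry$detector_pixels,
                               pixel_pitch = scan$geometry$pixel_pitch,
                               bit_depth = scan$geometry$bit_depth))
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_projections_tiff
#' @export
read_projections_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  frames <- vapply(pages, function(pg) as.numeric(pg) * side$scale,
                   numeric(length(pages[[1]])))
  pr <- side$protocol
  protocol <- acquisition_protocol(pr$name, pr$arc_start, pr$arc_stop,
                                   pr$arc_length, pr$n_projections,
                                   pr$total_mu, direction = pr$direction)
  g <- side$geometry
  geometry <- scan_geometry(g$sad, g$sdd, g$detector_pixels, g$pixel_pitch,
                            g$bit_depth)
  new_projection_set(frames, as.numeric(side$angles), protocol, geometry,
                     side$fluence_per_mu,
                     seed = side$seed %||% NA_integer_,
                     noiseless = isTRUE(side$noiseless),
                     n_binned = side$n_binned %||% 1)
}
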