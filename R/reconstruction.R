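#' Reconstruction settings
#'
#' @param grid_size pixels per side of the reconstruction grid (>= 32).
#' @param pixel_size_mm reconstructed pixel size, mm.
#' @param slice_thickness_mm native slice thickness, mm.
#' @param display_thickness_mm thickness over which slices are binned and
#'   averaged for display/analysis.
#' @param filter_window apodization window applied to the ramp filter; the
#'   vendor "smoothing" kernel is unpublished, so an apodized ramp stands in
#'   (default Hann at cutoff 0.8).
#' @param filter_cutoff cutoff as a fraction of the detector Nyquist, (0, 1].
#' @return object of class `recon_settings`.
#' @export
recon_settings <- function(grid_size = 512L, pixel_size_mm = 0.55,
                           slice_thickness_mm = 1,
                           display_thickness_mm = 4.8,
                           filter_window = c("hann", "ramp", "hamming", "cosine"),
                           filter_cutoff = 0.8) {
  filter_window <- match.arg(filter_window)
  if (grid_size < 32) stop("grid_size must be >= 32")
  if (filter_cutoff <= 0 || filter_cutoff > 1) stop("cutoff must be in (0, 1]")
  structure(list(grid_size = as.integer(grid_size),
                 pixel_size_mm = pixel_size_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 display_thickness_mm = display_thickness_mm,
                 filter_window = filter_window,
                 filter_cutoff = filter_cutoff),
            class = "recon_settings")
}

# desk-scale settings: 256 grid covering a 281.6 mm field of view
desk_settings <- function(...) {
  recon_settings(grid_size = 256L, pixel_size_mm = 1.1, ...)
}

new_recon_volume <- function(slices, pixel_size_mm, slice_thickness_mm,
                             provenance = list()) {
  structure(list(slices = slices, pixel_size_mm = pixel_size_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 provenance = provenance),
            class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf("recon_volume: %d slice(s) of %d x %d px (%.3g mm px, %.3g mm thick)\n",
              if (length(d) == 3) d[3] else 1L, d[1], d[2],
              x$pixel_size_mm, x$slice_thickness_mm))
  invisible(x)
}

# one slice as a matrix
volume_slice <- function(volume, k = 1L) {
  if (length(dim(volume$slices)) == 2L) volume$slices else volume$slices[, , k]
}

n_volume_slices <- function(volume) {
  d <- dim(volume$slices)
  if (length(d) == 3L) d[3] else 1L
}

#' Short-scan redundancy (Parker) weights
#'
#' For an arc of `180 + fan_angle` degrees each line is measured once or
#' twice; Parker weighting tapers the doubly measured wedges so that each
#' complementary ray pair carries unit total weight. A full 360 degree scan
#' measures every line twice and gets uniform weights 1/2.
#'
#' Weights use the half fan angle `gm = (arc - 180) / 2` implied by the arc
#' (equal to `fan_angle / 2` for an exact short scan); arcs longer than
#' `180 + fan_angle` are handled by the same smooth window (over-scan).
#'
#' @param angles gantry angles of the frames, degrees, in acquisition order
#'   (equally spaced along the arc).
#' @param fan_angle full fan opening subtended by the detector, degrees.
#' @param gamma fan angles of the detector pixels, degrees (signed); one
#'   weight column per entry.
#' @return matrix of weights between 0 and 1, `length(angles)` x `length(gamma)`.
#' @export
parker_weights <- function(angles, fan_angle, gamma) {
  n <- length(angles)
  if (n < 2) stop("need at least 2 angles")
  step <- abs((angles[2] - angles[1] + 180) %% 360 - 180)
  arc <- step * n
  if (arc >= 360 - 1e-6)
    return(matrix(0.5, n, length(gamma)))
  if (arc < 180 + fan_angle - 1e-9)
    stop(sprintf("arc (%.1f deg) shorter than 180 + fan angle (%.1f deg): insufficient data",
                 arc, 180 + fan_angle))
  gm <- (arc - 180) / 2 * pi / 180
  # progression along the arc, radians from the first frame
  bprog <- (seq_len(n) - 1) * step * pi / 180
  # scan direction: increasing gantry angle means decreasing math angle, so
  # the fan-angle sign is mirrored relative to the progression variable
  s <- -sign((((angles[2] - angles[1]) + 180) %% 360) - 180)
  g <- s * gamma * pi / 180
  W <- matrix(1, n, length(gamma))
  for (j in seq_along(g)) {
    gj <- g[j]
    b <- bprog
    w <- rep(1, n)
    d1 <- gm + gj                      # start-wedge half-width parameter
    in1 <- d1 > 1e-12 & b < 2 * d1
    w[in1] <- sin(pi / 4 * b[in1] / d1)^2
    d2 <- gm - gj
    in2 <- d2 > 1e-12 & b > pi + 2 * gj
    w[in2] <- cos(pi / 4 * (b[in2] - pi - 2 * gj) / d2)^2
    if (d2 <= 1e-12) w[b > pi + 2 * gj] <- 0
    if (d1 <= 1e-12) w[b < 2 * d1] <- 0
    W[, j] <- pmin(pmax(w, 0), 1)
  }
  W
}

# discrete band-limited ramp kernel (spatial domain), tap spacing du (mm)
ramp_kernel <- function(m, du) {
  h <- numeric(m)
  h[1] <- 1 / (4 * du^2)
  k <- seq_len(m - 1)
  odd <- k %% 2 == 1
  vals <- numeric(m - 1)
  vals[odd] <- -1 / (pi * k[odd] * du)^2
  # circular layout: positive lags then mirrored negative lags
  half <- floor(m / 2)
  h[2:(half + 1)] <- vals[1:half]
  if (m - half - 1 > 0) h[(half + 2):m] <- rev(vals[1:(m - half - 1)])
  h
}

window_gain <- function(ffrac, window, cutoff) {
  w <- rep(0, length(ffrac))
  inb <- ffrac <= cutoff + 1e-12
  x <- ffrac[inb] / cutoff
  w[inb] <- switch(window,
                   ramp = 1,
                   hann = 0.5 * (1 + cos(pi * x)),
                   hamming = 0.54 + 0.46 * cos(pi * x),
                   cosine = cos(pi * x / 2))
  w
}

#' Ramp-filter projections
#'
#' Applies the band-limited ramp filter with the configured apodization
#' window row-wise (along the detector dimension) in the frequency domain.
#' Linear in its input; a constant profile maps to (near) zero.
#'
#' @param projections matrix of (cosine- and redundancy-weighted) line
#'   integrals, detector pixels x angles, sampled every `du` mm.
#' @param settings a [recon_settings()] (window and cutoff).
#' @param du detector sample spacing at the isocenter, mm.
#' @return filtered projections, same shape, units mm^-2 times `du` applied
#'   in the convolution (ready for backprojection).
#' @export
filter_projections <- function(projections, settings, du) {
  projections <- as.matrix(projections)
  n <- nrow(projections)
  m <- nextn(2L * n, 2)
  H <- Re(fft(ramp_kernel(m, du)))
  ffrac <- c(seq(0, m / 2), seq(m / 2 - 1, 1)) / (m / 2)  # |f| / Nyquist
  H <- H * window_gain(ffrac, settings$filter_window, settings$filter_cutoff)
  pad <- rbind(projections, matrix(0, m - n, ncol(projections)))
  q <- Re(mvfft(mvfft(pad) * H, inverse = TRUE)) / m
  q[seq_len(n), , drop = FALSE] * du
}

#' Filtered backprojection
#'
#' Fan-beam filtered backprojection on a flat (virtual, isocenter-scaled)
#' detector: cosine weighting, redundancy weighting (Parker window for short
#' scans, 1/2 for full scans), apodized ramp filtering, and weighted
#' backprojection with linear interpolation. Input counts are log-transformed
#' with `ln(fluence * MU / counts)` (counts floored at 0.5). Pixels outside
#' the inscribed reconstruction circle are set to 0.
#'
#' @param scan a `projection_set` (or a plain line-integral matrix if
#'   `line_integrals = TRUE`, with `geometry`, `angles` supplied).
#' @param settings a [recon_settings()].
#' @param geometry,angles only needed when `scan` is a plain matrix.
#' @param line_integrals treat `scan` as line integrals, skipping the log
#'   transform.
#' @return a `recon_volume` with one slice in attenuation units (mm^-1).
#' @export
fbp_reconstruct <- function(scan, settings = recon_settings(),
                            geometry = NULL, angles = NULL,
                            line_integrals = FALSE) {
  if (inherits(scan, "projection_set")) {
    geometry <- scan$geometry
    angles <- scan$angles
    p <- if (line_integrals) scan$frames else scan_line_integrals(scan)
    prov <- list(protocol = scan$protocol$name, seed = scan$seed,
                 settings = unclass(settings))
  } else {
    if (is.null(geometry) || is.null(angles))
      stop("geometry and angles required for a plain projection matrix")
    p <- as.matrix(scan)
    if (!line_integrals)
      stop("plain matrices must already be line integrals")
    prov <- list(settings = unclass(settings))
  }
  if (is.null(dim(p)) || ncol(p) < 2) stop("need at least 2 projections")
  n <- length(angles)
  uiso <- detector_u_iso(geometry)
  du <- uiso[2] - uiso[1]
  # cosine weighting on the virtual flat detector
  cw <- geometry$sad / sqrt(geometry$sad^2 + uiso^2)
  p <- p * cw
  # redundancy weights
  step <- abs((angles[2] - angles[1] + 180) %% 360 - 180)
  arc <- step * n
  fan <- 2 * atan(max(abs(uiso)) / geometry$sad) * 180 / pi
  if (arc >= 360 - 1e-6) {
    W <- matrix(0.5, n, length(uiso))
  } else {
    W <- parker_weights(angles, fan, atan(uiso / geometry$sad) * 180 / pi)
  }
  p <- p * t(W)
  q <- filter_projections(p, settings, du)
  dbeta <- rep(step * pi / 180, n)
  ng <- settings$grid_size
  ox <- -(ng - 1) / 2 * settings$pixel_size_mm
  img <- cpp_fan_backproject(q, gantry_to_math(angles), geometry$sad,
                             uiso[1], du, ng, ng, settings$pixel_size_mm,
                             ox, ox, dbeta)
  # mask the inscribed circle
  xs <- grid_coords(ng, settings$pixel_size_mm)
  rmax <- ng / 2 * settings$pixel_size_mm
  m <- outer(xs, xs, function(x, y) x^2 + y^2) >= rmax^2
  img[m] <- 0
  new_recon_volume(img, settings$pixel_size_mm, settings$slice_thickness_mm,
                   provenance = prov)
}

#' Bin and average thin slices to a display thickness
#'
#' Consecutive groups of `round(display / slice)` native slices are averaged;
#' a trailing partial group is dropped.
#'
#' @param volume a `recon_volume`.
#' @param display_thickness_mm display slab thickness, mm (>= native slice
#'   thickness).
#' @return a `recon_volume` with updated slice thickness.
#' @export
bin_average_slices <- function(volume, display_thickness_mm = 4.8) {
  st <- volume$slice_thickness_mm
  if (display_thickness_mm < st)
    stop("display thickness must be >= slice thickness")
  g <- max(1L, round(display_thickness_mm / st))
  nk <- n_volume_slices(volume)
  nout <- nk %/% g
  if (nout < 1) stop("not enough slices for one display bin")
  sl <- volume$slices
  if (length(dim(sl)) == 2L) sl <- array(sl, c(dim(sl), 1L))
  out <- array(0, c(dim(sl)[1:2], nout))
  for (b in seq_len(nout)) {
    idx <- ((b - 1) * g + 1):(b * g)
    out[, , b] <- apply(sl[, , idx, drop = FALSE], c(1, 2), mean)
  }
  if (nout == 1L) out <- out[, , 1]
  new_recon_volume(out, volume$pixel_size_mm, st * g,
                   provenance = c(volume$provenance,
                                  list(display_thickness_mm = display_thickness_mm)))
}

#' Write / read a reconstructed volume as float TIFF plus YAML sidecar
#'
#' @param volume a `recon_volume`.
#' @param path TIFF path; sidecar at `<path>.yaml`.
#' @export
write_volume_tiff <- function(volume, path) {
  sl <- volume$slices
  if (length(dim(sl)) == 2L) sl <- array(sl, c(dim(sl), 1L))
  sc <- max(abs(sl), 1e-12)
  pages <- lapply(seq_len(dim(sl)[3]), function(k) {
    pg <- sl[, , k] / (2 * sc) + 0.5   # map to [0,1] for float TIFF
    pg
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(list(scale = sc, pixel_size_mm = volume$pixel_size_mm,
                        slice_thickness_mm = volume$slice_thickness_mm,
                        provenance = volume$provenance),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  sl <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  sl <- (sl - 0.5) * 2 * side$scale
  if (dim(sl)[3] == 1L) sl <- sl[, , 1]
  new_recon_volume(sl, side$pixel_size_mm, side$slice_thickness_mm,
                   provenance = side$provenance)
}
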