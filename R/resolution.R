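#' Extract an edge spread function at a water/air interface
#'
#' Samples pixel values along lines perpendicular to an axis-aligned
#' interface and averages over `n_lines` parallel lines to suppress noise.
#' The profile is ordered air first: positions are mm travelled from the air
#' side toward the water.
#'
#' @param slice matrix of reconstructed values (grid centered on the image).
#' @param edge an [edge_spec()] (axis the interface is perpendicular to and
#'   its mm position).
#' @param pixel_size_mm pixel size, mm.
#' @param n_lines number of parallel lines to average (centered on the
#'   image center).
#' @param half_length_mm profile half-length on either side of the edge, mm.
#' @param water_side which side of the interface holds water: `"negative"`
#'   (default, coordinates below `position`) or `"positive"`.
#' @return object of class `esf_profile`: list with `positions` (mm,
#'   strictly increasing, uniform) and `values`.
#' @export
extract_esf <- function(slice, edge, pixel_size_mm, n_lines = 64L,
                        half_length_mm = 40,
                        water_side = c("negative", "positive")) {
  water_side <- match.arg(water_side)
  stopifnot(inherits(edge, "edge_spec"))
  d <- dim(slice)
  # orient so the traverse direction is along rows (x axis = axis of edge)
  if (edge$axis == "y") slice <- t(slice)
  n_tr <- nrow(slice); n_par <- ncol(slice)
  coords <- grid_coords(n_tr, pixel_size_mm)
  ext <- range(coords)
  if (edge$position <= ext[1] || edge$position >= ext[2])
    stop("edge position lies outside the slice")
  keep <- abs(coords - edge$position) <= half_length_mm
  if (sum(keep) < 5) stop("profile too short; increase half_length_mm")
  mid <- (n_par + 1) / 2
  first <- floor(mid - (n_lines - 1) / 2)
  lines_idx <- first + seq_len(n_lines) - 1
  lines_idx <- lines_idx[lines_idx >= 1 & lines_idx <= n_par]
  prof <- rowMeans(slice[keep, lines_idx, drop = FALSE])
  pos <- coords[keep]
  # order air -> water: air sits on the positive side when water is negative
  if (water_side == "negative") {
    prof <- rev(prof)
    pos <- rev(edge$position - pos) + edge$position  # distance, increasing
    pos <- pos - edge$position
  } else {
    pos <- pos - edge$position
  }
  structure(list(positions = pos, values = prof), class = "esf_profile")
}

#' Differentiate an ESF into a line spread function
#'
#' Central finite differences on the uniform grid; one-sided differences at
#' the endpoints.
#'
#' @param esf an `esf_profile` (>= 5 samples, uniform spacing).
#' @return object of class `lsf_profile`: `positions` (mm) and `values`
#'   (attenuation per mm).
#' @export
esf_to_lsf <- function(esf) {
  x <- esf$positions; y <- esf$values
  n <- length(x)
  if (n < 5) stop("need at least 5 ESF samples")
  h <- diff(x)
  if (max(h) - min(h) > 1e-9 * mean(h)) stop("ESF spacing is not uniform")
  h <- mean(h)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * h)
  d[1] <- (y[2] - y[1]) / h
  d[n] <- (y[n] - y[n - 1]) / h
  structure(list(positions = x, values = d), class = "lsf_profile")
}

#' Fit a Gaussian to a line spread function
#'
#' Least-squares fit of `A * exp(-(x - c)^2 / (2 sigma^2))` (baseline fixed
#' at zero) by Levenberg-Marquardt, initialized from the profile moments.
#' Removes interface noise before the Fourier step.
#'
#' @param lsf an `lsf_profile` with a detectable peak (max absolute value
#'   greater than 5x the median absolute value).
#' @return object of class `gaussian_fit`: `amplitude`, `center`, `sigma`,
#'   `rss`.
#' @export
fit_gaussian_lsf <- function(lsf) {
  x <- lsf$positions; y <- lsf$values
  pk <- max(abs(y))
  if (pk == 0) stop("LSF is identically zero")
  med <- median(abs(y))
  if (med > 0 && pk <= 5 * med)
    stop("no detectable LSF peak (max <= 5x median absolute value)")
  sgn <- sign(y[which.max(abs(y))])
  yw <- pmax(sgn * y, 0)
  w <- yw / sum(yw)
  c0 <- sum(w * x)
  s0 <- sqrt(max(sum(w * (x - c0)^2), (x[2] - x[1])^2 / 12))
  a0 <- sgn * pk
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = list(A = a0, cc = c0, sig = s0),
      fn = function(p) y - p$A * exp(-(x - p$cc)^2 / (2 * p$sig^2)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Gaussian LSF fit failed: ", conditionMessage(e)))
  if (fit$info %in% c(0, 5, 9))
    stop("Gaussian LSF fit failed: ", fit$message)
  sig <- abs(fit$par$sig)
  span <- diff(range(x))
  if (sig >= 0.99 * span || sig <= (x[2] - x[1]) / 50)
    stop(sprintf("fitted sigma (%.3g mm) at the bounds; LSF peak not resolved", sig))
  structure(list(amplitude = fit$par$A, center = fit$par$cc,
                 sigma = sig, rss = fit$deviance),
            class = "gaussian_fit")
}

#' MTF of a Gaussian line spread function
#'
#' The Fourier transform of a Gaussian LSF of width `sigma` is itself
#' Gaussian; normalized to unit modulation at zero frequency it is
#' `MTF(f) = exp(-2 pi^2 sigma^2 f^2)`. Evaluated on `freq_grid`, with the
#' 50% frequency attached via [f50_from_mtf()].
#'
#' @param fit a `gaussian_fit` (or any list with a positive `sigma`, mm).
#' @param freq_grid frequencies, mm^-1; default covers past the 50% point.
#' @return object of class `mtf_curve`: `frequencies`, `modulation`, `f50`.
#' @export
mtf_from_fit <- function(fit, freq_grid = NULL) {
  sig <- fit$sigma
  if (is.null(sig) || sig <= 0) stop("sigma must be > 0")
  if (is.null(freq_grid)) {
    f50_cf <- sqrt(log(2) / 2) / (pi * sig)
    freq_grid <- seq(0, 4 * f50_cf, length.out = 257)
  }
  mod <- exp(-2 * pi^2 * sig^2 * freq_grid^2)
  curve <- structure(list(frequencies = freq_grid, modulation = mod,
                          f50 = NA_real_, sigma = sig),
                     class = "mtf_curve")
  curve$f50 <- f50_from_mtf(curve)
  curve
}

#' Numerical-FFT MTF of a sampled LSF (cross-check path)
#'
#' Discrete Fourier transform of a sampled LSF, normalized to 1 at zero
#' frequency. Used to cross-check the analytic route of [mtf_from_fit()].
#'
#' @param lsf an `lsf_profile`.
#' @param pad zero-padding factor.
#' @return an `mtf_curve` (no sigma attached).
#' @export
mtf_from_lsf_fft <- function(lsf, pad = 8L) {
  y <- lsf$values
  h <- lsf$positions[2] - lsf$positions[1]
  m <- nextn(pad * length(y), 2)
  sp <- Mod(fft(c(y, rep(0, m - length(y)))))
  if (sp[1] == 0) stop("LSF has zero area; MTF undefined")
  mod <- sp[seq_len(m %/% 2)] / sp[1]
  freqs <- (seq_len(m %/% 2) - 1) / (m * h)
  curve <- structure(list(frequencies = freqs, modulation = mod,
                          f50 = NA_real_),
                     class = "mtf_curve")
  curve$f50 <- tryCatch(f50_from_mtf(curve), error = function(e) NA_real_)
  curve
}

#' Frequency at 50% modulation
#'
#' Linear interpolation between the grid points bracketing modulation 0.5.
#'
#' @param curve an `mtf_curve` (modulation must cross 0.5 within the grid).
#' @return f50 in mm^-1.
#' @export
f50_from_mtf <- function(curve) {
  f <- curve$frequencies; m <- curve$modulation
  below <- which(m <= 0.5)
  if (length(below) == 0)
    stop("modulation never reaches 0.5 within the frequency grid")
  j <- below[1]
  if (j == 1) return(f[1])
  f[j - 1] + (0.5 - m[j - 1]) * (f[j] - f[j - 1]) / (m[j] - m[j - 1])
}

#' Full resolution chain on a reconstructed slice
#'
#' [extract_esf()] at the phantom's water/air interface, [esf_to_lsf()],
#' [fit_gaussian_lsf()], [mtf_from_fit()]; returns the f50 with the
#' intermediate objects attached.
#'
#' @inheritParams extract_esf
#' @return list with `f50` (mm^-1), `esf`, `lsf`, `fit`, `mtf`.
#' @export
measure_f50 <- function(slice, edge, pixel_size_mm, n_lines = 64L,
                        half_length_mm = 40) {
  esf <- extract_esf(slice, edge, pixel_size_mm, n_lines = n_lines,
                     half_length_mm = half_length_mm)
  lsf <- esf_to_lsf(esf)
  fit <- fit_gaussian_lsf(lsf)
  mtf <- mtf_from_fit(fit)
  list(f50 = mtf$f50, esf = esf, lsf = lsf, fit = fit, mtf = mtf)
}

#' Export ESF/LSF/MTF curves as CSV
#'
#' @param chain result of [measure_f50()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @export
write_resolution_csv <- function(chain, dir, prefix = "resolution") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(position_mm = chain$esf$positions,
                       value = chain$esf$values),
            file.path(dir, paste0(prefix, "_esf.csv")), row.names = FALSE)
  write.csv(data.frame(position_mm = chain$lsf$positions,
                       value = chain$lsf$values),
            file.path(dir, paste0(prefix, "_lsf.csv")), row.names = FALSE)
  write.csv(data.frame(frequency_mm = chain$mtf$frequencies,
                       frequency_lp_cm = 10 * chain$mtf$frequencies,
                       modulation = chain$mtf$modulation),
            file.path(dir, paste0(prefix, "_mtf.csv")), row.names = FALSE)
  invisible(dir)
}
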