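#' Protocol logistics arithmetic
#'
#' Exposure per projection, angular sampling rate, acquisition time from the
#' gantry speed, and projection-file storage. Gantry speed is an input (it is
#' set by the machine's readout constraints, not derivable here).
#'
#' @param total_mu total exposure, MU.
#' @param n_projections number of projections.
#' @return MU per projection.
#' @examples
#' mu_per_projection(13.5, 100)  # 0.135
#' @export
mu_per_projection <- function(total_mu, n_projections) {
  if (n_projections < 1) stop("n_projections must be >= 1")
  if (total_mu <= 0) stop("total_mu must be > 0")
  total_mu / n_projections
}

#' @rdname mu_per_projection
#' @param arc_length arc length, degrees.
#' @return degrees per projection.
#' @export
sampling_rate <- function(arc_length, n_projections) {
  if (n_projections < 1) stop("n_projections must be >= 1")
  arc_length / n_projections
}

#' @rdname mu_per_projection
#' @param gantry_speed gantry speed, degrees per minute (> 0).
#' @return acquisition time in seconds, reported to 0.1 s.
#' @export
acquisition_time <- function(arc_length, gantry_speed) {
  if (gantry_speed <= 0) stop("gantry_speed must be > 0")
  round(arc_length / gantry_speed * 60, 1)
}

#' @rdname mu_per_projection
#' @param active_pixels_per_side active detector pixels per side.
#' @param bit_depth bits per pixel.
#' @return storage in MB (10^6 bytes), truncated to an integer.
#' @export
projection_storage_mb <- function(n_projections, active_pixels_per_side = 1012,
                                  bit_depth = 16) {
  if (n_projections < 0 || active_pixels_per_side <= 0 || bit_depth <= 0)
    stop("arguments must be positive (n_projections >= 0)")
  bytes <- n_projections * active_pixels_per_side^2 * (bit_depth / 8)
  floor(bytes / 1e6)
}

#' Logistics report for a protocol
#'
#' @param protocol an [acquisition_protocol()].
#' @param gantry_speed gantry speed, deg/min.
#' @param active_pixels_per_side,bit_depth detector description for storage.
#' @return data.frame with one row: name, MU/projection, sampling rate,
#'   acquisition time (s), storage (MB).
#' @export
logistics_report <- function(protocol, gantry_speed = 166,
                             active_pixels_per_side = 1012, bit_depth = 16) {
  data.frame(
    protocol = protocol$name,
    n_projections = protocol$n_projections,
    arc_length_deg = protocol$arc_length,
    total_mu = protocol$total_mu,
    mu_per_projection = mu_per_projection(protocol$total_mu,
                                          protocol$n_projections),
    sampling_rate_deg = sampling_rate(protocol$arc_length,
                                      protocol$n_projections),
    acquisition_time_s = acquisition_time(protocol$arc_length, gantry_speed),
    storage_mb = projection_storage_mb(protocol$n_projections,
                                       active_pixels_per_side, bit_depth),
    stringsAsFactors = FALSE
  )
}
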