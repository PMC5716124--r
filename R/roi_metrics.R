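#' Circular and ring regions of interest
#'
#' ROIs are defined in physical mm on the reconstructed slice, centered on
#' `center` (mm from the image center).
#'
#' @param center numeric length 2, mm (x, y).
#' @param diameter circle diameter, mm.
#' @export
circle_roi <- function(center = c(0, 0), diameter) {
  if (diameter <= 0) stop("diameter must be > 0")
  structure(list(center = center, diameter = diameter), class = "circle_roi")
}

#' @rdname circle_roi
#' @param inner_diameter ring inner diameter, mm (>= 0).
#' @param thickness ring radial thickness, mm (> 0).
#' @export
ring_roi <- function(center = c(0, 0), inner_diameter, thickness) {
  if (thickness <= 0) stop("thickness must be > 0")
  if (inner_diameter < 0) stop("inner_diameter must be >= 0")
  structure(list(center = center, inner_diameter = inner_diameter,
                 thickness = thickness), class = "ring_roi")
}

#' Pixel mask of an ROI on a slice grid
#'
#' Pixel membership is pixel-center-inside-region; the grid is centered on
#' the image (pixel centers at `(i - (n+1)/2) * pixel_size`).
#'
#' @param roi a [circle_roi()] or [ring_roi()].
#' @param dim slice dimensions (pixels), length 2.
#' @param pixel_size_mm pixel size, mm.
#' @return logical matrix of `dim`.
#' @export
roi_mask <- function(roi, dim, pixel_size_mm) {
  xs <- grid_coords(dim[1], pixel_size_mm)
  ys <- grid_coords(dim[2], pixel_size_mm)
  X <- matrix(xs, dim[1], dim[2])
  Y <- matrix(ys, dim[1], dim[2], byrow = TRUE)
  r2 <- (X - roi$center[1])^2 + (Y - roi$center[2])^2
  m <- if (inherits(roi, "circle_roi")) {
    r2 < (roi$diameter / 2)^2
  } else if (inherits(roi, "ring_roi")) {
    ri <- roi$inner_diameter / 2
    ro <- ri + roi$thickness
    r2 >= ri^2 & r2 < ro^2
  } else stop("roi must be a circle_roi or ring_roi")
  if (!any(m)) stop("ROI mask is empty on this grid")
  m
}

#' ROI statistics
#'
#' Mean and sample (n-1) standard deviation of the pixels under a mask.
#' Masks with fewer than 25 pixels are refused as statistically meaningless.
#'
#' @param slice matrix of pixel values.
#' @param mask logical matrix (same shape) or an ROI object.
#' @param pixel_size_mm needed when `mask` is an ROI object.
#' @return list with `mean`, `stdev`, `n_pixels`.
#' @export
roi_stats <- function(slice, mask, pixel_size_mm = NULL) {
  if (!is.logical(mask)) {
    if (is.null(pixel_size_mm)) stop("pixel_size_mm required for ROI objects")
    mask <- roi_mask(mask, dim(slice), pixel_size_mm)
  }
  v <- slice[mask]
  if (length(v) < 25) stop("ROI has fewer than 25 pixels")
  list(mean = mean(v), stdev = sd(v), n_pixels = length(v))
}

#' Standard ROI set for the uniformity/noise phantom
#'
#' Center 2.5 cm circle, a 2 cm thick ring at the periphery of the water, a
#' 19 cm circle covering most of the water, and a 2 cm thick air ring just
#' outside the phantom.
#'
#' @param phantom_diameter water cylinder diameter, mm.
#' @return named list of ROIs: `center`, `periphery`, `water`, `air`.
#' @export
water_phantom_rois <- function(phantom_diameter = 220) {
  r <- phantom_diameter / 2
  list(center    = circle_roi(c(0, 0), 25),
       periphery = ring_roi(c(0, 0), inner_diameter = 2 * (r - 25),
                            thickness = 20),
       water     = circle_roi(c(0, 0), 190),
       air       = ring_roi(c(0, 0), inner_diameter = phantom_diameter + 10,
                            thickness = 20))
}

#' Insert + background ROI pair for CNR
#'
#' The signal ROI is a 2.5 cm circle centered on the insert (0.8 cm for the
#' dense bone plug); the 1 cm thick background ring starts at the insert
#' boundary.
#'
#' @param center insert center, mm.
#' @param insert_diameter physical plug diameter, mm.
#' @param roi_diameter signal ROI diameter, mm.
#' @param background_thickness background ring thickness, mm.
#' @return list with `insert` ([circle_roi()]) and `background`
#'   ([ring_roi()]).
#' @export
insert_rois <- function(center, insert_diameter = 30, roi_diameter = 25,
                        background_thickness = 10) {
  list(insert = circle_roi(center, roi_diameter),
       background = ring_roi(center, inner_diameter = insert_diameter,
                             thickness = background_thickness))
}

roi_means <- function(slice, rois, pixel_size_mm) {
  lapply(rois, function(r) roi_stats(slice, r, pixel_size_mm))
}

#' Uniformity metric
#'
#' Percent closeness of the center and periphery means, normalized by the
#' water-air contrast:
#' `(1 - |mean(center) - mean(periphery)| / (mean(water) - mean(air))) * 100`.
#'
#' @param slice matrix of reconstructed values.
#' @param rois named list with `center`, `periphery`, `water`, `air` ROIs
#'   (or logical masks).
#' @param pixel_size_mm pixel size, mm.
#' @return uniformity in percent (100 = perfectly uniform).
#' @export
uniformity <- function(slice, rois, pixel_size_mm) {
  s <- roi_means(slice, rois[c("center", "periphery", "water", "air")],
                 pixel_size_mm)
  den <- s$water$mean - s$air$mean
  if (den <= 0) stop("water-air contrast is not positive (broken reconstruction?)")
  (1 - abs(s$center$mean - s$periphery$mean) / den) * 100
}

#' Noise metric
#'
#' Standard deviation of the water ROI normalized by the water-air contrast,
#' in percent: `stdev(water) / (mean(water) - mean(air)) * 100`.
#'
#' @inheritParams uniformity
#' @param rois named list with `water` and `air` ROIs (or masks).
#' @export
noise_metric <- function(slice, rois, pixel_size_mm) {
  s <- roi_means(slice, rois[c("water", "air")], pixel_size_mm)
  den <- s$water$mean - s$air$mean
  if (den <= 0) stop("water-air contrast is not positive (broken reconstruction?)")
  s$water$stdev / den * 100
}

#' Contrast-to-noise ratio
#'
#' `|mean(insert) - mean(background)| / (0.5 * (stdev(insert) +
#' stdev(background)))` — note the denominator is the average of the two
#' standard deviations.
#'
#' @param slice matrix of reconstructed values.
#' @param insert signal ROI ([circle_roi()] or mask).
#' @param background background ROI ([ring_roi()] or mask).
#' @param pixel_size_mm pixel size, mm.
#' @return CNR (dimensionless).
#' @export
cnr <- function(slice, insert, background, pixel_size_mm) {
  si <- roi_stats(slice, insert, pixel_size_mm)
  sb <- roi_stats(slice, background, pixel_size_mm)
  den <- 0.5 * (si$stdev + sb$stdev)
  num <- abs(si$mean - sb$mean)
  if (den == 0) {
    if (num == 0) return(0)
    stop("noiseless input: both ROI standard deviations are zero")
  }
  num / den
}

#' Aggregate a metric over consecutive slices
#'
#' Per-slice values with their mean and sample (n-1) standard deviation,
#' following the six-consecutive-slice averaging convention.
#'
#' @param values numeric vector of per-slice metric values.
#' @param n_slices number of slices to aggregate (default 6).
#' @return object of class `slice_metric`: list with `per_slice`, `mean`,
#'   `sd`, `n`.
#' @export
aggregate_slices <- function(values, n_slices = 6L) {
  if (length(values) < n_slices)
    stop(sprintf("need %d slices, got %d", n_slices, length(values)))
  v <- values[seq_len(n_slices)]
  s <- if (n_slices == 1L) {
    warning("single slice: SD undefined, reported as 0")
    0
  } else sd(v)
  structure(list(per_slice = v, mean = mean(v), sd = s, n = n_slices),
            class = "slice_metric")
}

#' @export
print.slice_metric <- function(x, ...) {
  cat(sprintf("%.4g +/- %.4g (n = %d slices)\n", x$mean, x$sd, x$n))
  invisible(x)
}
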