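#' Material specification
#'
#' A material is described by its electron density relative to water (rED)
#' and the linear attenuation coefficient it implies at MV energies, where
#' Compton scattering dominates and attenuation is, to good approximation,
#' proportional to electron density.
#'
#' @param name material name (used as the region label).
#' @param rED electron density relative to water (dimensionless, >= 0).
#' @param mu_water linear attenuation of water, mm^-1.
#' @return an object of class `material_spec` with fields `name`, `rED`, `mu`.
#' @examples
#' material_spec("muscle", 1.043)
#' @export
material_spec <- function(name, rED, mu_water = 0.005) {
  stopifnot(is.character(name), length(name) == 1L)
  mu <- red_to_mu(rED, mu_water)
  structure(list(name = name, rED = rED, mu = mu), class = "material_spec")
}

#' Relative electron density to linear attenuation
#'
#' Maps relative electron density to a linear attenuation coefficient under
#' the Compton-dominance assumption valid at megavoltage energies:
#' `mu = rED * mu_water`.
#'
#' @param rED relative electron density (>= 0).
#' @param mu_water linear attenuation of water, mm^-1 (> 0).
#' @return linear attenuation, mm^-1.
#' @examples
#' red_to_mu(0.459, 0.005)  # exhale-phase lung
#' @export
red_to_mu <- function(rED, mu_water = 0.005) {
  if (any(rED < 0)) stop("rED must be >= 0")
  if (mu_water <= 0) stop("mu_water must be > 0")
  rED * mu_water
}

#' Default insert set for the pelvis phantom
#'
#' Four tissue-equivalent plugs: muscle (rED 1.043), trabecular bone (1.117),
#' dense bone (1.513) and exhale-phase lung (0.459).
#'
#' @param mu_water linear attenuation of water, mm^-1.
#' @return list of [material_spec()] objects.
#' @export
default_inserts <- function(mu_water = 0.005) {
  list(
    material_spec("muscle",          1.043, mu_water),
    material_spec("trabecular_bone", 1.117, mu_water),
    material_spec("dense_bone",      1.513, mu_water),
    material_spec("lung_exhale",     0.459, mu_water)
  )
}

#' Water/air interface specification
#'
#' Describes the planar interface of a half-filled phantom used for edge
#' spread function measurements.
#'
#' @param axis grid axis the interface is perpendicular to ("x" or "y").
#' @param position mm coordinate of the interface plane.
#' @export
edge_spec <- function(axis = c("y", "x"), position = 0) {
  axis <- match.arg(axis)
  structure(list(axis = axis, position = position), class = "edge_spec")
}

new_voxel_phantom <- function(mu, labels, legend, spacing, origin,
                              edge = NULL, meta = list()) {
  stopifnot(identical(dim(mu), dim(labels)), all(spacing > 0))
  structure(list(mu = mu, labels = labels, legend = legend,
                 spacing = spacing, origin = origin, edge = edge,
                 meta = meta),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat("voxel_phantom:", paste(dim(x$mu), collapse = " x "),
      "voxels @", paste(x$spacing, collapse = " x "), "mm\n")
  cat("  regions:", paste(sprintf("%s=%d", names(x$legend), x$legend),
                          collapse = ", "), "\n")
  cat("  mu range: [", format(min(x$mu)), ",", format(max(x$mu)), "] mm^-1\n")
  invisible(x)
}

# pixel-center coordinate vectors for a centered grid of n pixels
grid_coords <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

#' Cylindrical water phantom
#'
#' Builds a voxelized water cylinder (default 220 mm diameter, 170 mm height)
#' used for uniformity and noise measurements; half filled it provides the
#' sharp water/air interface used for spatial resolution. The desk-scale
#' default is a single transverse slice; `n_slices > 1` extrudes it.
#'
#' Voxel membership is voxel-center-inside-region; physical coordinates refer
#' to voxel centers and the grid is centered on the cylinder axis.
#'
#' @param diameter,height cylinder dimensions, mm.
#' @param spacing in-plane voxel size, mm (must be <= diameter/8).
#' @param fill `"full"` or `"half"`; `"half"` fills the water on the negative
#'   side of `edge`.
#' @param edge an [edge_spec()]; default is a horizontal interface through the
#'   axis (`axis = "y"`, position 0).
#' @param mu_water water linear attenuation, mm^-1.
#' @param margin_mm air margin added around the cylinder (room for the
#'   outside-air ROI ring).
#' @param n_slices number of identical transverse slices to generate.
#' @return a `voxel_phantom`; labels: 0 air, 1 water.
#' @examples
#' ph <- make_cylinder_phantom(spacing = 2)
#' @export
make_cylinder_phantom <- function(diameter = 220, height = 170, spacing = 1,
                                  fill = c("full", "half"), edge = edge_spec(),
                                  mu_water = 0.005, margin_mm = 30,
                                  n_slices = 1L) {
  fill <- match.arg(fill)
  if (diameter <= 0 || height <= 0 || spacing <= 0)
    stop("diameter, height and spacing must be > 0")
  if (spacing > diameter / 8)
    stop("spacing too coarse to define ROIs (must be <= diameter/8)")
  r <- diameter / 2
  n <- 2L * ceiling((r + margin_mm) / spacing)
  xs <- grid_coords(n, spacing)
  X <- matrix(xs, n, n)
  Y <- matrix(xs, n, n, byrow = TRUE)
  inside <- (X^2 + Y^2) < r^2
  if (fill == "half") {
    stopifnot(inherits(edge, "edge_spec"))
    ext <- r
    if (abs(edge$position) >= ext)
      stop("edge position must lie strictly inside the phantom")
    side <- if (edge$axis == "y") Y < edge$position else X < edge$position
    inside <- inside & side
  } else {
    edge <- NULL
  }
  mu <- matrix(0, n, n); mu[inside] <- mu_water
  lab <- matrix(0L, n, n); lab[inside] <- 1L
  if (n_slices > 1L) {
    mu <- array(mu, dim = c(n, n, n_slices))
    lab <- array(lab, dim = c(n, n, n_slices))
  }
  new_voxel_phantom(mu, lab, c(air = 0L, water = 1L),
                    spacing = c(spacing, spacing, min(height, spacing)),
                    origin = c(xs[1], xs[1], 0), edge = edge,
                    meta = list(kind = "cylinder", diameter = diameter,
                                height = height, mu_water = mu_water))
}

#' Pelvis-shaped contrast phantom
#'
#' An elliptical water body (5 cm thick axially in the physical phantom) with
#' up to eight 3 cm diameter cylindrical inserts of configurable relative
#' electron density, centered on a 12 cm diameter circle around the phantom
#' center and equally spaced in angle.
#'
#' @param spacing voxel size, mm.
#' @param inserts list of [material_spec()]; at most 8.
#' @param mu_water water attenuation, mm^-1.
#' @param semi_axes ellipse semi-axes (x, y), mm.
#' @param insert_ring_diameter diameter of the circle of insert centers, mm.
#' @param insert_diameter insert plug diameter, mm.
#' @param start_angle_deg angular position of the first insert.
#' @param margin_mm air margin around the ellipse.
#' @return a `voxel_phantom`; labels: 0 air, 1 water, 2.. inserts (named in
#'   the legend by material).
#' @export
make_pelvis_phantom <- function(spacing = 1, inserts = default_inserts(mu_water),
                                mu_water = 0.005, semi_axes = c(170, 120),
                                insert_ring_diameter = 120,
                                insert_diameter = 30,
                                start_angle_deg = 0, margin_mm = 25) {
  if (length(inserts) > 8) stop("at most 8 inserts")
  stopifnot(all(vapply(inserts, inherits, TRUE, "material_spec")))
  a <- semi_axes[1]; b <- semi_axes[2]
  rins <- insert_diameter / 2
  rc <- insert_ring_diameter / 2
  k <- length(inserts)
  if (k > 1) {
    gap <- 2 * rc * sin(pi / k)
    if (gap <= insert_diameter) stop("inserts overlap at this ring diameter")
  }
  n <- 2L * ceiling((max(a, b) + margin_mm) / spacing)
  xs <- grid_coords(n, spacing)
  X <- matrix(xs, n, n)
  Y <- matrix(xs, n, n, byrow = TRUE)
  body <- (X / a)^2 + (Y / b)^2 < 1
  mu <- matrix(0, n, n); mu[body] <- mu_water
  lab <- matrix(0L, n, n); lab[body] <- 1L
  legend <- c(air = 0L, water = 1L)
  centers <- list()
  if (k > 0) {
    ang <- (start_angle_deg + (seq_len(k) - 1) * 360 / k) * pi / 180
    for (i in seq_len(k)) {
      cx <- rc * cos(ang[i]); cy <- rc * sin(ang[i])
      if ((cx / a)^2 + (cy / b)^2 >= 1)
        stop("insert ring lies outside the phantom body")
      m <- ((X - cx)^2 + (Y - cy)^2) < rins^2
      mu[m] <- inserts[[i]]$mu
      lab[m] <- i + 1L
      legend[inserts[[i]]$name] <- i + 1L
      centers[[inserts[[i]]$name]] <- c(cx, cy)
    }
  }
  new_voxel_phantom(mu, lab, legend,
                    spacing = c(spacing, spacing, spacing),
                    origin = c(xs[1], xs[1], 0),
                    meta = list(kind = "pelvis", semi_axes = semi_axes,
                                insert_diameter = insert_diameter,
                                insert_centers = centers,
                                inserts = inserts, mu_water = mu_water,
                                thickness_mm = 50))
}

#' Write / read a phantom as multi-page TIFF plus YAML sidecar
#'
#' The attenuation grid is stored as 32-bit float TIFF pages; spacing,
#' origin and the label legend (with the label grid run-length encoded) go in
#' a YAML sidecar next to it.
#'
#' @param phantom a `voxel_phantom`.
#' @param path TIFF file path; the sidecar is `<path>.yaml`.
#' @return `write_phantom_tiff` returns `path` invisibly;
#'   `read_phantom_tiff` returns the restored `voxel_phantom`.
#' @export
write_phantom_tiff <- function(phantom, path) {
  mu <- phantom$mu
  if (length(dim(mu)) == 2L) mu <- array(mu, c(dim(mu), 1L))
  pages <- lapply(seq_len(dim(mu)[3]), function(k) mu[, , k])
  # tiff writes [row, col]; keep the grid as-is and record the convention
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  rle_lab <- rle(as.integer(phantom$labels))
  side <- list(spacing = as.numeric(phantom$spacing),
               origin = as.numeric(phantom$origin),
               dim = as.integer(dim(phantom$mu)),
               legend = as.list(phantom$legend),
               labels_rle = list(lengths = rle_lab$lengths,
                                 values = rle_lab$values),
               edge = if (!is.null(phantom$edge))
                 list(axis = phantom$edge$axis,
                      position = phantom$edge$position))
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_phantom_tiff
#' @export
read_phantom_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  d <- as.integer(side$dim)
  mu <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  mu <- array(mu, dim = d)
  labels <- array(inverse.rle(list(
    lengths = as.integer(side$labels_rle$lengths),
    values = as.integer(side$labels_rle$values))), dim = d)
  legend <- unlist(side$legend)
  storage.mode(legend) <- "integer"
  edge <- if (!is.null(side$edge))
    edge_spec(side$edge$axis, side$edge$position)
  new_voxel_phantom(mu, labels, legend, as.numeric(side$spacing),
                    as.numeric(side$origin), edge = edge)
}

# one transverse slice of a phantom as a plain matrix
phantom_slice <- function(phantom, k = 1L) {
  if (length(dim(phantom$mu)) == 2L) phantom$mu else phantom$mu[, , k]
}
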