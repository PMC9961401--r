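# Kernel-smoothed probability density surfaces of nest subsets; diagnostic
# maps only, no inference is derived from them.

#' Reference ("ad hoc") kernel bandwidth
#'
#' The bivariate-normal reference rule used by home-range kernel
#' estimators: `h = 0.5 * (sd_x + sd_y) * n^(-1/6)`, in metres.
#'
#' @param xy Two-column coordinate matrix (at least two points with
#'   non-zero dispersion).
#' @return Bandwidth in metres.
#' @examples
#' xy <- cbind(scale(rnorm(64)), scale(rnorm(64)))  # unit SDs
#' href_bandwidth(xy)  # 64^(-1/6) = 0.5
#' @export
href_bandwidth <- function(xy) {
  xy <- if (inherits(xy, "mpp")) nest_coords(xy) else as.matrix(xy)
  n <- nrow(xy)
  if (n < 2L) stop("need at least 2 points")
  s <- 0.5 * (stats::sd(xy[, 1]) + stats::sd(xy[, 2]))
  if (s == 0) stop("zero dispersion")
  s * n^(-1 / 6)
}

#' Gaussian kernel density surface
#'
#' Mean of isotropic Gaussian kernels (SD `h`) centred at the points,
#' evaluated at the centres of a square grid: a probability density whose
#' discrete integral `sum(z) * cell^2` is within 1% of one whenever the
#' grid extends at least ~4h beyond every point (the default extent pads
#' by 4h).
#'
#' @param xy Two-column coordinate matrix or a `mpp`.
#' @param h Bandwidth in metres; default [href_bandwidth()].
#' @param cell Grid cell side in metres (default 1).
#' @param extent Optional `c(xmin, xmax, ymin, ymax)`; default point range
#'   padded by `4 h`.
#' @return Object of class `density_raster`: grid centre coordinates `x`,
#'   `y`, density matrix `z` (rows follow `x`), `cell`, `h`, `origin`.
#' @export
kernel_density <- function(xy, h = NULL, cell = 1, extent = NULL) {
  xy <- if (inherits(xy, "mpp")) nest_coords(xy) else as.matrix(xy)
  n <- nrow(xy)
  if (n == 0L) stop("no points")
  h <- h %||% href_bandwidth(xy)
  if (!(h > 0) || !(cell > 0)) stop("h and cell must be positive")
  if (is.null(extent)) {
    extent <- c(min(xy[, 1]) - 4 * h, max(xy[, 1]) + 4 * h,
                min(xy[, 2]) - 4 * h, max(xy[, 2]) + 4 * h)
  }
  xg <- seq(extent[1] + cell / 2, extent[2], by = cell)
  yg <- seq(extent[3] + cell / 2, extent[4], by = cell)
  z <- matrix(0, nrow = length(xg), ncol = length(yg))
  for (i in seq_len(n)) {
    z <- z + outer(stats::dnorm(xg, xy[i, 1], h), stats::dnorm(yg, xy[i, 2], h))
  }
  z <- z / n
  structure(list(x = xg, y = yg, z = z, cell = cell, h = h,
                 origin = c(extent[1], extent[3])),
            class = "density_raster")
}

#' @export
print.density_raster <- function(x, ...) {
  cat(sprintf("density raster: %d x %d cells of %g m, h = %.2f m, integral = %.4f\n",
              length(x$x), length(x$y), x$cell, x$h, sum(x$z) * x$cell^2))
  invisible(x)
}

#' Plot a density surface with superimposed nest points
#'
#' @param x A `density_raster`.
#' @param points Optional two-column matrix of locations to overlay.
#' @param ... Passed to [graphics::image()].
#' @export
plot.density_raster <- function(x, points = NULL, ...) {
  graphics::image(x$x, x$y, x$z, asp = 1, xlab = "x (m)", ylab = "y (m)",
                  col = grDevices::hcl.colors(24, "YlOrRd", rev = TRUE), ...)
  if (!is.null(points)) graphics::points(points, pch = 21, bg = "white")
  invisible(x)
}

#' Export a density raster as an ESRI ASCII grid
#'
#' @param raster A `density_raster`.
#' @param path Output `.asc` path.
#' @return Invisibly, `path`.
#' @export
write_asc <- function(raster, path) {
  stopifnot(inherits(raster, "density_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", length(raster$x)),
               sprintf("nrows %d", length(raster$y)),
               sprintf("xllcorner %.6f", raster$origin[1]),
               sprintf("yllcorner %.6f", raster$origin[2]),
               sprintf("cellsize %.6f", raster$cell),
               "NODATA_value -9999"), con)
  for (j in rev(seq_along(raster$y))) {  # ESRI grids run top row first
    writeLines(paste(formatC(raster$z[, j], format = "g", digits = 8),
                     collapse = " "), con)
  }
  invisible(path)
}
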