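# Study windows: simple planar polygons (metres) bounding a survey site.

#' Construct a study window
#'
#' A study window is a simple (non-self-intersecting) planar polygon in a
#' local metric frame, representing the surveyed grassland. All spatial
#' statistics are computed relative to a window.
#'
#' @param ring Two-column matrix (or data frame) of vertex coordinates in
#'   metres, listed in order around the boundary. A closing repeat of the
#'   first vertex is optional.
#' @return An object of class `study_window` with elements `ring` (open
#'   vertex matrix) and `area` (m^2, shoelace formula).
#' @examples
#' w <- study_window(cbind(c(0, 65, 65, 0), c(0, 0, 65, 65)))
#' window_area(w)
#' @export
study_window <- function(ring) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2L || !is.numeric(ring)) {
    stop("ring must be a numeric two-column matrix of vertices")
  }
  storage.mode(ring) <- "double"
  n <- nrow(ring)
  if (n >= 2L && all(ring[1L, ] == ring[n, ])) {
    ring <- ring[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3L) stop("degenerate window: fewer than 3 distinct vertices")
  if (anyNA(ring)) stop("window vertices contain NA")
  area <- shoelace_area(ring)
  if (area <= 0) stop("degenerate window: zero area")
  if (!ring_is_simple(ring)) stop("window polygon is self-intersecting")
  structure(list(ring = ring, area = area), class = "study_window")
}

#' @export
print.study_window <- function(x, ...) {
  bb <- window_bbox(x)
  cat(sprintf("study window: %d vertices, area %.1f m^2, bbox [%.1f, %.1f] x [%.1f, %.1f]\n",
              nrow(x$ring), x$area, bb[1], bb[2], bb[3], bb[4]))
  invisible(x)
}

shoelace_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

# Proper-intersection test between non-adjacent boundary edges.
ring_is_simple <- function(ring) {
  n <- nrow(ring)
  seg <- cbind(ring, rbind(ring[-1L, , drop = FALSE], ring[1L, , drop = FALSE]))
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  for (i in seq_len(n - 2L)) {
    for (j in seq.int(i + 2L, n)) {
      if (i == 1L && j == n) next  # adjacent around the ring
      a <- seg[i, ]; b <- seg[j, ]
      o1 <- orient(a[1], a[2], a[3], a[4], b[1], b[2])
      o2 <- orient(a[1], a[2], a[3], a[4], b[3], b[4])
      o3 <- orient(b[1], b[2], b[3], b[4], a[1], a[2])
      o4 <- orient(b[1], b[2], b[3], b[4], a[3], a[4])
      if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Rectangular study window
#'
#' @param xmin,xmax,ymin,ymax Rectangle bounds in metres.
#' @return A `study_window`.
#' @export
rectangle_window <- function(xmin, xmax, ymin, ymax) {
  study_window(cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax)))
}

#' Default window from point locations
#'
#' Bounding rectangle of the points, expanded by `buffer` metres on each
#' side. Used when no surveyed boundary polygon is available.
#'
#' @param xy Two-column coordinate matrix.
#' @param buffer Buffer width in metres (default 2).
#' @return A `study_window`.
#' @export
bounding_window <- function(xy, buffer = 2) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 1L) stop("no points to bound")
  rectangle_window(min(xy[, 1]) - buffer, max(xy[, 1]) + buffer,
                   min(xy[, 2]) - buffer, max(xy[, 2]) + buffer)
}

#' @rdname study_window
#' @param window A `study_window`.
#' @export
window_area <- function(window) {
  stopifnot(inherits(window, "study_window"))
  window$area
}

window_bbox <- function(window) {
  r <- window$ring
  c(xmin = min(r[, 1]), xmax = max(r[, 1]), ymin = min(r[, 2]), ymax = max(r[, 2]))
}

closed_ring <- function(window) {
  rbind(window$ring, window$ring[1L, , drop = FALSE])
}

#' Test whether points fall inside a study window
#'
#' Points on (or within `tol` of) the boundary count as inside.
#'
#' @param window A `study_window`.
#' @param xy Two-column coordinate matrix.
#' @param tol Boundary tolerance in metres.
#' @return Logical vector, one entry per point.
#' @export
points_in_window <- function(window, xy, tol = 1e-8) {
  stopifnot(inherits(window, "study_window"))
  xy <- matrix(as.numeric(xy), ncol = 2L)
  if (nrow(xy) == 0L) return(logical(0))
  inside <- mgcv::in.out(closed_ring(window), xy)
  if (any(!inside) && tol > 0) {
    idx <- which(!inside)
    inside[idx] <- boundary_distance(window, xy[idx, , drop = FALSE]) <= tol
  }
  inside
}

boundary_distance <- function(window, xy) {
  ring <- window$ring
  n <- nrow(ring)
  a <- ring
  b <- rbind(ring[-1L, , drop = FALSE], ring[1L, , drop = FALSE])
  vapply(seq_len(nrow(xy)), function(i) {
    p <- xy[i, ]
    dx <- b[, 1] - a[, 1]; dy <- b[, 2] - a[, 2]
    len2 <- dx^2 + dy^2
    t <- pmin(1, pmax(0, ((p[1] - a[, 1]) * dx + (p[2] - a[, 2]) * dy) / pmax(len2, 1e-300)))
    qx <- a[, 1] + t * dx; qy <- a[, 2] + t * dy
    sqrt(min((p[1] - qx)^2 + (p[2] - qy)^2))
  }, numeric(1))
}

#' Read a study window from GeoJSON
#'
#' Accepts a GeoJSON `Polygon` geometry (outer ring; holes are not
#' supported), either bare or wrapped in a Feature/FeatureCollection.
#' Coordinates are taken to be planar metres in the local site frame.
#'
#' @param path Path to a GeoJSON file.
#' @return A `study_window`.
#' @export
window_from_geojson <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  geom <- g
  if (identical(g$type, "FeatureCollection")) geom <- g$features$geometry
  if (identical(geom$type[1], "Feature")) geom <- geom$geometry
  type <- geom$type[1]
  if (!identical(type, "Polygon")) {
    stop("unsupported GeoJSON geometry type: ", type, " (expected Polygon)")
  }
  coords <- geom$coordinates
  if (is.list(coords)) coords <- coords[[1]]
  if (length(dim(coords)) == 3L) coords <- coords[1, , ]
  study_window(coords)
}

#' Write a study window to GeoJSON
#'
#' @param window A `study_window`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
window_to_geojson <- function(window, path) {
  stopifnot(inherits(window, "study_window"))
  ring <- closed_ring(window)
  obj <- list(type = "Polygon",
              coordinates = list(lapply(seq_len(nrow(ring)), function(i) ring[i, ])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Fraction of each rectangular cell lying inside the window, estimated on a
# k x k lattice of sample points per cell (exact for cells wholly in/out).
cell_cover_fraction <- function(window, cells, k = 8L) {
  m <- nrow(cells)
  off <- (seq_len(k) - 0.5) / k
  pts <- matrix(0, nrow = m * k * k, ncol = 2L)
  row <- 1L
  for (i in seq_len(m)) {
    gx <- cells$xmin[i] + off * (cells$xmax[i] - cells$xmin[i])
    gy <- cells$ymin[i] + off * (cells$ymax[i] - cells$ymin[i])
    pts[row:(row + k * k - 1L), ] <- cbind(rep(gx, times = k), rep(gy, each = k))
    row <- row + k * k
  }
  inside <- mgcv::in.out(closed_ring(window), pts)
  colMeans(matrix(inside, nrow = k * k))
}
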