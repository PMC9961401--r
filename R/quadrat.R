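# Quadrat counts, variance-mean ratios, and two-sided Monte Carlo tests of
# Complete Spatial Randomness at a ladder of grid scales.

#' Quadrat counts on a square grid
#'
#' Tiles the window's bounding box with axis-aligned `d` x `d` cells
#' anchored at its lower-left corner. Cells are half-open,
#' `[x0, x0 + d) x [y0, y0 + d)`, so a point on a shared interior edge is
#' counted once, in the cell with the larger index (points exactly on the
#' bounding box's upper/right edge stay in the last cell). Cells whose
#' overlap with the window is below `min_cover` of the cell area are
#' dropped, and points falling in dropped cells are excluded from the
#' quadrat analysis; this avoids spuriously low counts in boundary slivers
#' of irregular windows.
#'
#' @param pattern A `mpp`, or a two-column coordinate matrix (then
#'   `window` is required or defaults to the buffered bounding box).
#' @param d Quadrat width in metres.
#' @param window Optional `study_window` when `pattern` is a matrix.
#' @param min_cover Minimum inside-window area fraction for a cell to be
#'   retained (default 0.5).
#' @return Object of class `quadrat_counts`: `counts` (per retained cell),
#'   `cells` (geometry and cover of every cell), `d`, `n_excluded`.
#' @export
quadrat_counts <- function(pattern, d, window = NULL, min_cover = 0.5) {
  if (!(d > 0)) stop("quadrat width d must be positive")
  if (inherits(pattern, "mpp")) {
    xy <- nest_coords(pattern)
    window <- pattern$window
  } else {
    xy <- as.matrix(pattern)
    window <- window %||% bounding_window(xy, buffer = 2)
  }
  if (nrow(xy) == 0L) stop("no points")
  bb <- window_bbox(window)
  x0 <- bb[["xmin"]]; y0 <- bb[["ymin"]]
  nx <- ceiling((bb[["xmax"]] - x0) / d)
  ny <- ceiling((bb[["ymax"]] - y0) / d)
  cells <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  cells$xmin <- x0 + (cells$ix - 1L) * d
  cells$xmax <- cells$xmin + d
  cells$ymin <- y0 + (cells$iy - 1L) * d
  cells$ymax <- cells$ymin + d
  cells$cover <- cell_cover_fraction(window, cells)
  cells$retained <- cells$cover >= min_cover
  if (!any(cells$retained)) stop("no quadrats retained at d = ", d)

  ix <- pmin(floor((xy[, 1] - x0) / d) + 1L, nx)
  iy <- pmin(floor((xy[, 2] - y0) / d) + 1L, ny)
  cell_of <- (iy - 1L) * nx + ix
  ret_ids <- which(cells$retained)
  counts <- tabulate(match(cell_of, ret_ids), nbins = length(ret_ids))
  names(counts) <- sprintf("c%02d_%02d", cells$ix[ret_ids], cells$iy[ret_ids])
  structure(list(counts = counts, cells = cells, d = d,
                 n_excluded = sum(!cell_of %in% ret_ids)),
            class = "quadrat_counts")
}

#' Variance-mean ratio of quadrat counts
#'
#' Sample variance (denominator n - 1) of the counts divided by their
#' mean: 1 in expectation under a Poisson (CSR) pattern, above 1 for
#' clumped patterns, below 1 for regular ones.
#'
#' @param counts Numeric count vector or a `quadrat_counts` object.
#' @return The ratio.
#' @examples
#' vmr(c(0, 0, 4, 0))  # mean 1, sample variance 4 -> 4
#' @export
vmr <- function(counts) {
  if (inherits(counts, "quadrat_counts")) counts <- counts$counts
  if (length(counts) < 2L) stop("need at least 2 quadrats")
  m <- mean(counts)
  if (m == 0) stop("empty quadrat system")
  stats::var(counts) / m
}

quadrat_chi2 <- function(counts) {
  m <- mean(counts)
  sum((counts - m)^2 / m)
}

#' Monte Carlo quadrat test of Complete Spatial Randomness
#'
#' Computes the Pearson chi-square statistic of the observed quadrat
#' counts, then generates `R` replicate count vectors by placing the same
#' number of points uniformly over the retained quadrat region (CSR
#' conditioned on the observed point total: a symmetric multinomial over
#' the equal-area retained cells). One-sided Monte Carlo p-values use the
#' `(matching replicates + 1) / (R + 1)` convention; the two-sided p is
#' twice the smaller one, capped at 1.
#'
#' @param pattern,d,window,min_cover As in [quadrat_counts()].
#' @param R Number of CSR replicates (default 999).
#' @param seed Optional seed for reproducibility.
#' @return Object of class `quadrat_result` with `d`, `counts`,
#'   `n_quadrats`, `vmr`, `chi2_obs`, `p_mc` (two-sided), `p_lower`,
#'   `p_upper`, `R`, `seed`.
#' @export
mc_csr_test <- function(pattern, d, R = 999L, seed = NULL, window = NULL,
                        min_cover = 0.5) {
  if (R < 1L) stop("R must be at least 1")
  qc <- quadrat_counts(pattern, d, window = window, min_cover = min_cover)
  counts <- qc$counts
  k <- length(counts)
  if (k < 2L) stop("need at least 2 retained quadrats")
  n <- sum(counts)
  if (n == 0L) stop("empty quadrat system")
  chi2_obs <- quadrat_chi2(counts)
  m <- n / k
  chi2_rep <- with_seed(seed, {
    sim <- stats::rmultinom(R, n, rep.int(1 / k, k))
    colSums((sim - m)^2) / m
  })
  p_lo <- (sum(chi2_rep <= chi2_obs) + 1) / (R + 1)
  p_hi <- (sum(chi2_rep >= chi2_obs) + 1) / (R + 1)
  structure(list(d = d, counts = counts, n_quadrats = k, n_points = n,
                 vmr = vmr(counts), chi2_obs = chi2_obs,
                 p_mc = min(1, 2 * min(p_lo, p_hi)),
                 p_lower = p_lo, p_upper = p_hi, R = R, seed = seed,
                 n_excluded = qc$n_excluded),
            class = "quadrat_result")
}

#' @export
print.quadrat_result <- function(x, ...) {
  cat(sprintf("CSR quadrat test: d = %g m, %d quadrats, %d points\n",
              x$d, x$n_quadrats, x$n_points))
  cat(sprintf("  VMR = %.2f, chi2 = %.2f, two-sided Monte Carlo p = %.3g (R = %d)\n",
              x$vmr, x$chi2_obs, x$p_mc, x$R))
  invisible(x)
}

#' CSR tests across a ladder of quadrat widths
#'
#' @param pattern A `mpp`.
#' @param d_ladder Increasing quadrat widths in metres.
#' @param R,seed As in [mc_csr_test()].
#' @return Data frame with one row per width: `d`, `n_quadrats`, `vmr`,
#'   `chi2_obs`, `p_mc`.
#' @export
csr_profile <- function(pattern, d_ladder = seq(4, 32, by = 4), R = 999L,
                        seed = NULL) {
  rows <- lapply(seq_along(d_ladder), function(i) {
    s <- if (is.null(seed)) NULL else seed + i - 1L
    r <- mc_csr_test(pattern, d_ladder[i], R = R, seed = s)
    data.frame(d = r$d, n_quadrats = r$n_quadrats, n_points = r$n_points,
               vmr = r$vmr, chi2_obs = r$chi2_obs, p_mc = r$p_mc)
  })
  do.call(rbind, rows)
}
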