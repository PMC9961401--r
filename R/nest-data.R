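# Nest tables and marked point patterns: one record per nest x season, with
# species, colony-size class and per-parasite larvae counts as marks.

CORE_COLUMNS <- c("nest_id", "site", "season", "x", "y", "species", "size_class")
CANONICAL_TAXA <- c("teleius", "nausithous", "alcon", "microdon")
SIZE_LEVELS <- c("small", "medium", "large")
SEASON_LEVELS <- c("autumn", "spring")

larvae_columns <- function(records) grep("^larvae_", names(records), value = TRUE)

#' Taxa recorded in a nest table or pattern
#'
#' @param x A `mpp` pattern or a nest records data frame.
#' @return Character vector of parasite taxon names (suffixes of the
#'   `larvae_<taxon>` count columns).
#' @export
larvae_taxa <- function(x) {
  records <- if (inherits(x, "mpp")) x$records else x
  sub("^larvae_", "", larvae_columns(records))
}

validate_records <- function(records) {
  missing <- setdiff(CORE_COLUMNS, names(records))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  lc <- larvae_columns(records)
  if (!length(lc)) stop("missing required column(s): larvae_<taxon> (at least one)")
  for (col in lc) {
    v <- records[[col]]
    if (!is_count_vector(v)) {
      stop("invalid larvae counts in column ", col,
           ": counts must be non-negative integers")
    }
  }
  bad_season <- setdiff(unique(records$season), SEASON_LEVELS)
  if (length(bad_season)) {
    stop("unknown season value(s): ", paste(bad_season, collapse = ", "))
  }
  bad_size <- setdiff(unique(records$size_class), SIZE_LEVELS)
  if (length(bad_size)) {
    stop("unknown size_class value(s): ", paste(bad_size, collapse = ", "),
         " (expected small/medium/large)")
  }
  key <- paste(records$nest_id, records$season)
  if (anyDuplicated(key)) {
    stop("duplicated (nest_id, season) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  if (!is.numeric(records$x) || !is.numeric(records$y) ||
      anyNA(records$x) || anyNA(records$y)) {
    stop("coordinates x, y must be numeric and non-missing")
  }
  invisible(records)
}

#' Marked point pattern of ant nests
#'
#' Bundles the nest records of one site and one season with the study
#' window on which spatial statistics are computed. Every nest must lie
#' inside (or on the boundary of) the window.
#'
#' @param records Data frame with columns `nest_id`, `site`, `season`, `x`,
#'   `y`, `species`, `size_class` and one `larvae_<taxon>` count column per
#'   parasite taxon.
#' @param window A `study_window`, or `NULL` to use the bounding rectangle
#'   of the points buffered by 2 m.
#' @return An object of class `mpp` with elements `window` and `records`.
#' @export
marked_point_pattern <- function(records, window = NULL) {
  records <- as.data.frame(records)
  validate_records(records)
  if (length(unique(records$site)) > 1L) {
    stop("a pattern holds one site; got: ",
         paste(unique(records$site), collapse = ", "))
  }
  if (length(unique(records$season)) > 1L) {
    stop("a pattern holds one season; got: ",
         paste(unique(records$season), collapse = ", "))
  }
  xy <- cbind(records$x, records$y)
  if (is.null(window)) window <- bounding_window(xy, buffer = 2)
  stopifnot(inherits(window, "study_window"))
  inside <- points_in_window(window, xy)
  if (any(!inside)) {
    stop("nest(s) outside the study window: ",
         paste(records$nest_id[!inside], collapse = ", "))
  }
  rownames(records) <- NULL
  structure(list(window = window, records = records), class = "mpp")
}

#' @export
print.mpp <- function(x, ...) {
  r <- x$records
  cat(sprintf("marked nest pattern: %s, %s, %d nests, window %.0f m^2\n",
              r$site[1], r$season[1], nrow(r), window_area(x$window)))
  inf <- is_infested(x, larvae_taxa(x))
  cat(sprintf("  species: %s\n",
              paste(sprintf("%s=%d", names(table(r$species)), table(r$species)),
                    collapse = ", ")))
  cat(sprintf("  infested by any recorded parasite: %d (%.0f%%)\n",
              sum(inf), 100 * mean(inf)))
  invisible(x)
}

#' Number of nests and coordinates of a pattern
#'
#' @param pattern A `mpp`.
#' @return `n_nests()`: integer count; `nest_coords()`: two-column matrix.
#' @export
n_nests <- function(pattern) nrow(pattern$records)

#' @rdname n_nests
#' @export
nest_coords <- function(pattern) {
  cbind(x = pattern$records$x, y = pattern$records$y)
}

#' Derived infestation indicator
#'
#' A nest is infested by a taxon set when its larvae counts summed over the
#' set are positive. Infestation is always derived from the per-taxon
#' counts, never stored, so any taxon subset (a single parasite, "any
#' parasite", "all but the focal one") is computed uniformly.
#'
#' @param x A `mpp` pattern or nest records data frame.
#' @param taxa Character vector of taxon names; `character(0)` yields all
#'   `FALSE`.
#' @return Logical vector, one entry per nest.
#' @examples
#' p <- simulate_site_pair(synthetic_config(seed = 1))$autumn
#' mean(is_infested(p, "teleius"))
#' @export
is_infested <- function(x, taxa = "teleius") {
  records <- if (inherits(x, "mpp")) x$records else x
  if (!length(taxa)) return(rep(FALSE, nrow(records)))
  cols <- paste0("larvae_", taxa)
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    stop("unknown parasite taxon/taxa: ",
         paste(sub("^larvae_", "", missing), collapse = ", "))
  }
  rowSums(records[, cols, drop = FALSE]) > 0
}

#' Read a nest table, split into site-season patterns
#'
#' The nest table is a UTF-8 CSV with a header row and columns `nest_id`,
#' `site`, `season`, `x`, `y`, `species`, `size_class`, plus one
#' `larvae_<taxon>` column per parasite taxon. Canonical taxa (teleius,
#' nausithous, alcon, microdon) missing from the file are added as zero
#' columns. When no window file is supplied the window of each site is the
#' bounding rectangle of that site's points (both seasons) buffered by 2 m,
#' so autumn and spring share a frame.
#'
#' @param path CSV file path.
#' @param window Optional: a GeoJSON polygon file path or a `study_window`
#'   applied to every site.
#' @return Named list of `mpp` patterns, one per site:season combination
#'   present, names `"<site>:<season>"`.
#' @export
read_nest_table <- function(path, window = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_schema <- setdiff(CORE_COLUMNS, names(df))
  if (length(validate_schema)) {
    stop("missing required column(s): ", paste(validate_schema, collapse = ", "))
  }
  if (!length(larvae_columns(df))) {
    stop("missing required column(s): larvae_<taxon> (at least one)")
  }
  for (taxon in setdiff(CANONICAL_TAXA, larvae_taxa(df))) {
    df[[paste0("larvae_", taxon)]] <- 0L
  }
  df <- df[, c(CORE_COLUMNS, sort(larvae_columns(df)))]  # canonical order
  validate_records(df)
  win <- window
  if (is.character(win)) win <- window_from_geojson(win)
  out <- list()
  for (site in unique(df$site)) {
    site_rows <- df[df$site == site, , drop = FALSE]
    site_win <- win %||% bounding_window(cbind(site_rows$x, site_rows$y), buffer = 2)
    for (season in intersect(SEASON_LEVELS, unique(site_rows$season))) {
      rec <- site_rows[site_rows$season == season, , drop = FALSE]
      out[[paste(site, season, sep = ":")]] <- marked_point_pattern(rec, site_win)
    }
  }
  out
}

#' Write patterns back to the standard nest-table CSV
#'
#' Field-for-field inverse of [read_nest_table()]: reading a written file
#' reproduces the same records.
#'
#' @param patterns A single `mpp` or a list of them.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_nest_table <- function(patterns, path) {
  if (inherits(patterns, "mpp")) patterns <- list(patterns)
  recs <- lapply(patterns, function(p) p$records)
  all_cols <- unique(unlist(lapply(recs, names)))
  lc <- sort(grep("^larvae_", all_cols, value = TRUE))
  cols <- c(CORE_COLUMNS, lc)
  recs <- lapply(recs, function(r) {
    for (col in setdiff(lc, names(r))) r[[col]] <- 0L
    r[, cols, drop = FALSE]
  })
  df <- do.call(rbind, recs)
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
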