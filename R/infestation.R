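# Infestation-rate tabulation and chi-square season contrasts.

#' Infestation rate of a nest subset
#'
#' Counts nests infested by a taxon set over the nests matching the
#' filters. On a marked point pattern the numerator is the number of nests
#' whose larvae counts summed over `taxa` are positive. On the packaged
#' survey fixture ([table1_fixture()]) the per-taxon infested-nest cells
#' are summed, treating them as disjoint sets of nests (a documented
#' approximation: a few nests carried two taxa).
#'
#' @param source A `mpp`, a list of them (as from [read_nest_table()]), or
#'   a `table1_fixture`.
#' @param taxa Character vector of parasite taxa; `character(0)` gives a
#'   zero rate.
#' @param site,season,species Optional filters (fixture and pattern-list
#'   sources).
#' @return Object of class `rate_estimate`: `numerator`, `denominator`,
#'   `proportion`, and the filters used.
#' @examples
#' infestation_rate(table1_fixture(), "teleius", site = "Krakow", season = "autumn")
#' @export
infestation_rate <- function(source, taxa = "teleius", site = NULL,
                             season = NULL, species = NULL) {
  if (inherits(source, "table1_fixture")) {
    fx <- source
    if (!is.null(site)) fx <- fx[fx$site %in% site, , drop = FALSE]
    if (!is.null(season)) fx <- fx[fx$season %in% season, , drop = FALSE]
    if (!is.null(species)) fx <- fx[fx$species %in% species, , drop = FALSE]
    if (!nrow(fx) || sum(fx$nests) == 0) stop("no nests match")
    num <- if (!length(taxa)) 0L else {
      cols <- paste0("infested_", taxa)
      missing <- setdiff(cols, names(fx))
      if (length(missing)) {
        stop("unknown parasite taxon/taxa: ",
             paste(sub("^infested_", "", missing), collapse = ", "))
      }
      sum(fx[, cols])
    }
    den <- sum(fx$nests)
  } else {
    if (inherits(source, "mpp")) source <- list(source)
    recs <- do.call(rbind, lapply(source, function(p) {
      p$records[, c(CORE_COLUMNS, larvae_columns(p$records))]
    }))
    if (!is.null(site)) recs <- recs[recs$site %in% site, , drop = FALSE]
    if (!is.null(season)) recs <- recs[recs$season %in% season, , drop = FALSE]
    if (!is.null(species)) recs <- recs[recs$species %in% species, , drop = FALSE]
    if (!nrow(recs)) stop("no nests match")
    num <- sum(is_infested(recs, taxa))
    den <- nrow(recs)
  }
  structure(list(numerator = num, denominator = den,
                 proportion = num / den, site = site, season = season,
                 species = species, taxa = taxa),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% infested (%s%s%s)\n", x$numerator, x$denominator,
              100 * x$proportion,
              paste(x$taxa, collapse = "+"),
              if (is.null(x$site)) "" else paste0(", ", paste(x$site, collapse = "/")),
              if (is.null(x$season)) "" else paste0(", ", paste(x$season, collapse = "/"))))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' `chi2 = sum (O - E)^2 / E` with expectations from the margins, one
#' degree of freedom; the optional Yates continuity correction shrinks
#' each `|O - E|` by 0.5 (floored at zero).
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @param correction Apply the continuity correction (default FALSE).
#' @return Object of class `contingency_result`: `table`, `chi2`, `df`,
#'   `p`, `correction`.
#' @export
chi2_2x2 <- function(table, correction = FALSE) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2")
  if (any(tab < 0) || anyNA(tab)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) stop("zero margin")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  dev <- abs(tab - E)
  if (correction) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / E)
  structure(list(table = tab, chi2 = chi2, df = 1L,
                 p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
                 correction = correction),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("chi-square (df = 1%s): chi2 = %.3f, p = %.3g\n",
              if (x$correction) ", Yates-corrected" else "", x$chi2, x$p))
  invisible(x)
}

#' Autumn vs spring infestation contrast
#'
#' Builds the 2x2 season-by-infestation table from the autumn and spring
#' rates of one site and applies [chi2_2x2()]. Both the uncorrected and
#' Yates-corrected statistics are carried on the result so either
#' convention is inspectable.
#'
#' @param source As in [infestation_rate()] (fixture or pattern list).
#' @param site Site to contrast.
#' @param taxa,species Passed to [infestation_rate()].
#' @param correction Which statistic the printed result uses.
#' @return A `contingency_result` with extra elements `rates` (the two
#'   `rate_estimate`s) and `corrected` (the Yates-corrected companion).
#' @export
season_contrast <- function(source, site, taxa = "teleius", species = NULL,
                            correction = FALSE) {
  ra <- infestation_rate(source, taxa, site = site, season = "autumn",
                         species = species)
  rs <- infestation_rate(source, taxa, site = site, season = "spring",
                         species = species)
  tab <- rbind(autumn = c(infested = ra$numerator,
                          empty = ra$denominator - ra$numerator),
               spring = c(infested = rs$numerator,
                          empty = rs$denominator - rs$numerator))
  res <- chi2_2x2(tab, correction = correction)
  res$rates <- list(autumn = ra, spring = rs)
  res$corrected <- chi2_2x2(tab, correction = TRUE)
  res
}
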