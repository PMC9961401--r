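# Distance-band adjacency, join-count statistics for categorical nest
# marks, and random-labelling Monte Carlo tests with directional
# hypotheses (greater = aggregation, less = segregation/repulsion).

#' Distance-band adjacency graph
#'
#' Two nests are neighbours when their Euclidean distance is at most `d`
#' (inclusive). Bands are cumulative: the edge set is monotonically
#' non-decreasing in `d`. Isolated nodes are retained.
#'
#' @param pattern A `mpp` or a two-column coordinate matrix.
#' @param d Neighbourhood distance in metres.
#' @return Object of class `dband_graph`: `d`, `n`, `edges` (two-column
#'   matrix of node pairs, i < j), `xy`.
#' @export
distance_band_graph <- function(pattern, d) {
  if (!(d > 0)) stop("distance threshold d must be positive")
  xy <- if (inherits(pattern, "mpp")) nest_coords(pattern) else as.matrix(pattern)
  n <- nrow(xy)
  if (n < 2L) stop("need at least 2 points")
  D <- as.matrix(stats::dist(xy))
  adj <- which(upper.tri(D) & D <= d, arr.ind = TRUE)
  edges <- cbind(i = adj[, 1L], j = adj[, 2L])
  structure(list(d = d, n = n, edges = edges, xy = xy), class = "dband_graph")
}

#' @export
print.dband_graph <- function(x, ...) {
  cat(sprintf("distance-band graph: %d nodes, %d edges at d <= %g m\n",
              x$n, nrow(x$edges), x$d))
  invisible(x)
}

check_labels <- function(graph, labels) {
  labels <- as.character(labels)
  if (length(labels) != graph$n) {
    stop("labels length (", length(labels), ") must equal node count (", graph$n, ")")
  }
  labels
}

#' Join-count statistic for a category pair
#'
#' Directed ("sum across nests") convention: each unordered adjacent pair
#' contributes twice, so for a single category `a` the statistic is twice
#' the number of edges with both endpoints labelled `a`, and for distinct
#' categories twice the number of edges joining them. Halve for the
#' undirected convention.
#'
#' @param graph A `dband_graph`.
#' @param labels Per-node categorical labels (length `n`).
#' @param a,b Category names; `a == b` counts within-category joins.
#' @param categories Optional universe of admissible categories (defaults
#'   to the labels present); an `a` or `b` outside it is an error.
#' @return Non-negative integer join count.
#' @examples
#' g <- distance_band_graph(rbind(c(0, 0), c(1, 0), c(0, 1)), d = 2)
#' join_count(g, c("A", "A", "B"), "A", "A")  # 2
#' join_count(g, c("A", "A", "B"), "A", "B")  # 4
#' @export
join_count <- function(graph, labels, a, b = a, categories = NULL) {
  stopifnot(inherits(graph, "dband_graph"))
  labels <- check_labels(graph, labels)
  categories <- categories %||% unique(labels)
  unknown <- setdiff(c(a, b), categories)
  if (length(unknown)) {
    stop("unknown category: ", paste(unknown, collapse = ", "))
  }
  la <- labels[graph$edges[, 1L]]
  lb <- labels[graph$edges[, 2L]]
  if (identical(a, b)) {
    2L * sum(la == a & lb == a)
  } else {
    2L * sum((la == a & lb == b) | (la == b & lb == a))
  }
}

#' Random-labelling Monte Carlo test of a join-count statistic
#'
#' Keeps nest locations (the graph) fixed and redistributes the labels
#' uniformly at random `R` times, comparing the observed join count with
#' the permutation distribution. Directional p-values follow the
#' `(matching replicates + 1) / (R + 1)` convention:
#' `greater` uses replicates `>=` the observed value (aggregation of like
#' marks), `less` uses `<=` (segregation of unlike marks). A constant
#' label vector makes the test degenerate: the result is flagged and
#' carries p = 1.
#'
#' @param graph A `dband_graph`.
#' @param labels Per-node categorical labels.
#' @param a,b Category pair, as in [join_count()].
#' @param hypothesis `"greater"` or `"less"`.
#' @param R Number of permutations (default 999).
#' @param seed Optional seed.
#' @param categories Optional category universe.
#' @return Object of class `join_count_result`: `statistic_name`, `pair`,
#'   `d`, `J_obs`, `null_mean`, `null_sd`, `hypothesis`, `p`, `R`,
#'   `seed`, `degenerate`.
#' @export
random_labelling_test <- function(graph, labels, a, b = a,
                                  hypothesis = c("greater", "less"),
                                  R = 999L, seed = NULL, categories = NULL) {
  stopifnot(inherits(graph, "dband_graph"))
  hypothesis <- match.arg(hypothesis)
  if (R < 1L) stop("R must be at least 1")
  labels <- check_labels(graph, labels)
  J_obs <- join_count(graph, labels, a, b, categories = categories)
  degenerate <- length(unique(labels)) < 2L || !any(labels == a) ||
    (!identical(a, b) && !any(labels == b))
  if (length(unique(labels)) < 2L) {
    warning("constant labels: random-labelling test is degenerate")
  }
  e1 <- graph$edges[, 1L]
  e2 <- graph$edges[, 2L]
  J_rep <- with_seed(seed, {
    vapply(seq_len(R), function(r) {
      lab <- sample(labels)
      la <- lab[e1]; lb <- lab[e2]
      if (identical(a, b)) {
        2 * sum(la == a & lb == a)
      } else {
        2 * sum((la == a & lb == b) | (la == b & lb == a))
      }
    }, numeric(1))
  })
  p <- if (hypothesis == "greater") {
    (sum(J_rep >= J_obs) + 1) / (R + 1)
  } else {
    (sum(J_rep <= J_obs) + 1) / (R + 1)
  }
  structure(list(statistic_name = paste0("J_", a, b), pair = c(a, b),
                 d = graph$d, J_obs = J_obs, null_mean = mean(J_rep),
                 null_sd = stats::sd(J_rep), hypothesis = hypothesis,
                 p = p, R = R, seed = seed, degenerate = degenerate),
            class = "join_count_result")
}

#' @export
print.join_count_result <- function(x, ...) {
  cat(sprintf("%s at d = %g m: J = %d, null %.1f +/- %.1f, p(%s) = %.3g%s\n",
              x$statistic_name, x$d, x$J_obs, x$null_mean, x$null_sd,
              x$hypothesis, x$p, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# Label derivations for the survey's mark dichotomies.
derive_labels <- function(pattern, mark, taxa = "teleius",
                          doubly_infested = c("focal_first", "exclude")) {
  doubly_infested <- match.arg(doubly_infested)
  r <- pattern$records
  keep <- rep(TRUE, nrow(r))
  labels <- switch(mark,
    species = ifelse(r$species == "scabrinodis", "s", "o"),
    size = ifelse(r$size_class %in% c("medium", "large"), "b", "s"),
    infestation = ifelse(is_infested(r, taxa), "I", "E"),
    focal_vs_other = {
      focal <- is_infested(r, taxa)
      other <- is_infested(r, setdiff(larvae_taxa(r), taxa))
      keep <- focal | other
      if (doubly_infested == "exclude") keep <- keep & !(focal & other)
      # focal-first precedence: a doubly infested nest counts as focal
      ifelse(focal, "T", "O")
    },
    stop("unknown mark spec: ", mark)
  )
  list(labels = labels[keep], keep = keep)
}

default_pairs <- function(mark) {
  switch(mark,
    species = list(c("s", "s"), c("o", "o"), c("s", "o")),
    size = list(c("b", "b"), c("s", "b")),
    infestation = list(c("I", "I"), c("E", "E"), c("I", "E")),
    focal_vs_other = list(c("T", "T"), c("O", "O"), c("T", "O")))
}

mark_categories <- function(mark) {
  switch(mark,
    species = c("s", "o"), size = c("b", "s"),
    infestation = c("I", "E"), focal_vs_other = c("T", "O"))
}

#' Join-count profile over category pairs and distance bands
#'
#' Sweeps [random_labelling_test()] over a ladder of neighbourhood
#' distances for a derived mark dichotomy:
#' \describe{
#'   \item{`species`}{`s` = *My. scabrinodis*, `o` = other Myrmica.}
#'   \item{`size`}{`b` = medium or large colony, `s` = small.}
#'   \item{`infestation`}{`I` = infested by the taxon set `taxa`,
#'     `E` = empty.}
#'   \item{`focal_vs_other`}{among infested nests only, `T` = hosts the
#'     focal taxon, `O` = hosts only other parasites; a doubly infested
#'     nest counts as focal by default (`doubly_infested = "focal_first"`),
#'     or can be excluded.}
#' }
#' Same-category pairs default to the `greater` (aggregation) hypothesis,
#' mixed pairs to `less` (segregation). An empty category yields a flagged
#' degenerate result rather than an error, so multi-scale sweeps never
#' abort.
#'
#' @param pattern A `mpp`.
#' @param mark One of `"species"`, `"size"`, `"infestation"`,
#'   `"focal_vs_other"`.
#' @param taxa Taxon set defining infestation for the infestation marks.
#' @param pairs List of category pairs (default: the standard pairs of the
#'   mark).
#' @param d_ladder Increasing neighbourhood distances (metres).
#' @param hypotheses Optional character vector parallel to `pairs`.
#' @param R,seed As in [random_labelling_test()].
#' @param doubly_infested Handling of nests hosting both the focal and
#'   another parasite in the `focal_vs_other` mark.
#' @return Object of class `join_count_profile`; `as.data.frame()` yields
#'   one row per pair x distance with site, season, statistic, `J_obs`,
#'   null summary, hypothesis and p.
#' @export
join_count_profile <- function(pattern, mark = c("species", "size", "infestation",
                                                 "focal_vs_other"),
                               taxa = "teleius", pairs = NULL,
                               d_ladder = seq(4, 32, by = 4),
                               hypotheses = NULL, R = 999L, seed = NULL,
                               doubly_infested = c("focal_first", "exclude")) {
  stopifnot(inherits(pattern, "mpp"))
  mark <- match.arg(mark)
  doubly_infested <- match.arg(doubly_infested)
  pairs <- pairs %||% default_pairs(mark)
  hypotheses <- hypotheses %||% vapply(pairs, function(p) {
    if (identical(p[1], p[2])) "greater" else "less"
  }, character(1))
  stopifnot(length(hypotheses) == length(pairs))

  der <- derive_labels(pattern, mark, taxa = taxa,
                       doubly_infested = doubly_infested)
  xy <- nest_coords(pattern)[der$keep, , drop = FALSE]
  cats <- mark_categories(mark)
  results <- list()
  idx <- 0L
  for (di in seq_along(d_ladder)) {
    if (nrow(xy) < 2L) break
    graph <- distance_band_graph(xy, d_ladder[di])
    for (pi in seq_along(pairs)) {
      idx <- idx + 1L
      s <- if (is.null(seed)) NULL else seed + idx
      pr <- pairs[[pi]]
      res <- suppressWarnings(
        random_labelling_test(graph, der$labels, pr[1], pr[2],
                              hypothesis = hypotheses[pi], R = R, seed = s,
                              categories = cats))
      results[[idx]] <- res
    }
  }
  structure(list(results = results, mark = mark, taxa = taxa,
                 site = pattern$records$site[1],
                 season = pattern$records$season[1], R = R, seed = seed),
            class = "join_count_profile")
}

#' @export
as.data.frame.join_count_profile <- function(x, ...) {
  rows <- lapply(x$results, function(r) {
    data.frame(site = x$site, season = x$season, mark = x$mark,
               statistic = r$statistic_name,
               pair = paste(r$pair, collapse = ""), d = r$d,
               J_obs = r$J_obs, null_mean = r$null_mean, null_sd = r$null_sd,
               hypothesis = r$hypothesis, p = r$p, degenerate = r$degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.join_count_profile <- function(x, ...) {
  cat(sprintf("join-count profile (%s marks), %s %s:\n", x$mark, x$site, x$season))
  print(as.data.frame(x)[, c("statistic", "d", "J_obs", "null_mean", "hypothesis", "p")],
        digits = 3)
  invisible(x)
}
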