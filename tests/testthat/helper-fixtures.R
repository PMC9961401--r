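# Shared fixtures and independent oracles, built in code at test time.

# A small nest records data frame; coordinates in a 20 x 20 m frame.
toy_records <- function(n = 6, season = "autumn", site = "Kosyn", seed = 1) {
  set.seed(seed)
  data.frame(nest_id = sprintf("N%02d", seq_len(n)), site = site,
             season = season,
             x = runif(n, 0, 20), y = runif(n, 0, 20),
             species = sample(c("scabrinodis", "rubra"), n, replace = TRUE),
             size_class = sample(c("small", "medium", "large"), n, replace = TRUE),
             larvae_teleius = rpois(n, 1),
             larvae_nausithous = 0L, larvae_alcon = 0L,
             larvae_microdon = rpois(n, 0.5),
             stringsAsFactors = FALSE)
}

toy_pattern <- function(...) marked_point_pattern(toy_records(...))

# Brute-force O(n^2) pairwise-distance edge oracle.
brute_edges <- function(xy, d) {
  n <- nrow(xy)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (sqrt(sum((xy[i, ] - xy[j, ])^2)) <= d) out <- rbind(out, c(i, j))
    }
  }
  out
}

# Exhaustive edge-scan join-count oracle (directed convention).
brute_join <- function(edges, labels, a, b) {
  J <- 0L
  for (k in seq_len(NROW(edges))) {
    la <- labels[edges[k, 1]]; lb <- labels[edges[k, 2]]
    if (a == b) {
      if (la == a && lb == a) J <- J + 2L
    } else if ((la == a && lb == b) || (la == b && lb == a)) {
      J <- J + 2L
    }
  }
  J
}

# All permutations of a vector (for exhaustive null enumeration, n <= 8).
all_perms <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- all_perms(v[-i])
    out <- rbind(out, cbind(v[i], sub))
  }
  out
}
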