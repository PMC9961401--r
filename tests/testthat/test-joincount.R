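# Distance-band graphs, join counts and the random-labelling test.

test_that("distance bands are inclusive and keep isolated nodes", {
  xy <- rbind(c(0, 0), c(3, 0), c(10, 0))
  g5 <- distance_band_graph(xy, 5)
  expect_equal(unname(g5$edges), cbind(1L, 2L), ignore_attr = TRUE)
  deg <- tabulate(c(g5$edges), nbins = 3)
  expect_equal(deg, c(1, 1, 0))
  g10 <- distance_band_graph(xy, 10)  # distance exactly 10 included
  expect_equal(nrow(g10$edges), 3)
  expect_error(distance_band_graph(xy[1, , drop = FALSE], 5), "at least 2")
})

test_that("edge sets equal the brute-force pairwise oracle and grow with d", {
  set.seed(8)
  xy <- cbind(runif(30, 0, 30), runif(30, 0, 30))
  prev <- 0
  for (d in c(4, 8, 12, 20)) {
    g <- distance_band_graph(xy, d)
    oracle <- brute_edges(xy, d)
    expect_equal(nrow(g$edges), NROW(oracle))
    if (NROW(oracle)) {
      expect_equal(unname(g$edges[order(g$edges[, 1], g$edges[, 2]), ]),
                   unname(oracle), ignore_attr = TRUE)
    }
    expect_gte(nrow(g$edges), prev)  # cumulative bands are monotone
    prev <- nrow(g$edges)
  }
})

test_that("join counts on a labelled triangle follow the sum-across-nests convention", {
  g <- distance_band_graph(rbind(c(0, 0), c(1, 0), c(0.5, 1)), d = 2)
  labs <- c("A", "A", "B")
  expect_equal(join_count(g, labs, "A", "A"), 2)
  expect_equal(join_count(g, labs, "A", "B"), 4)
  expect_equal(join_count(g, labs, "B", "B"), 0)
  expect_equal(join_count(g, rep("A", 3), "A"), 2 * nrow(g$edges))
  expect_error(join_count(g, labs, "C"), "unknown category")
})

test_that("join counts match the exhaustive edge-scan oracle and their sum is 2|E|", {
  set.seed(21)
  xy <- cbind(runif(25, 0, 20), runif(25, 0, 20))
  g <- distance_band_graph(xy, 8)
  labs <- sample(c("A", "B", "C"), 25, replace = TRUE)
  cats <- c("A", "B", "C")
  total <- 0
  for (a in cats) for (b in cats) {
    if (match(b, cats) < match(a, cats)) next
    J <- join_count(g, labs, a, b, categories = cats)
    expect_equal(J, brute_join(g$edges, labs, a, b))
    total <- total + J
  }
  # unordered within + between pairs, directed convention: totals 2|E|
  expect_equal(total, 2 * nrow(g$edges))
})

test_that("random-labelling p follows the (matches + 1)/(R + 1) conventions", {
  set.seed(4)
  xy <- cbind(runif(15, 0, 10), runif(15, 0, 10))
  g <- distance_band_graph(xy, 6)
  # constant labels: every replicate equals the observed value
  expect_warning(res <- random_labelling_test(g, rep("A", 15), "A", R = 99,
                                              seed = 1),
                 "degenerate")
  expect_equal(res$p, 1)
  expect_true(res$degenerate)
  expect_equal(res$null_sd, 0)

  # an observed count strictly above all replicates hits the 1/(R+1) floor:
  # a tight cluster of A's at one end, B's far away
  xy2 <- rbind(cbind(runif(12, 0, 1), runif(12, 0, 1)),
               cbind(runif(12, 50, 51), runif(12, 50, 51)))
  g2 <- distance_band_graph(xy2, 5)
  labs2 <- rep(c("A", "B"), each = 12)
  res2 <- random_labelling_test(g2, labs2, "A", hypothesis = "greater",
                                R = 999, seed = 2)
  expect_equal(res2$p, 0.001)
})

test_that("permutation p is invariant to node reordering and seeded", {
  set.seed(12)
  xy <- cbind(runif(20, 0, 15), runif(20, 0, 15))
  labs <- sample(c("I", "E"), 20, replace = TRUE)
  g <- distance_band_graph(xy, 7)
  r1 <- random_labelling_test(g, labs, "I", R = 1999, seed = 5)
  perm <- sample(20)
  g2 <- distance_band_graph(xy[perm, ], 7)
  r2 <- random_labelling_test(g2, labs[perm], "I", R = 1999, seed = 5)
  # the statistic is order-invariant exactly; the permutation stream is not,
  # so the p agrees up to Monte Carlo error
  expect_identical(r1$J_obs, r2$J_obs)
  mc_se <- sqrt(r1$p * (1 - r1$p) / 2000)
  expect_lt(abs(r1$p - r2$p), 4 * mc_se)
  expect_lt(abs(r1$null_mean - r2$null_mean), 4 * r1$null_sd / sqrt(2000))
  # identical call with the same seed reproduces p exactly
  r3 <- random_labelling_test(g, labs, "I", R = 1999, seed = 5)
  expect_identical(r1$p, r3$p)
})

test_that("Monte Carlo null matches exhaustive enumeration on small graphs", {
  xy <- rbind(c(0, 0), c(1, 0), c(2, 0), c(0, 1), c(1, 1), c(2, 1))
  g <- distance_band_graph(xy, 1.2)
  labs <- c("A", "A", "B", "B", "A", "B")
  # exhaustive null over all 720 label permutations
  perms <- all_perms(seq_along(labs))
  J_all <- apply(perms, 1, function(p) brute_join(g$edges, labs[p], "A", "A"))
  res <- random_labelling_test(g, labs, "A", R = 2000, seed = 9)
  mc_se <- sd(J_all) / sqrt(2000)
  expect_lt(abs(res$null_mean - mean(J_all)), 4 * mc_se)
  expect_lt(abs(res$null_sd - sd(J_all)), 0.2)
  # hypergeometric expectation: E[J_aa] = 2|E| n_a (n_a - 1) / (n (n - 1))
  n_a <- sum(labs == "A")
  expect_equal(mean(J_all), 2 * nrow(g$edges) * n_a * (n_a - 1) / (6 * 5))
})

test_that("profiles compose single-call results and flag empty categories", {
  p <- toy_pattern(n = 15, seed = 6)
  prof <- join_count_profile(p, "species", d_ladder = c(6, 12), R = 49, seed = 3)
  df <- as.data.frame(prof)
  expect_equal(nrow(df), 6)  # 3 pairs x 2 distances
  expect_setequal(unique(df$pair), c("ss", "oo", "so"))
  # single-call equivalence for one cell of the sweep
  g <- distance_band_graph(p, 6)
  labs <- ifelse(p$records$species == "scabrinodis", "s", "o")
  expect_equal(df$J_obs[df$pair == "ss" & df$d == 6],
               join_count(g, labs, "s", "s", categories = c("s", "o")))
  # J_obs non-decreasing in d for fixed labels
  for (pr in unique(df$pair)) {
    expect_true(all(diff(df$J_obs[df$pair == pr][order(df$d[df$pair == pr])]) >= 0))
  }
  # a pattern with no infested nests gives degenerate flagged rows, no error
  rec <- toy_records(n = 10, seed = 2)
  rec$larvae_teleius <- 0L
  rec$larvae_microdon <- 0L
  p0 <- marked_point_pattern(rec)
  prof0 <- join_count_profile(p0, "infestation", d_ladder = 8, R = 49, seed = 1)
  df0 <- as.data.frame(prof0)
  expect_true(all(df0$degenerate))
})

test_that("doubly infested nests follow the focal-first precedence or are excluded", {
  rec <- toy_records(n = 8, seed = 9)
  rec$larvae_teleius <- c(1L, 1L, 0L, 0L, 0L, 0L, 2L, 0L)
  rec$larvae_microdon <- c(1L, 0L, 2L, 1L, 0L, 0L, 0L, 0L)
  p <- marked_point_pattern(rec)
  keep_first <- myrmspat:::derive_labels(p, "focal_vs_other", "teleius",
                                         doubly_infested = "focal_first")
  expect_equal(sum(keep_first$keep), 5)           # all infested nests
  expect_equal(sum(keep_first$labels == "T"), 3)  # double counts as focal
  keep_excl <- myrmspat:::derive_labels(p, "focal_vs_other", "teleius",
                                        doubly_infested = "exclude")
  expect_equal(sum(keep_excl$keep), 4)            # the double infestation dropped
})
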