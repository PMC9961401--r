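# Thomas process generator and two-season synthetic survey.

test_that("zero dispersal collapses every offspring onto its parent", {
  w <- rectangle_window(0, 50, 0, 50)
  xy <- simulate_thomas(w, kappa = 0.01, mu = 5, sigma = 0, seed = 7)
  pid <- attr(xy, "parent")
  expect_gt(nrow(xy), 0)
  # offspring of a common parent coincide
  for (p in unique(pid)) {
    sub <- xy[pid == p, , drop = FALSE]
    expect_equal(max(dist(sub), 0), 0)
  }
})

test_that("expected offspring count is kappa * mu * area (Poisson thinning)", {
  w <- rectangle_window(0, 200, 0, 200)  # large window, negligible edge loss
  counts <- vapply(1:200, function(s) {
    nrow(simulate_thomas(w, kappa = 0.001, mu = 5, sigma = 1, seed = s))
  }, numeric(1))
  expected <- 0.001 * 5 * 200^2  # 200
  # MC standard error of the mean is about sqrt(var)/sqrt(200); var is
  # inflated by clustering (~ expected * (1 + mu)), so allow 4 SEs.
  se <- sqrt(expected * (1 + 5) / 200)
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("clustered defaults produce overdispersed quadrat counts", {
  w <- rectangle_window(0, 65, 0, 65)
  over <- vapply(1:200, function(s) {
    xy <- simulate_thomas(w, kappa = 0.002, mu = 8, sigma = 3, seed = 1000 + s)
    if (nrow(xy) < 5) return(NA_real_)
    vmr(quadrat_counts(xy, 8, window = w))
  }, numeric(1))
  expect_gte(mean(over > 1, na.rm = TRUE), 0.95)
})

test_that("site pairs are reproducible from the seed and differ across seeds", {
  cf <- synthetic_config(seed = 11)
  p1 <- simulate_site_pair(cf)
  p2 <- simulate_site_pair(cf)
  expect_identical(p1$autumn$records, p2$autumn$records)
  expect_identical(p1$spring$records, p2$spring$records)
  p3 <- simulate_site_pair(synthetic_config(seed = 12))
  expect_false(identical(p1$autumn$records, p3$autumn$records))
  # byte-identical written tables
  f1 <- tempfile(); f2 <- tempfile(); on.exit(unlink(c(f1, f2)))
  write_nest_table(p1$autumn, f1)
  write_nest_table(p2$autumn, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("spring infestation only persists in autumn-infested nests", {
  for (s in 1:20) {
    pair <- simulate_site_pair(synthetic_config(seed = s))
    autumn_inf <- pair$autumn$records$nest_id[is_infested(pair$autumn, "teleius")]
    spring_inf <- pair$spring$records$nest_id[is_infested(pair$spring, "teleius")]
    expect_true(all(spring_inf %in% autumn_inf))
  }
})

test_that("logistic boundaries behave: -Inf intercept kills spring, zero logits give 1/2", {
  cf <- synthetic_config(seed = 3,
    spring_logit = c(intercept = -1e6, size_medium = 0, size_large = 0,
                     species_other = 0, site_kosyn = 0, other_parasite = 0))
  pair <- simulate_site_pair(cf)
  expect_equal(sum(is_infested(pair$spring, "teleius")), 0)

  cf0 <- synthetic_config(seed = 4, kappa = 0.008,
    autumn_logit = c(intercept = 0, size_medium = 0, size_large = 0))
  rate <- mean(vapply(1:30, function(s) {
    cf0$seed <- s
    mean(is_infested(simulate_site_pair(cf0)$autumn, "teleius"))
  }, numeric(1)))
  expect_lt(abs(rate - 0.5), 0.05)
})

test_that("config validation rejects malformed mixtures and parameters", {
  expect_error(synthetic_config(kappa = -1), "positive")
  expect_error(synthetic_config(species_mix = c(a = 0.5, b = 0.2)), "summing to 1")
  expect_error(synthetic_config(size_probs = c(small = 0.5, medium = 0.5)),
               "small/medium/large|summing")
  expect_error(synthetic_config(dropout = 1.5), "\\[0, 1\\]")
})

test_that("refitting the generating autumn model recovers the size effects", {
  # moderate-n parameter recovery: sign recovery per replicate, mean within
  # Monte Carlo error of the truth across replicates
  cf <- synthetic_config(seed = 0, kappa = 0.0045)  # n around 150
  est <- t(vapply(1:60, function(s) {
    cf$seed <- s
    pair <- simulate_site_pair(cf)
    dat <- occurrence_data(pair$autumn)
    f <- suppressWarnings(fit_logistic(y ~ size, dat))
    f$beta[c("sizemedium", "sizelarge")]
  }, numeric(2)))
  expect_lt(abs(mean(est[, "sizemedium"]) - 1.01), 3 * sd(est[, 1]) / sqrt(60))
  expect_lt(abs(mean(est[, "sizelarge"]) - 1.73), 3 * sd(est[, 2]) / sqrt(60))
  expect_gt(mean(est[, "sizelarge"] > 0), 0.9)
})
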