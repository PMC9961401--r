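# Candidate occurrence models, AIC comparison/averaging, variograms.

test_that("the candidate set holds the 16 distinct published structures", {
  cand <- candidate_models()
  expect_length(cand, 16)
  labels <- vapply(cand, `[[`, character(1), "label")
  expect_false(anyDuplicated(labels) > 0)
  expect_true("Nest size" %in% labels)
  rhs <- vapply(cand, `[[`, character(1), "rhs")
  expect_false(anyDuplicated(rhs) > 0)
})

test_that("saturated 2x2 logit recovers the closed-form log odds ratio", {
  dat <- data.frame(y = c(rep(1, 5), rep(0, 5), rep(1, 8), rep(0, 2)),
                    g = factor(rep(c("a", "b"), each = 10)))
  f <- fit_logistic(y ~ g, dat)
  expect_equal(unname(f$beta["gb"]), log((8 / 2) / (5 / 5)), tolerance = 1e-8)
  expect_equal(unname(f$beta["(Intercept)"]), 0, tolerance = 1e-8)
  # balanced predictor with identical rates: slope 0
  dat2 <- data.frame(y = rep(c(1, 0, 1, 0), 5),
                     g = factor(rep(c("a", "a", "b", "b"), 5)))
  expect_equal(unname(fit_logistic(y ~ g, dat2)$beta["gb"]), 0, tolerance = 1e-8)
})

test_that("maximized log-likelihood matches a brute-force grid search", {
  set.seed(71)
  n <- 60
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.4 + 0.9 * x))
  f <- fit_logistic(y ~ x, data.frame(y = y, x = x))
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  grid <- expand.grid(b0 = seq(-3, 3, by = 0.002), b1 = seq(-3, 3, by = 0.05))
  ll <- mapply(loglik, grid$b0, grid$b1)
  expect_lte(max(ll), f$loglik + 1e-9)        # IRLS attains the maximum
  expect_lt(f$loglik - max(ll), 1e-3)         # and the grid gets close to it
  expect_equal(f$aic, -2 * f$loglik + 2 * f$k)
})

test_that("separation is flagged and rank deficiency names the aliased column", {
  dat <- data.frame(y = c(0, 0, 0, 1, 1, 1), x = c(1, 2, 3, 4, 5, 6))
  expect_warning(f <- fit_logistic(y ~ x, dat), "separation")
  expect_false(f$converged)
  expect_lte(max(abs(f$beta)), 15)
  dat2 <- data.frame(y = rbinom(20, 1, 0.5), a = rnorm(20))
  dat2$b <- dat2$a
  expect_error(suppressWarnings(fit_logistic(y ~ a + b, dat2)), "aliased.*b")
})

test_that("AIC ranking, selection and conditional averaging behave", {
  set.seed(55)
  pair <- simulate_site_pair(synthetic_config(seed = 55, kappa = 0.003))
  dat <- occurrence_data(pair$autumn)
  cmp <- compare_candidates(dat)
  expect_equal(cmp$table$delta[1], 0)
  expect_true(all(diff(cmp$table$aic) >= 0))
  expect_gte(sum(cmp$table$selected), 1)
  w <- cmp$table$weight[cmp$table$selected]
  expect_equal(sum(w), 1)
  for (f in cmp$fits) expect_equal(f$aic, -2 * f$loglik + 2 * f$k)
  # ranking invariant to candidate order
  cmp2 <- compare_candidates(dat, rev(candidate_models()))
  expect_equal(cmp2$table$label, cmp$table$label)
  expect_equal(cmp2$averaged$beta, cmp$averaged$beta)
})

test_that("identical specs tie and a lone best model dominates the average", {
  set.seed(17)
  dat <- data.frame(y = rbinom(80, 1, 0.4),
                    size = factor(sample(c("small", "medium", "large"), 80, TRUE),
                                  levels = c("small", "medium", "large")))
  twin <- list(list(label = "Nest size A", rhs = "size"),
               list(label = "Nest size B", rhs = "size"))
  cmp <- compare_candidates(dat, twin)
  expect_equal(cmp$table$aic[1], cmp$table$aic[2])
  expect_true(all(cmp$table$selected))
  single <- fit_logistic(y ~ size, dat)
  expect_equal(cmp$averaged$beta[cmp$averaged$term == "sizelarge"],
               unname(single$beta["sizelarge"]), tolerance = 1e-10)
  # singleton selected set: averaged betas equal the best model's
  set.seed(18)
  x <- rnorm(300)
  strong <- data.frame(y = rbinom(300, 1, plogis(2.5 * x)), size = x,
                       site = factor(sample(c("Krakow", "Kosyn"), 300, TRUE)))
  cands <- list(list(label = "slope", rhs = "size"),
                list(label = "null", rhs = "1"))
  cmp2 <- compare_candidates(strong, cands)
  if (sum(cmp2$table$selected) == 1) {
    best <- cmp2$fits[[1]]
    expect_equal(cmp2$averaged$beta[cmp2$averaged$term == "size"],
                 unname(best$beta["size"]), tolerance = 1e-10)
  }
})

test_that("null data select the simplest structures most of the time", {
  hits <- vapply(1:40, function(s) {
    set.seed(400 + s)
    dat <- data.frame(
      y = rbinom(120, 1, 0.4),
      species2 = factor(sample(c("scabrinodis", "other"), 120, TRUE),
                        levels = c("scabrinodis", "other")),
      size = factor(sample(c("small", "medium", "large"), 120, TRUE),
                    levels = c("small", "medium", "large")),
      site = factor(sample(c("Krakow", "Kosyn"), 120, TRUE),
                    levels = c("Krakow", "Kosyn")),
      other = factor(sample(c("absent", "present"), 120, TRUE),
                     levels = c("absent", "present")))
    cmp <- suppressWarnings(compare_candidates(dat))
    # a single-variable model (2 or fewer non-intercept terms) ranks best
    cmp$table$k[1] <= 3
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("variogram gamma matches a hand-enumerated pair sum", {
  coords <- rbind(c(0, 0), c(1, 0), c(2, 0))
  r <- c(1, 3, 2)
  v <- residual_variogram(r, coords, lag_width = 1.5, max_lag = 3)
  # lag (0, 1.5]: pairs (1,2) and (2,3): ((1-3)^2 + (3-2)^2) / (2 * 2) = 1.25
  expect_equal(v$variogram$gamma[1], 1.25)
  # lag (1.5, 3]: pair (1,3): (1-2)^2 / 2 = 0.5
  expect_equal(v$variogram$gamma[2], 0.5)
  expect_equal(v$variogram$n_pairs, c(2L, 1L))
  expect_true(all(v$variogram$flagged))
  # constant residuals: flat zero
  v0 <- residual_variogram(rep(2, 10), cbind(1:10, 0), lag_width = 2, max_lag = 10)
  expect_true(all(v0$variogram$gamma[v0$variogram$n_pairs > 0] == 0))
})

test_that("iid residuals give a flat variogram at the sample variance", {
  set.seed(77)
  devs <- replicate(100, {
    coords <- cbind(runif(40, 0, 30), runif(40, 0, 30))
    r <- rnorm(40)
    v <- residual_variogram(r, coords, lag_width = 10, max_lag = 30)$variogram
    ok <- v$n_pairs >= 10
    max(abs(v$gamma[ok] - var(r) * (39 / 40)))  # population variance sill
  })
  # white noise: lag-wise deviations from the sill stay modest on average
  expect_lt(mean(devs), 0.6)
  expect_lt(median(devs), 0.5)
})
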