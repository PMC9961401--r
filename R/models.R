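# Candidate logistic models for parasite occurrence in Myrmica nests,
# AIC ranking, delta-AIC < 2 model averaging, and residual variograms.
# Variables: species2 (scabrinodis vs other, reference scabrinodis),
# size (small/medium/large, reference small), site (reference Krakow),
# other (other-parasite presence, reference absent).

#' Candidate fixed-effect structures for parasite occurrence
#'
#' The 16 biologically motivated model structures compared in the
#' analysis, from the full interaction model (host species x other
#' parasites, plus site, plus nest size x other parasites) down to the
#' single-variable models. Interactions always carry their main effects.
#'
#' @return List of 16 specs, each a list with `label` (human-readable
#'   structure) and `rhs` (model formula right-hand side over `species2`,
#'   `size`, `site`, `other`).
#' @export
candidate_models <- function() {
  spec <- function(label, rhs) list(label = label, rhs = rhs)
  list(
    spec("Ant species x Other parasites + Site + Other parasites x Nest size",
         "species2 * other + site + other * size"),
    spec("Ant species x Other parasites + Site + Nest size",
         "species2 * other + site + size"),
    spec("Ant species + Site + Nest size x Other parasites",
         "species2 + site + size * other"),
    spec("Ant species + Other parasites + Nest size + Site",
         "species2 + other + size + site"),
    spec("Ant species x Other parasites + Nest size x Other parasites",
         "species2 * other + size * other"),
    spec("Ant species + Nest size x Other parasites",
         "species2 + size * other"),
    spec("Nest size + Site + Ant species", "size + site + species2"),
    spec("Nest size + Site", "size + site"),
    spec("Nest size + Ant species", "size + species2"),
    spec("Nest size + Site + Other parasites", "size + site + other"),
    spec("Ant species x Other parasites", "species2 * other"),
    spec("Nest size x Other parasites", "size * other"),
    spec("Nest size", "size"),
    spec("Ant species", "species2"),
    spec("Site", "site"),
    spec("Other parasites", "other")
  )
}

#' Build an occurrence model frame from nest patterns
#'
#' One row per nest with the binary focal-parasite response `y` and the
#' coded explanatory factors: `species2` (scabrinodis reference vs other),
#' `size` (small reference), `site` (Krakow reference when present),
#' `other` (presence of any non-focal parasite, absent reference).
#'
#' @param patterns A `mpp`, or a list of them (e.g. several sites of one
#'   season).
#' @param taxa Focal parasite taxon set (default teleius).
#' @return Data frame with columns `y`, `species2`, `size`, `site`,
#'   `other`, `x`, `y_coord`.
#' @export
occurrence_data <- function(patterns, taxa = "teleius") {
  if (inherits(patterns, "mpp")) patterns <- list(patterns)
  recs <- do.call(rbind, lapply(patterns, function(p) p$records))
  y <- as.integer(is_infested(recs, taxa))
  other <- is_infested(recs, setdiff(larvae_taxa(recs), taxa))
  sites <- unique(recs$site)
  site_levels <- c(intersect("Krakow", sites), setdiff(sites, "Krakow"))
  data.frame(y = y,
             species2 = factor(ifelse(recs$species == "scabrinodis",
                                      "scabrinodis", "other"),
                               levels = c("scabrinodis", "other")),
             size = factor(recs$size_class, levels = SIZE_LEVELS),
             site = factor(recs$site, levels = site_levels),
             other = factor(ifelse(other, "present", "absent"),
                            levels = c("absent", "present")),
             x = recs$x, y_coord = recs$y,
             stringsAsFactors = FALSE)
}

#' Fit one binomial-logit occurrence model
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares (convergence when the relative deviance change is below 1e-10,
#' at most 100 iterations), with Wald standard errors from the inverse
#' observed information. Complete separation is detected and flagged: the
#' fit is marked non-converged and diverging coefficients are capped at
#' +/- 15 on the logit scale. A rank-deficient design is an error naming
#' the aliased columns.
#'
#' @param formula Model formula (response on the left), or a spec from
#'   [candidate_models()] (then the response is `y`).
#' @param data Model frame, e.g. from [occurrence_data()].
#' @return Object of class `model_fit`: `label`, `formula`, `beta`, `se`,
#'   `p` (Wald), `loglik`, `k`, `aic` (`-2 loglik + 2 k`), `converged`,
#'   `separation`, and the underlying `glm`.
#' @export
fit_logistic <- function(formula, data) {
  label <- NULL
  if (is.list(formula) && !inherits(formula, "formula")) {
    label <- formula$label
    formula <- stats::as.formula(paste("y ~", formula$rhs))
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, family = stats::binomial(), data = data,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop("rank-deficient design; aliased column(s): ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  }
  se <- sqrt(diag(stats::vcov(fit)))
  converged <- fit$converged && !separation
  if (separation) {
    warning("possible complete separation; coefficients capped at |beta| = 15")
    beta <- pmin(pmax(beta, -15), 15)
  }
  ll <- as.numeric(stats::logLik(fit))
  k <- length(beta)
  structure(list(label = label %||% deparse(formula[[3]]), formula = formula,
                 beta = beta, se = se,
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 loglik = ll, k = k, aic = -2 * ll + 2 * k,
                 converged = converged, separation = separation, glm = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("logit fit [%s]: logLik = %.2f, k = %d, AIC = %.1f%s\n",
              x$label, x$loglik, x$k, x$aic,
              if (!x$converged) " (NOT converged)" else ""))
  print(data.frame(beta = round(x$beta, 3), se = round(x$se, 3),
                   p = signif(x$p, 3)))
  invisible(x)
}

#' Compare candidate models by AIC and average the supported set
#'
#' Fits every candidate, ranks by AIC and marks the supported set
#' (delta AIC < 2). Coefficients are combined by conditional (natural)
#' model averaging: Akaike weights `w_i` proportional to `exp(-delta_i/2)`
#' are renormalised, per term, over the supported models that contain the
#' term, and the averaged standard error combines within-model variance
#' and between-model spread,
#' `sqrt(sum_i w_i (se_i^2 + (beta_i - beta_bar)^2))`. A candidate whose
#' fit fails is flagged and excluded; the comparison proceeds.
#'
#' @param data Model frame from [occurrence_data()].
#' @param candidates List of specs (default [candidate_models()]).
#' @return Object of class `model_comparison`: `table` (label, k, AIC,
#'   delta, weight, selected, converged per candidate, AIC-ranked),
#'   `selected` labels, `averaged` (term, beta, se, z, p), `fits`,
#'   `failed`.
#' @export
compare_candidates <- function(data, candidates = candidate_models()) {
  fits <- list()
  failed <- character(0)
  for (cand in candidates) {
    f <- tryCatch(suppressWarnings(fit_logistic(cand, data)),
                  error = function(e) e)
    if (inherits(f, "error")) {
      failed <- c(failed, sprintf("%s: %s", cand$label, conditionMessage(f)))
    } else {
      fits[[length(fits) + 1L]] <- f
    }
  }
  if (!length(fits)) stop("no candidate model could be fitted")
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  ord <- order(aic)
  fits <- fits[ord]
  aic <- aic[ord]
  delta <- aic - aic[1L]
  selected <- delta < 2
  w <- exp(-delta / 2) * selected
  w <- w / sum(w)
  tab <- data.frame(label = vapply(fits, `[[`, character(1), "label"),
                    k = vapply(fits, `[[`, numeric(1), "k"),
                    aic = aic, delta = delta,
                    weight = ifelse(selected, w, NA_real_),
                    selected = selected,
                    converged = vapply(fits, `[[`, logical(1), "converged"),
                    stringsAsFactors = FALSE)
  sel_fits <- fits[selected]
  sel_w <- w[selected]
  terms <- unique(unlist(lapply(sel_fits, function(f) names(f$beta))))
  averaged <- do.call(rbind, lapply(terms, function(tm) {
    has <- vapply(sel_fits, function(f) tm %in% names(f$beta), logical(1))
    wi <- sel_w[has] / sum(sel_w[has])
    b <- vapply(sel_fits[has], function(f) f$beta[[tm]], numeric(1))
    s <- vapply(sel_fits[has], function(f) f$se[[tm]], numeric(1))
    bbar <- sum(wi * b)
    sbar <- sqrt(sum(wi * (s^2 + (b - bbar)^2)))
    data.frame(term = tm, beta = bbar, se = sbar, z = bbar / sbar,
               p = 2 * stats::pnorm(-abs(bbar / sbar)),
               n_models = sum(has), stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, selected = tab$label[selected],
                 averaged = averaged, fits = fits, failed = failed),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("candidate occurrence models (AIC-ranked):\n")
  tab <- x$table
  tab$aic <- round(tab$aic, 1); tab$delta <- round(tab$delta, 2)
  tab$weight <- round(tab$weight, 3)
  print(tab[, c("label", "k", "aic", "delta", "weight", "selected")],
        right = FALSE)
  cat("\nconditionally averaged coefficients (delta AIC < 2 set):\n")
  av <- x$averaged
  av$beta <- round(av$beta, 3); av$se <- round(av$se, 3); av$p <- signif(av$p, 3)
  print(av[, c("term", "beta", "se", "p", "n_models")], right = FALSE)
  if (length(x$failed)) cat("\nfailed fits:", paste(x$failed, collapse = "; "), "\n")
  invisible(x)
}

#' Empirical semivariogram of model residuals
#'
#' Pearson residuals of a fitted occurrence model, paired across nests and
#' binned by separation distance:
#' `gamma(h) = (1 / (2 |N(h)|)) * sum over pairs in N(h) of (r_i - r_j)^2`.
#' A flat variogram (sill at the residual variance across all lags)
#' indicates spatially independent residuals. Bins with fewer than 10
#' pairs are flagged as unreliable.
#'
#' @param fit A `model_fit` (its Pearson residuals are used) or a numeric
#'   residual vector.
#' @param coords Two-column coordinate matrix aligned with the residuals.
#' @param lag_width Bin width in metres (default 4).
#' @param max_lag Largest separation considered (default 32).
#' @return Object of class `variogram_est`: data frame with `lag_mid`,
#'   `gamma`, `n_pairs`, `flagged`.
#' @export
residual_variogram <- function(fit, coords, lag_width = 4, max_lag = 32) {
  r <- if (inherits(fit, "model_fit")) {
    stats::residuals(fit$glm, type = "pearson")
  } else {
    as.numeric(fit)
  }
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("need at least 2 points")
  stopifnot(nrow(coords) == length(r))
  D <- stats::dist(coords)
  dr2 <- stats::dist(r)^2
  breaks <- seq(0, max_lag, by = lag_width)
  bin <- cut(D, breaks = breaks, include.lowest = TRUE)
  keep <- !is.na(bin)
  gamma <- tapply(dr2[keep], bin[keep], function(v) mean(v) / 2)
  n_pairs <- tapply(rep(1, sum(keep)), bin[keep], sum)
  out <- data.frame(lag_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    gamma = as.numeric(gamma[levels(bin)]),
                    n_pairs = as.integer(ifelse(is.na(n_pairs[levels(bin)]), 0,
                                                n_pairs[levels(bin)])))
  out$flagged <- out$n_pairs < 10L
  structure(list(variogram = out, lag_width = lag_width, max_lag = max_lag),
            class = "variogram_est")
}

#' @export
print.variogram_est <- function(x, ...) {
  cat("empirical residual semivariogram:\n")
  print(transform(x$variogram, gamma = round(gamma, 3)))
  invisible(x)
}

#' @export
plot.variogram_est <- function(x, ...) {
  v <- x$variogram
  graphics::plot(v$lag_mid, v$gamma, type = "b", pch = ifelse(v$flagged, 1, 16),
                 xlab = "lag (m)", ylab = expression(gamma(h)), ...)
  invisible(x)
}
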