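## Phenotype-factor (group-mean) model and activity-score derivation.

jags_factor_model <- function(K, study_effect) {
  mu <- paste0(
    "    mu[i] <- g[ph[i]]",
    if (K > 0) " + inprod(R[i,], theta)",
    if (study_effect) " + u[study[i]]",
    "\n"
  )
  paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    mu,
    "    y[i] ~ dnorm(mu[i], 1 / (sigw2 / n[i] + sigb2))\n",
    "  }\n",
    "  for (p in 1:P) {\n",
    "    g[p] ~ dnorm(0, 1.0E-6)\n",
    "  }\n",
    jags_variance_block(FALSE),
    jags_theta_block(K),
    if (study_effect) paste0(
      "  for (s in 1:S) {\n",
      "    u[s] ~ dnorm(0, iu2)\n",
      "  }\n",
      jags_half_cauchy("iu2", "iau", 25),  # sigma_u ~ C+(0, 25)
      "  sigma_u <- 1 / sqrt(iu2)\n"
    ),
    "}\n"
  )
}

#' Estimate phenotype-group mean adjustments
#'
#' Fits the factorial preliminary model: mean percent dose adjustment per
#' metabolizer phenotype group (treatment-coded against the EM reference,
#' which is pinned at 0 and must already be excluded from the rows), plus
#' unshrunk pooling-confounder effects, a study-level random effect, and the
#' sample-size-weighted two-component residual variance. This is the model
#' from which activity scores are derived (see [derive_activity_scores()]).
#'
#' @param points A `sampling_points` data.frame; EM rows are dropped
#'   automatically. Non-substrate substances should normally be excluded
#'   first (see [non_substrate_substances()]).
#' @param confounders Character vector of 0/1 flag fields entered as
#'   unshrunk covariates (default `c("pool_rm17", "pool_im17")`).
#' @param study_effect Include a study-level Gaussian random effect with a
#'   half-Cauchy(0, 25) scale (default `TRUE`, as in the preliminary
#'   analyses; the main slope model omits it).
#' @param level Credibility-interval probability (default 0.90; use 0.95 to
#'   reproduce pooling-effect intervals quoted at that level).
#' @param chains,adapt,warmup,iter,seed MCMC settings.
#' @param rhat_max Reliability threshold on the convergence statistic.
#' @return An object of class `phenofit` with elements `groups` (per-level
#'   posterior summaries; levels with zero rows are absent, not zero),
#'   `pooling` (confounder-effect summaries), `variance`, `draws`, and
#'   `diagnostics`.
#' @export
fit_phenotype_factor <- function(points,
                                 confounders = c("pool_rm17", "pool_im17"),
                                 study_effect = TRUE, level = 0.9,
                                 chains = 3, adapt = 1000, warmup = 1000,
                                 iter = 2000, seed = 1, rhat_max = 1.01) {
  if (any(points$phenotype == "EM")) {
    points <- apply_exclusions(points, drop_em = TRUE)
  }
  if (nrow(points) == 0) stop("no sampling points", call. = FALSE)
  confounders <- varying_confounders(points, confounders)
  levels_present <- PHENOTYPES[PHENOTYPES %in% unique(points$phenotype)]
  ph <- match(points$phenotype, levels_present)
  study <- match(points$study_id, unique(points$study_id))

  K <- length(confounders)
  jdata <- list(y = points$adjustment, n = points$n, ph = ph,
                N = nrow(points), P = length(levels_present))
  if (K > 0) {
    jdata$R <- matrix(vapply(confounders, function(f) as.numeric(points[[f]]),
                             numeric(nrow(points))), nrow = nrow(points))
    jdata$K <- K
  }
  if (study_effect) {
    jdata$study <- study
    jdata$S <- max(study)
  }

  monitors <- c("g", if (K > 0) "theta", "sigma_w", "sigma_b",
                if (study_effect) c("sigma_u", "u"))
  samples <- run_jags(jags_factor_model(K, study_effect), jdata, monitors,
                      chains = chains, adapt = adapt, warmup = warmup,
                      iter = iter, seed = seed)
  summ <- summarize_draws(samples, level = level)
  draws <- as.matrix(samples)

  g_names <- grep("^g(\\[|$)", colnames(draws), value = TRUE)
  g_draws <- draws[, g_names, drop = FALSE]
  colnames(g_draws) <- levels_present
  groups <- indexed_summary(summ, "g", levels_present)

  pooling <- if (K > 0) indexed_summary(summ, "theta", confounders)
  variance <- rbind(indexed_summary(summ, "sigma_w", "sigma_w"),
                    indexed_summary(summ, "sigma_b", "sigma_b"),
                    if (study_effect) indexed_summary(summ, "sigma_u",
                                                      "sigma_u"))

  core <- c(groups$term, confounders, "sigma_w", "sigma_b")
  core_idx <- summ$parameter %in% c(g_names, "sigma_w", "sigma_b",
                                    if (K > 0) grep("^theta",
                                                    summ$parameter,
                                                    value = TRUE))
  diagnostics <- list(
    rhat_max = max(summ$rhat[core_idx], na.rm = TRUE),
    ess_min = min(summ$ess[core_idx]),
    reliable = all(summ$rhat[core_idx] <= rhat_max, na.rm = TRUE),
    rhat_threshold = rhat_max
  )
  if (!diagnostics$reliable) {
    warning("phenotype-factor fit flagged non-reliable (max Rhat ",
            sprintf("%.3f", diagnostics$rhat_max), ")", call. = FALSE)
  }

  theta_draws <- if (K > 0) {
    th <- draws[, intersect(colnames(draws),
                            c("theta", paste0("theta[", seq_len(K), "]"))),
                drop = FALSE]
    colnames(th) <- confounders
    th
  }
  mu_hat <- colMeans(g_draws)[points$phenotype]
  if (K > 0) mu_hat <- mu_hat + drop(jdata$R %*% colMeans(theta_draws))
  if (study_effect) {
    u_names <- grep("^u(\\[|$)", colnames(draws), value = TRUE)
    u_mean <- colMeans(draws[, u_names, drop = FALSE])
    mu_hat <- mu_hat + u_mean[study]
  }

  structure(list(
    groups = groups, pooling = pooling, variance = variance,
    level = level, points = points,
    draws = list(g = g_draws, theta = theta_draws),
    residuals = unname(points$adjustment - mu_hat),
    diagnostics = diagnostics, seed = seed
  ), class = "phenofit")
}

#' @export
print.phenofit <- function(x, digits = 2, ...) {
  cat("Phenotype-group mean adjustments (percentage points vs EM, ",
      100 * x$level, "% CI):\n", sep = "")
  print(within(x$groups[, c("term", "median", "lower", "upper")], {
    median <- round(median, digits); lower <- round(lower, digits)
    upper <- round(upper, digits)
  }), row.names = FALSE)
  if (!is.null(x$pooling)) {
    cat("Pooling effects (percentage points):\n")
    print(within(x$pooling[, c("term", "median", "lower", "upper")], {
      median <- round(median, digits); lower <- round(lower, digits)
      upper <- round(upper, digits)
    }), row.names = FALSE)
  }
  invisible(x)
}

#' Plot adjustments against activity score with the group estimates
#'
#' Scatter of sampling-point adjustments at their phenotype's activity
#' score (point area scaled by group sample size), overlaid with the
#' posterior group means and intervals.
#'
#' @param x A `phenofit`.
#' @param scores An [activity_score_map()] locating the phenotype groups.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.phenofit <- function(x, scores = activity_score_map(), ...) {
  s <- unname(unclass(scores)[x$points$phenotype])
  graphics::plot(s, x$points$adjustment,
                 cex = 0.5 + sqrt(x$points$n) / 8, col = "grey50",
                 xlab = "activity score",
                 ylab = "dose adjustment (percentage points)", ...)
  gs <- unname(unclass(scores)[x$groups$term])
  graphics::points(gs, x$groups$median, pch = 16, col = "firebrick")
  graphics::segments(gs, x$groups$lower, gs, x$groups$upper,
                     col = "firebrick")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Derive EM-anchored, IM-scaled activity scores
#'
#' Rescales phenotype-group mean adjustments into activity scores: the EM
#' baseline is 0, and the scale is set by the IM group (one inactive allele,
#' score -1), i.e. each group's raw score is its adjustment divided by the
#' absolute IM adjustment, sign preserved (computed per posterior draw, so
#' the IM score is exactly -1 with a degenerate interval). The score of one
#' *17 allele is the average of the per-allele estimates in the RM group
#' (one *17) and the UM group (two *17, halved). The final working map
#' rounds to `digits` decimals and sets UM = 2 x RM exactly.
#'
#' @param fit A [fit_phenotype_factor()] result, or a named numeric vector
#'   of group median adjustments (e.g. `c(IM = -25, PM = -49, ...)`).
#' @param digits Rounding of the final map (default 1).
#' @param tol IM adjustments smaller than this (percentage points) leave the
#'   scale undefined and raise an error.
#' @return An object of class `score_derivation`: `raw` (unrounded group
#'   scores with intervals where draws are available), `allelic_17` (the one
#'   *17-allele score), and `map` (the rounded [activity_score_map()] used
#'   downstream).
#' @export
derive_activity_scores <- function(fit, digits = 1, tol = 1e-6) {
  if (inherits(fit, "phenofit")) {
    med <- stats::setNames(fit$groups$median, fit$groups$term)
    g_draws <- fit$draws$g
    level <- fit$level
  } else {
    med <- fit
    g_draws <- NULL
    level <- 0.9
  }
  if (!"IM" %in% names(med)) {
    stop("IM group absent: the activity-score scale is set by IM",
         call. = FALSE)
  }
  if (abs(med[["IM"]]) < tol) {
    stop("IM adjustment within tolerance of zero: score scale undefined",
         call. = FALSE)
  }

  groups <- setdiff(names(med), "EM")
  if (!is.null(g_draws)) {
    score_draws <- sweep(g_draws[, groups, drop = FALSE], 1,
                         abs(g_draws[, "IM"]), "/")
    probs <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
    q <- t(apply(score_draws, 2, stats::quantile, probs = probs,
                 names = FALSE))
    raw <- data.frame(term = c("EM", groups),
                      median = c(0, q[, 2]),
                      lower = c(0, q[, 1]), upper = c(0, q[, 3]),
                      stringsAsFactors = FALSE)
  } else {
    raw <- data.frame(term = c("EM", groups),
                      median = c(0, unname(med[groups] / abs(med[["IM"]]))),
                      lower = NA_real_, upper = NA_real_,
                      stringsAsFactors = FALSE)
  }

  raw_score <- stats::setNames(raw$median, raw$term)
  per_allele <- c(if ("RM" %in% names(raw_score)) raw_score[["RM"]],
                  if ("UM" %in% names(raw_score)) raw_score[["UM"]] / 2)
  if (length(per_allele) == 0) {
    stop("neither RM nor UM present: cannot estimate the *17 allelic score",
         call. = FALSE)
  }
  if (!is.null(g_draws) && all(c("RM", "UM") %in% colnames(score_draws))) {
    a17_draws <- (score_draws[, "RM"] + score_draws[, "UM"] / 2) / 2
    a17 <- stats::quantile(a17_draws, probs = probs, names = FALSE)
    allelic_17 <- data.frame(term = "allele_17", median = a17[2],
                             lower = a17[1], upper = a17[3])
  } else {
    allelic_17 <- data.frame(term = "allele_17", median = mean(per_allele),
                             lower = NA_real_, upper = NA_real_)
  }

  a17r <- round(allelic_17$median, digits)
  pm <- if ("PM" %in% names(raw_score)) {
    round(raw_score[["PM"]], digits)
  } else {
    warning("PM group absent; final map uses the conventional PM score -2",
            call. = FALSE)
    -2
  }
  map <- activity_score_map(pm = pm, im = -1, em = 0, rm = a17r,
                            um = 2 * a17r)

  structure(list(raw = raw, allelic_17 = allelic_17, map = map,
                 digits = digits),
            class = "score_derivation")
}

#' @export
print.score_derivation <- function(x, digits = 2, ...) {
  cat("Derived activity scores (EM = 0, IM = -1):\n")
  tab <- x$raw
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  cat("One *17 allele: ", round(x$allelic_17$median, digits),
      if (is.finite(x$allelic_17$lower)) {
        paste0(" [", round(x$allelic_17$lower, digits), ", ",
               round(x$allelic_17$upper, digits), "]")
      }, "\n", sep = "")
  cat("Final working map:\n")
  print(x$map)
  invisible(x)
}

## Flat-prior regression of adjustments on arbitrary columns Z (plus
## confounders and optional study effect) -- used by the diagnostics.
jags_flat_regression <- function(K, study_effect) {
  mu <- paste0(
    "    mu[i] <- inprod(Z[i,], b)",
    if (K > 0) " + inprod(R[i,], theta)",
    if (study_effect) " + u[study[i]]",
    "\n"
  )
  paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    mu,
    "    y[i] ~ dnorm(mu[i], 1 / (sigw2 / n[i] + sigb2))\n",
    "  }\n",
    "  for (j in 1:J) {\n",
    "    b[j] ~ dnorm(0, 1.0E-6)\n",
    "  }\n",
    jags_variance_block(FALSE),
    jags_theta_block(K),
    if (study_effect) paste0(
      "  for (s in 1:S) {\n",
      "    u[s] ~ dnorm(0, iu2)\n",
      "  }\n",
      jags_half_cauchy("iu2", "iau", 25),
      "  sigma_u <- 1 / sqrt(iu2)\n"
    ),
    "}\n"
  )
}

## A confounder column with no variation is unidentifiable (its coefficient
## would be sampled from the flat prior); drop it with a warning.
varying_confounders <- function(points, confounders) {
  if (length(confounders) == 0) return(character(0))
  keep <- vapply(confounders, function(f) {
    length(unique(points[[f]])) > 1
  }, logical(1))
  if (any(!keep)) {
    warning("confounder(s) constant in these data, dropped: ",
            paste(confounders[!keep], collapse = ", "), call. = FALSE)
  }
  confounders[keep]
}

flat_regression <- function(points, Z, confounders, study_effect, level,
                            chains, adapt, warmup, iter, seed) {
  confounders <- varying_confounders(points, confounders)
  K <- length(confounders)
  jdata <- list(y = points$adjustment, n = points$n,
                Z = Z, J = ncol(Z), N = nrow(points))
  if (K > 0) {
    jdata$R <- matrix(vapply(confounders, function(f) as.numeric(points[[f]]),
                             numeric(nrow(points))), nrow = nrow(points))
    jdata$K <- K
  }
  if (study_effect) {
    jdata$study <- match(points$study_id, unique(points$study_id))
    jdata$S <- max(jdata$study)
  }
  samples <- run_jags(jags_flat_regression(K, study_effect), jdata,
                      c("b", if (K > 0) "theta", "sigma_w", "sigma_b"),
                      chains = chains, adapt = adapt, warmup = warmup,
                      iter = iter, seed = seed)
  summarize_draws(samples, level = level)
}

#' Check linearity of the activity-score effect
#'
#' Two diagnostic fits against deviations from a single linear
#' activity-score effect: (a) quadratic and cubic polynomial terms added to
#' the linear predictor, and (b) a separate additional slope for the
#' *17-carrying phenotypes (RM/UM) relative to the *null-carrying ones
#' (PM/IM). All terms carry flat priors; a term whose credibility interval
#' excludes zero signals a deviation from linearity.
#'
#' @param points A `sampling_points` data.frame (EM rows dropped
#'   automatically).
#' @param scores An [activity_score_map()].
#' @param confounders,study_effect,level,chains,adapt,warmup,iter,seed As in
#'   [fit_phenotype_factor()].
#' @return A data.frame of class `linearity_diag` with one row per
#'   diagnostic term (`linear`, `quadratic`, `cubic`, `slope_17_extra`),
#'   its posterior median, interval, and an `excludes_zero` indicator.
#'   Polynomial terms are reported absent when fewer than 3 (quadratic) or
#'   4 (cubic) distinct score values are present.
#' @export
check_linearity <- function(points, scores = activity_score_map(),
                            confounders = "pool_rm17", study_effect = TRUE,
                            level = 0.9, chains = 3, adapt = 1000,
                            warmup = 1000, iter = 2000, seed = 1) {
  if (any(points$phenotype == "EM")) {
    points <- apply_exclusions(points, drop_em = TRUE)
  }
  s <- unname(unclass(scores)[points$phenotype])
  ndistinct <- length(unique(s))
  degree <- min(3, ndistinct - 1)

  out <- NULL
  if (degree >= 1) {
    if (degree < 3) {
      warning("fewer than ", degree + 2, " distinct activity-score values: ",
              "higher polynomial terms unidentifiable, reported as absent",
              call. = FALSE)
    }
    Z <- vapply(seq_len(degree), function(p) s^p, numeric(length(s)))
    colnames(Z) <- c("linear", "quadratic", "cubic")[seq_len(degree)]
    summ <- flat_regression(points, Z, confounders, study_effect, level,
                            chains, adapt, warmup, iter, seed)
    out <- indexed_summary(summ, "b", colnames(Z))
  }

  is17 <- as.numeric(points$phenotype %in% c("RM", "UM"))
  if (length(unique(is17)) > 1) {
    Z2 <- cbind(linear = s, slope_17_extra = s * is17)
    summ2 <- flat_regression(points, Z2, confounders, study_effect, level,
                             chains, adapt, warmup, iter, seed + 1)
    out <- rbind(out, indexed_summary(summ2, "b",
                                      colnames(Z2))[2, , drop = FALSE])
  }
  if (is.null(out)) stop("no linearity diagnostics identifiable", call. = FALSE)
  out$excludes_zero <- out$lower > 0 | out$upper < 0
  class(out) <- c("linearity_diag", "data.frame")
  out
}

sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

#' Compare raw and log scales for the adjustment data
#'
#' Fits the phenotype-factor model on the raw percent-adjustment scale and
#' on the log scale (100 * log(adjusted dose / 100), which keeps units
#' comparable to percentage points), and compares the symmetry of the
#' posterior-mean residuals. Rows whose adjusted dose (100 + adjustment) is
#' not positive are excluded from the log branch with a warning. The verdict
#' keeps the raw scale unless its residuals are clearly asymmetric
#' (|skewness| above `skew_threshold`) and the log scale improves on it.
#'
#' @inheritParams fit_phenotype_factor
#' @param skew_threshold Absolute residual skewness regarded as asymmetric
#'   (default 0.5).
#' @return A list of class `transform_check`: per-scale residual skewness,
#'   group-median tables, and `verdict` (`"raw"` or `"log"`).
#' @export
check_log_transform <- function(points,
                                confounders = c("pool_rm17", "pool_im17"),
                                study_effect = TRUE, skew_threshold = 0.5,
                                level = 0.9, chains = 3, adapt = 1000,
                                warmup = 1000, iter = 2000, seed = 1) {
  if (any(points$phenotype == "EM")) {
    points <- apply_exclusions(points, drop_em = TRUE)
  }
  fit_raw <- fit_phenotype_factor(points, confounders = confounders,
                                  study_effect = study_effect, level = level,
                                  chains = chains, adapt = adapt,
                                  warmup = warmup, iter = iter, seed = seed)

  pos <- 100 + points$adjustment > 0
  if (any(!pos)) {
    warning(sum(!pos), " row(s) with non-positive adjusted dose excluded ",
            "from the log branch", call. = FALSE)
  }
  plog <- points[pos, , drop = FALSE]
  plog$adjustment <- 100 * log((100 + plog$adjustment) / 100)
  fit_log <- fit_phenotype_factor(plog, confounders = confounders,
                                  study_effect = study_effect, level = level,
                                  chains = chains, adapt = adapt,
                                  warmup = warmup, iter = iter,
                                  seed = seed + 1)

  skew_raw <- sample_skewness(fit_raw$residuals)
  skew_log <- sample_skewness(fit_log$residuals)
  verdict <- if (abs(skew_raw) <= skew_threshold) {
    "raw"
  } else if (abs(skew_log) < abs(skew_raw)) {
    "log"
  } else {
    "raw"
  }
  structure(list(skew_raw = skew_raw, skew_log = skew_log,
                 groups_raw = fit_raw$groups, groups_log = fit_log$groups,
                 skew_threshold = skew_threshold, verdict = verdict),
            class = "transform_check")
}

#' @export
print.transform_check <- function(x, ...) {
  cat("Residual skewness: raw ", round(x$skew_raw, 3), ", log ",
      round(x$skew_log, 3), " (threshold ", x$skew_threshold, ")\n",
      sep = "")
  cat("Verdict: keep the ", x$verdict, " scale\n", sep = "")
  invisible(x)
}
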