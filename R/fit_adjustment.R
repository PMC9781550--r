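#' Fit the activity-score adjustment model
#'
#' Fits the no-intercept linear model of percent dose adjustments,
#' `y = X beta + R theta + e`, where each column of `X` carries the CYP2C19
#' activity scores for one substance (so `beta` is the per-substance slope of
#' adjustment on activity score, in percentage points per activity-score
#' unit), `R` holds study-design confounders whose coefficients `theta` are
#' always estimated without shrinkage, and the residual of sampling point `i`
#' has the two-component variance `sigma_w^2 / n_i + sigma_b^2` weighting
#' points by their group sample size (see [sampling_point_variance()]).
#'
#' Four prior regimes for the slopes are available:
#' \describe{
#'   \item{`"fixed"`}{independent effectively-flat normals (scale 1000
#'     percentage points); no pooling across substances.}
#'   \item{`"gaussian"`}{`beta_j ~ N(0, tau^2)` with `tau ~ C+(0, 1)` — the
#'     meta-analytic Gaussian random effect.}
#'   \item{`"horseshoe"`}{`beta_j ~ N(0, tau^2 lambda_j^2)`,
#'     `lambda_j ~ C+(0, 1)`, `tau ~ C+(0, 0.1)` — global-local shrinkage
#'     approximating a two-population (near-zero versus free) coefficient
#'     model.}
#'   \item{`"reg_horseshoe"`}{the regularized horseshoe: the local variance is
#'     capped by a slab of scale `c ~ half-t(df = 8, scale = 2.5)` via
#'     [regularized_xi_sq()], preventing extreme slopes from tiny studies.}
#' }
#'
#' Sampling is by Gibbs (JAGS), with half-Cauchy/half-t hyperpriors expressed
#' as inverse-gamma scale mixtures for conjugate updates. Variance scales
#' `sigma_w`, `sigma_b` carry informative log-normal(4, 0.25) priors keeping
#' both components away from zero.
#'
#' @param data A `sampling_points` data.frame (EM rows are dropped
#'   automatically) or a prebuilt [build_design()] object.
#' @param prior One of `"reg_horseshoe"`, `"horseshoe"`, `"gaussian"`,
#'   `"fixed"`.
#' @param scores,confounders Passed to [build_design()] when `data` is a
#'   sampling-point table.
#' @param tau_scale Half-Cauchy scale of the global shrinkage parameter;
#'   default 1 for `"gaussian"`, 0.1 for the horseshoe regimes.
#' @param c_scale,c_df Slab scale and degrees of freedom of the regularized
#'   horseshoe (defaults 2.5 and 8).
#' @param level Central credibility-interval probability (default 0.90).
#' @param fix_variance Optional `c(sigma_w =, sigma_b =)` to fix the residual
#'   scales instead of estimating them (used for closed-form cross-checks).
#' @param chains,adapt,warmup,iter,thin MCMC settings.
#' @param seed Integer seed; chain RNG seeds are derived deterministically.
#' @param rhat_max Convergence-statistic threshold above which the fit is
#'   flagged non-reliable (default 1.01, applied to slopes, confounder
#'   effects and variance scales).
#' @return An object of class `adjfit`; see [summary.adjfit()],
#'   [coef.adjfit()], [predict.adjfit()], [plot.adjfit()].
#' @export
fit_adjustment <- function(data,
                           prior = c("reg_horseshoe", "horseshoe",
                                     "gaussian", "fixed"),
                           scores = activity_score_map(),
                           confounders = "pool_rm17",
                           tau_scale = NULL, c_scale = 2.5, c_df = 8,
                           level = 0.9, fix_variance = NULL,
                           chains = 3, adapt = 1000, warmup = 1000,
                           iter = 2000, thin = 1, seed = 1,
                           rhat_max = 1.01) {
  prior <- match.arg(prior)
  if (inherits(data, "adj_design")) {
    design <- data
  } else {
    pts <- data
    if (any(pts$phenotype == "EM")) {
      pts <- apply_exclusions(pts, drop_em = TRUE)
    }
    design <- build_design(pts, scores = scores, confounders = confounders)
  }
  if (any(colSums(design$X != 0) == 0)) {
    stop("design has an all-zero substance column", call. = FALSE)
  }
  if (is.null(tau_scale)) {
    tau_scale <- if (prior == "gaussian") 1 else 0.1
  }
  stopifnot(tau_scale > 0, c_scale > 0, c_df >= 1, level > 0, level < 1)

  D <- ncol(design$X)
  K <- ncol(design$R)
  jdata <- list(y = design$y, X = design$X, n = design$n,
                N = length(design$y), D = D)
  if (K > 0) {
    jdata$R <- design$R
    jdata$K <- K
  }
  fixed_variance <- !is.null(fix_variance)
  if (fixed_variance) {
    stopifnot(all(c("sigma_w", "sigma_b") %in% names(fix_variance)))
    jdata$sigw2 <- unname(fix_variance[["sigma_w"]])^2
    jdata$sigb2 <- unname(fix_variance[["sigma_b"]])^2
  }

  monitors <- c("beta", if (K > 0) "theta",
                if (!fixed_variance) c("sigma_w", "sigma_b"),
                if (prior != "fixed") "tau",
                if (prior %in% c("horseshoe", "reg_horseshoe")) "lam2",
                if (prior == "reg_horseshoe") "c")
  model_string <- jags_adjustment_model(prior, K, tau_scale, c_scale, c_df,
                                        fixed_variance)
  ## start the global scale overdispersed across chains: a Gibbs chain that
  ## starts in the tau ~ 0 corner of the funnel can take very long to leave
  ## it, and chains started apart expose that through the convergence
  ## statistic instead of hiding it
  tau0 <- c(30, 5, 100, 15, 60)
  extra_inits <- if (prior != "fixed") {
    function(ch) {
      t0 <- tau0[(ch - 1) %% length(tau0) + 1]
      ini <- list(itau2 = 1 / t0^2, iat = 1)
      if (prior %in% c("horseshoe", "reg_horseshoe")) {
        ini$ilam2 <- rep(1, D)
        ini$ialam <- rep(1, D)
      }
      ini
    }
  }
  samples <- run_jags(model_string, jdata, monitors, chains = chains,
                      adapt = adapt, warmup = warmup, iter = iter,
                      thin = thin, seed = seed, extra_inits = extra_inits)
  summ <- summarize_draws(samples, level = level)
  draws <- as.matrix(samples)

  slope_names <- if (D == 1) "beta" else paste0("beta[", seq_len(D), "]")
  beta_draws <- draws[, slope_names, drop = FALSE]
  colnames(beta_draws) <- design$substances
  slopes <- indexed_summary(summ, "beta", design$substances)

  theta <- if (K > 0) indexed_summary(summ, "theta", colnames(design$R))
  variance <- if (!fixed_variance) {
    indexed_summary(summ, "sigma_w", "sigma_w") |>
      rbind(indexed_summary(summ, "sigma_b", "sigma_b"))
  }
  shrinkage <- if (prior != "fixed") {
    rows <- indexed_summary(summ, "tau", "tau")
    if (prior == "reg_horseshoe") {
      rows <- rbind(rows, indexed_summary(summ, "c", "c"))
    }
    if (prior %in% c("horseshoe", "reg_horseshoe")) {
      lam <- indexed_summary(summ, "lam2",
                             paste0("lam2[", design$substances, "]"))
      rows <- rbind(rows, lam)
    }
    rows
  }

  core <- c(slope_names,
            if (K > 0) paste0("theta", if (K == 1) "" else
                              paste0("[", seq_len(K), "]")),
            if (!fixed_variance) c("sigma_w", "sigma_b"))
  core <- intersect(core, summ$parameter)
  core_rhat <- summ$rhat[summ$parameter %in% core]
  diagnostics <- list(
    rhat_max = max(core_rhat, na.rm = TRUE),
    ess_min = min(summ$ess[summ$parameter %in% core]),
    reliable = all(core_rhat <= rhat_max, na.rm = TRUE),
    rhat_threshold = rhat_max,
    chains = chains, iter = iter, warmup = warmup
  )
  if (!diagnostics$reliable) {
    warning("fit flagged non-reliable: max convergence statistic ",
            sprintf("%.3f", diagnostics$rhat_max), " > ", rhat_max,
            call. = FALSE)
  }

  structure(list(
    call = match.call(), prior = prior, level = level, design = design,
    tau_scale = tau_scale, c_scale = c_scale, c_df = c_df,
    slopes = slopes, theta = theta, variance = variance,
    shrinkage = shrinkage, summary = summ,
    draws = list(beta = beta_draws,
                 theta = if (K > 0) {
                   th <- draws[, intersect(colnames(draws),
                                           c("theta",
                                             paste0("theta[", seq_len(K), "]"))),
                               drop = FALSE]
                   colnames(th) <- colnames(design$R)
                   th
                 }),
    diagnostics = diagnostics,
    seed = seed
  ), class = "adjfit")
}

#' @export
print.adjfit <- function(x, digits = 2, ...) {
  cat("Dose-adjustment model (", x$prior, " prior), ",
      length(x$design$y), " sampling points, ",
      length(x$design$substances), " substances\n", sep = "")
  cat("Per-substance slopes (percentage points per activity-score unit,\n",
      100 * x$level, "% credibility intervals):\n", sep = "")
  tab <- x$slopes[, c("term", "median", "lower", "upper")]
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  if (!x$diagnostics$reliable) {
    cat("WARNING: fit flagged non-reliable (max Rhat ",
        sprintf("%.3f", x$diagnostics$rhat_max), ")\n", sep = "")
  }
  invisible(x)
}

#' Summary of a fitted adjustment model
#'
#' @param object An `adjfit` object.
#' @param ... Unused.
#' @return `object`, invisibly; prints slope, confounder, variance and
#'   shrinkage summaries with diagnostics.
#' @export
summary.adjfit <- function(object, ...) {
  print(object)
  if (!is.null(object$theta)) {
    cat("\nConfounder effects (percentage points, no shrinkage):\n")
    print(object$theta[, c("term", "median", "lower", "upper")],
          row.names = FALSE, digits = 3)
  }
  if (!is.null(object$variance)) {
    cat("\nResidual scales (percentage points):\n")
    print(object$variance[, c("term", "median", "lower", "upper")],
          row.names = FALSE, digits = 3)
  }
  if (!is.null(object$shrinkage)) {
    cat("\nShrinkage parameters:\n")
    print(utils::head(object$shrinkage[, c("term", "median", "lower", "upper")],
                      3), row.names = FALSE, digits = 3)
  }
  cat("\nDiagnostics: max Rhat ",
      sprintf("%.3f", object$diagnostics$rhat_max),
      ", min ESS ", round(object$diagnostics$ess_min),
      if (object$diagnostics$reliable) " (reliable)" else " (NON-RELIABLE)",
      "\n", sep = "")
  invisible(object)
}

#' @export
coef.adjfit <- function(object, ...) {
  stats::setNames(object$slopes$median, object$slopes$term)
}

#' @export
residuals.adjfit <- function(object, ...) {
  d <- object$design
  mu <- drop(d$X %*% colMeans(object$draws$beta))
  if (!is.null(object$draws$theta)) {
    mu <- mu + drop(d$R %*% colMeans(object$draws$theta))
  }
  d$y - mu
}

#' @export
fitted.adjfit <- function(object, ...) {
  object$design$y - stats::residuals(object)
}

#' Predict the adjusted dose for a phenotype or activity score
#'
#' Transforms the posterior slope draws of one substance into adjusted-dose
#' draws, `dose = 100 + beta * score` (% of label dose), and summarises them
#' at the fit's credibility level. Scores may be given directly, so doses can
#' be predicted for metabolic activity levels between the phenotype groups.
#' At score 0 (the EM reference) the prediction is exactly 100% with a
#' zero-width interval, by construction of the no-intercept model.
#'
#' @param object An `adjfit`.
#' @param substance Substance token (must have a slope in the fit).
#' @param phenotype Character vector of phenotype groups, resolved through
#'   `map`; ignored when `score` is given.
#' @param score Numeric activity score(s).
#' @param map [activity_score_map()] used to resolve phenotypes.
#' @param level Interval probability; defaults to the fit's level.
#' @param ... Unused.
#' @return A data.frame of class `adj_dose_pred` with columns `substance`,
#'   `phenotype`, `score`, `dose_pct`, `lower`, `upper`.
#' @export
predict.adjfit <- function(object, substance,
                           phenotype = c("PM", "IM", "RM", "UM"),
                           score = NULL, map = activity_score_map(),
                           level = object$level, ...) {
  if (!object$diagnostics$reliable) {
    warning("predicting from a fit flagged non-reliable (max Rhat ",
            sprintf("%.3f", object$diagnostics$rhat_max), ")",
            call. = FALSE)
  }
  substance <- normalize_substance(substance)
  if (!substance %in% colnames(object$draws$beta)) {
    stop("unknown substance '", substance, "'; fitted substances: ",
         paste(colnames(object$draws$beta), collapse = ", "), call. = FALSE)
  }
  if (is.null(score)) {
    phenotype <- match_enum(phenotype, PHENOTYPES, "phenotype")
    score <- unname(unclass(map)[phenotype])
  } else {
    phenotype <- rep(NA_character_, length(score))
  }
  b <- object$draws$beta[, substance]
  probs <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  out <- t(vapply(score, function(s) {
    stats::quantile(100 + b * s, probs = probs, names = FALSE)
  }, numeric(3)))
  structure(data.frame(
    substance = substance, phenotype = phenotype, score = score,
    dose_pct = out[, 2], lower = out[, 1], upper = out[, 3],
    stringsAsFactors = FALSE
  ), class = c("adj_dose_pred", "data.frame"))
}

#' @export
print.adj_dose_pred <- function(x, digits = 1, ...) {
  cat("Adjusted dose (% of label dose):\n")
  y <- as.data.frame(x)
  y[c("score", "dose_pct", "lower", "upper")] <-
    lapply(y[c("score", "dose_pct", "lower", "upper")], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Forest plot of per-substance slopes
#'
#' @param x An `adjfit`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.adjfit <- function(x, ...) {
  s <- x$slopes[order(x$slopes$median), ]
  k <- nrow(s)
  graphics::plot(s$median, seq_len(k), xlim = range(s$lower, s$upper, 0),
                 yaxt = "n", ylab = "", pch = 16,
                 xlab = "slope (percentage points per activity-score unit)",
                 main = paste0("Activity-score slopes (", x$prior, ")"), ...)
  graphics::segments(s$lower, seq_len(k), s$upper, seq_len(k))
  graphics::abline(v = 0, lty = 3)
  graphics::axis(2, at = seq_len(k), labels = s$term, las = 2, cex.axis = 0.7)
  invisible(x)
}
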