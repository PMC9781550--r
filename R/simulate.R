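#' Configuration for the synthetic sampling-point generator
#'
#' Describes the generative process the analysis assumes: per-substance
#' activity-score slopes that are exactly zero for substances without a
#' CYP2C19 pathway (sparsity), heterogeneous study counts, group sample
#' sizes drawn log-uniformly over a wide range (mimicking the mix of tiny
#' pharmacokinetic panels and large TDM cohorts), the two-component residual
#' variance, and study-design pooling flags with additive confounder
#' effects. The defaults reflect the structure of the CYP2C19 psychotropic
#' literature the model was designed for: a 50% rate of true pathways,
#' sample sizes 1-507, an RM-pooling bias of +38 percentage points, and a
#' true *17 allelic activity of 0.79 (so the *17 effect is weaker than the
#' *null effect).
#'
#' @param n_substances Number of substances.
#' @param prop_nonzero Probability a substance has a true CYP2C19 pathway.
#' @param slope_mean,slope_sd Normal distribution of nonzero slopes
#'   (percentage points per activity-score unit).
#' @param slopes Optional named vector of true slopes, overriding the random
#'   mixture (names become substance tokens).
#' @param sigma_w,sigma_b True residual scales (percentage points).
#' @param studies_per_substance Either a `c(min, max)` range or a vector of
#'   per-substance study counts (a length-2 vector with exactly 2 substances
#'   is read as a range).
#' @param n_range Group sample-size range, sampled log-uniformly.
#' @param score_map True metabolic activity per phenotype used to generate
#'   adjustments.
#' @param conf_probs Probabilities of the pooling flags.
#' @param conf_effects True additive confounder effects theta (percentage
#'   points) applied to flagged rows.
#' @param star17_prob Probability a study genotyped the *17 allele (and so
#'   can report RM/UM groups).
#' @param phenotype_probs Inclusion probability per phenotype group within a
#'   study (RM/UM apply only to *17-genotyping studies).
#' @param include_em Emit EM reference rows with adjustment 0 (default
#'   `TRUE`; they exercise the exclusion logic downstream).
#' @param quadratic Curvature injected into the true score-response
#'   (percentage points per squared score unit; default 0, a purely linear
#'   truth).
#' @param multiplicative If `TRUE`, effects act multiplicatively on the
#'   dose scale (log-normal), producing right-skewed raw residuals.
#' @param seed Integer seed making the dataset reproducible.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_substances = 18, prop_nonzero = 0.5,
                             slope_mean = 20, slope_sd = 10, slopes = NULL,
                             sigma_w = 55, sigma_b = 20,
                             studies_per_substance = c(1, 8),
                             n_range = c(1, 507),
                             score_map = activity_score_map(rm = 0.79),
                             conf_probs = c(pool_rm17 = 0.25,
                                            pool_im17 = 0.15,
                                            pool_em2 = 0.2,
                                            pool_em17 = 0.4),
                             conf_effects = c(pool_rm17 = 38,
                                              pool_im17 = 2,
                                              pool_em2 = 0,
                                              pool_em17 = 0),
                             star17_prob = 0.5,
                             phenotype_probs = c(PM = 0.75, IM = 0.9,
                                                 RM = 0.8, UM = 0.5),
                             include_em = TRUE, quadratic = 0,
                             multiplicative = FALSE, seed = 1L) {
  if (!is.null(slopes)) {
    if (is.null(names(slopes))) {
      names(slopes) <- sprintf("substance_%02d", seq_along(slopes))
    }
    n_substances <- length(slopes)
  }
  cfg <- list(n_substances = as.integer(n_substances),
              prop_nonzero = prop_nonzero, slope_mean = slope_mean,
              slope_sd = slope_sd, slopes = slopes, sigma_w = sigma_w,
              sigma_b = sigma_b,
              studies_per_substance = studies_per_substance,
              n_range = n_range, score_map = score_map,
              conf_probs = conf_probs, conf_effects = conf_effects,
              star17_prob = star17_prob, phenotype_probs = phenotype_probs,
              include_em = include_em, quadratic = quadratic,
              multiplicative = multiplicative, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_substances >= 1,
              prop_nonzero >= 0, prop_nonzero <= 1,
              sigma_w > 0, sigma_b > 0, slope_sd >= 0,
              all(n_range >= 1), n_range[2] >= n_range[1],
              star17_prob >= 0, star17_prob <= 1,
              all(conf_probs >= 0), all(conf_probs <= 1),
              all(phenotype_probs >= 0), all(phenotype_probs <= 1),
              all(names(conf_probs) %in% FLAG_FIELDS),
              inherits(score_map, "activity_score_map"))
    if (length(studies_per_substance) == 2) {
      stopifnot(studies_per_substance[1] >= 1,
                studies_per_substance[2] >= studies_per_substance[1])
    } else {
      stopifnot(length(studies_per_substance) == n_substances,
                all(studies_per_substance >= 1))
    }
  })
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic sampling-point dataset with ground truth
#'
#' Draws a dataset from the generative model the analysis assumes:
#' `y = slope * score + theta' r + e`, `e ~ N(0, sigma_w^2 / n + sigma_b^2)`,
#' with per-substance slopes exactly zero for non-pathway substances. The
#' result is bit-identical for identical configurations (the seed lives in
#' the config).
#'
#' @param cfg A [generator_config()].
#' @return A list with `points` (a validated `sampling_points` data.frame,
#'   including EM rows with adjustment 0 when configured) and `truth` (true
#'   slopes, confounder effects, variance scales and score map).
#' @export
simulate_sampling_points <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)

  if (!is.null(cfg$slopes)) {
    slopes <- cfg$slopes
  } else {
    nz <- stats::runif(cfg$n_substances) < cfg$prop_nonzero
    slopes <- ifelse(nz, stats::rnorm(cfg$n_substances, cfg$slope_mean,
                                      cfg$slope_sd), 0)
    names(slopes) <- sprintf("substance_%02d", seq_len(cfg$n_substances))
  }
  substances <- names(slopes)

  sps <- cfg$studies_per_substance
  n_studies <- if (length(sps) == cfg$n_substances && cfg$n_substances != 2) {
    sps
  } else {
    sample(seq(sps[1], sps[2]), cfg$n_substances, replace = TRUE)
  }

  sm <- unclass(cfg$score_map)
  cp <- function(f) if (f %in% names(cfg$conf_probs)) cfg$conf_probs[[f]] else 0
  ce <- function(f) if (f %in% names(cfg$conf_effects)) cfg$conf_effects[[f]] else 0
  rows <- list()
  sid <- 0L
  for (d in seq_along(substances)) {
    for (st in seq_len(n_studies[d])) {
      sid <- sid + 1L
      star17 <- stats::runif(1) < cfg$star17_prob
      id_method <- if (star17) "genotyping" else {
        if (stats::runif(1) < 0.4) "phenotyping" else "genotyping"
      }
      inc <- stats::runif(4) < cfg$phenotype_probs[c("PM", "IM", "RM", "UM")]
      groups <- c("PM", "IM")[inc[1:2]]
      if (star17) groups <- c(groups, c("RM", "UM")[inc[3:4]])
      if (length(groups) == 0) groups <- "IM"

      pool_rm17 <- star17 && ("RM" %in% groups || "UM" %in% groups) &&
        stats::runif(1) < cp("pool_rm17")
      if (pool_rm17) {
        # the pooled group is reported as RM; no separate UM row
        groups <- union(setdiff(groups, "UM"), "RM")
      }
      pool_im17 <- star17 && "IM" %in% groups &&
        stats::runif(1) < cp("pool_im17")
      pool_em17 <- !star17 && id_method == "genotyping" &&
        stats::runif(1) < cp("pool_em17")
      pool_em2 <- id_method == "phenotyping" &&
        stats::runif(1) < cp("pool_em2")

      pk_param <- sample(PK_PARAMS, 1, prob = c(0.25, 0.2, 0.45, 0.1))
      population <- if (stats::runif(1) < 0.4) "healthy" else "patients"
      dosing <- if (population == "healthy") {
        if (stats::runif(1) < 0.8) "SD" else "MD"
      } else {
        if (stats::runif(1) < 0.9) "MD" else "SD"
      }
      if (cfg$include_em) groups <- c(groups, "EM")

      for (g in groups) {
        n <- max(1L, round(exp(stats::runif(1, log(cfg$n_range[1]),
                                            log(cfg$n_range[2])))))
        flags <- c(
          pool_rm17 = as.integer(pool_rm17 && g == "RM"),
          pool_im17 = as.integer(pool_im17 && g == "IM"),
          pool_em2 = as.integer(pool_em2),
          pool_em17 = as.integer(pool_em17)
        )
        if (g == "EM") {
          y <- 0
        } else {
          mu <- slopes[[d]] * sm[[g]] + cfg$quadratic * sm[[g]]^2 +
            sum(vapply(FLAG_FIELDS, function(f) ce(f) * flags[[f]],
                       numeric(1)))
          e <- stats::rnorm(1, 0, sqrt(cfg$sigma_w^2 / n + cfg$sigma_b^2))
          y <- if (cfg$multiplicative) {
            100 * (exp((mu + e) / 100) - 1)
          } else {
            mu + e
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          study_id = sprintf("S%04d", sid), substance = substances[d],
          phenotype = g, adjustment = y, n = n,
          pool_rm17 = flags[["pool_rm17"]], pool_im17 = flags[["pool_im17"]],
          pool_em2 = flags[["pool_em2"]], pool_em17 = flags[["pool_em17"]],
          pk_param = pk_param, population = population, dosing = dosing,
          id_method = id_method, stringsAsFactors = FALSE
        )
      }
    }
  }
  points <- suppressWarnings(validate_sampling_points(do.call(rbind, rows)))
  truth <- structure(list(
    slopes = slopes,
    theta = cfg$conf_effects,
    sigma_w = cfg$sigma_w, sigma_b = cfg$sigma_b,
    score_map = cfg$score_map,
    quadratic = cfg$quadratic,
    config = cfg
  ), class = "synthetic_truth")
  list(points = points, truth = truth)
}

#' Synthetic stand-in for the CYP2C19 psychotropic study database
#'
#' A fully synthetic dataset emulating the structure of the published
#' CYP2C19 psychotropic pharmacokinetic literature: the 18 substances and
#' their per-substance study counts follow the packaged study-characteristics
#' table (see [study_characteristics()]), substances reported as
#' non-substrates have true slope exactly 0, the four SSRI-class substrates
#' carry the strongest slopes, sample sizes span 1-507, and RM-pooling
#' biases flagged rows upward by +38 percentage points. No value in it is
#' a measured datum; it exists so the full pipeline can be exercised and
#' its estimates compared against known truth.
#'
#' @param seed Integer seed.
#' @return As [simulate_sampling_points()]: a list with `points` and
#'   `truth`.
#' @export
simulate_example_dataset <- function(seed = 2022L) {
  slopes <- c(
    amitriptyline = 15, citalopram = 28, clomipramine = 15, clozapine = 10,
    diazepam = 20, doxepine = 18, escitalopram = 32, etizolam = 25,
    fluoxetine = 0, fluvoxamine = 0, imipramine = 15, maprotiline = 0,
    mianserin = 0, moclobemide = 12, sertraline = 25, trimipramine = 12,
    venlafaxine = 22, zotepine = 5
  )
  studies <- c(
    amitriptyline = 7, citalopram = 4, clomipramine = 3, clozapine = 3,
    diazepam = 1, doxepine = 1, escitalopram = 11, etizolam = 1,
    fluoxetine = 2, fluvoxamine = 1, imipramine = 4, maprotiline = 1,
    mianserin = 1, moclobemide = 1, sertraline = 4, trimipramine = 2,
    venlafaxine = 3, zotepine = 1
  )
  cfg <- generator_config(slopes = slopes,
                          studies_per_substance = unname(studies),
                          seed = seed)
  simulate_sampling_points(cfg)
}

#' Compare a fitted adjustment model against generator truth
#'
#' @param truth A `synthetic_truth` object from the generator.
#' @param fit An [fit_adjustment()] result sharing the substance index.
#' @return A list of class `recovery_report`: `per_substance` (true slope,
#'   posterior median, bias, absolute error, interval-coverage indicator)
#'   and `aggregate` (RMSE, coverage overall and split by zero/nonzero
#'   truth, sign-error rate among nonzero slopes, and sigma_w / sigma_b
#'   recovery when estimated).
#' @export
recovery_report <- function(truth, fit) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(fit, "adjfit"))
  est <- fit$slopes
  if (!all(est$term %in% names(truth$slopes))) {
    stop("fitted substances missing from truth: ",
         paste(setdiff(est$term, names(truth$slopes)), collapse = ", "),
         call. = FALSE)
  }
  true <- unname(truth$slopes[est$term])
  per <- data.frame(
    substance = est$term, true = true, median = est$median,
    lower = est$lower, upper = est$upper,
    bias = est$median - true, abs_error = abs(est$median - true),
    covered = est$lower <= true & true <= est$upper,
    stringsAsFactors = FALSE
  )
  nz <- per$true != 0
  agg <- list(
    rmse = sqrt(mean(per$bias^2)),
    coverage = mean(per$covered),
    coverage_nonzero = if (any(nz)) mean(per$covered[nz]) else NA_real_,
    coverage_zero = if (any(!nz)) mean(per$covered[!nz]) else NA_real_,
    sign_error_rate = if (any(nz)) {
      mean(sign(per$median[nz]) != sign(per$true[nz]))
    } else NA_real_
  )
  if (!is.null(fit$variance)) {
    v <- stats::setNames(fit$variance$median, fit$variance$term)
    agg$sigma_w_ratio <- unname(v["sigma_w"] / truth$sigma_w)
    agg$sigma_b_ratio <- unname(v["sigma_b"] / truth$sigma_b)
  }
  structure(list(per_substance = per, aggregate = agg),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  a <- x$aggregate
  cat("Slope recovery over ", nrow(x$per_substance), " substances:\n",
      "  RMSE ", round(a$rmse, 2),
      ", coverage ", round(100 * a$coverage, 1), "%",
      " (nonzero ", round(100 * a$coverage_nonzero, 1),
      "%, zero ", round(100 * a$coverage_zero, 1), "%)",
      ", sign errors ", round(100 * a$sign_error_rate, 1), "%\n", sep = "")
  if (!is.null(a$sigma_w_ratio)) {
    cat("  sigma_w est/true ", round(a$sigma_w_ratio, 2),
        ", sigma_b est/true ", round(a$sigma_b_ratio, 2), "\n", sep = "")
  }
  invisible(x)
}
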