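#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]: input data, exclusion
#' rules, activity-score source, prior regimes, confounders, interval level,
#' seed and MCMC settings.
#'
#' @param input A sampling-point CSV path, or a data.frame.
#' @param output_dir Directory for the output tables (created if missing).
#' @param drop_substances Substances excluded from all modelling (default
#'   the non-substrates, [non_substrate_substances()]).
#' @param score_map `"derived"` (estimate activity scores from the data via
#'   the phenotype-factor model, excluding RM-pooled rows for that step) or
#'   a fixed [activity_score_map()].
#' @param regimes Prior regimes to fit; at least one.
#' @param confounders Confounder set of the slope model (default
#'   `"pool_rm17"`).
#' @param screen Study properties to screen, or `NULL` to skip the
#'   screening stage.
#' @param level Credibility-interval probability.
#' @param seed Integer pipeline seed; all per-stage sampler seeds derive
#'   from it deterministically.
#' @param mcmc Named list of sampler settings (`chains`, `adapt`, `warmup`,
#'   `iter`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, output_dir = tempfile("pgxdose_run_"),
                            drop_substances = non_substrate_substances(),
                            score_map = "derived",
                            regimes = c("fixed", "gaussian", "horseshoe",
                                        "reg_horseshoe"),
                            confounders = "pool_rm17", screen = NULL,
                            level = 0.9, seed = 1L,
                            mcmc = list(chains = 3, adapt = 1000,
                                        warmup = 1000, iter = 2000)) {
  if (length(regimes) < 1) {
    stop("at least one prior regime must be named", call. = FALSE)
  }
  regimes <- match.arg(regimes, c("fixed", "gaussian", "horseshoe",
                                  "reg_horseshoe"), several.ok = TRUE)
  if (is.character(input) && !file.exists(input)) {
    stop("input file does not exist: ", input, call. = FALSE)
  }
  if (!(identical(score_map, "derived") ||
        inherits(score_map, "activity_score_map"))) {
    stop("score_map must be \"derived\" or an activity_score_map",
         call. = FALSE)
  }
  stopifnot(level > 0, level < 1)
  mcmc_defaults <- list(chains = 3, adapt = 1000, warmup = 1000, iter = 2000)
  mcmc <- utils::modifyList(mcmc_defaults, mcmc)
  structure(list(input = input, output_dir = output_dir,
                 drop_substances = drop_substances, score_map = score_map,
                 regimes = regimes, confounders = confounders,
                 screen = screen, level = level, seed = as.integer(seed),
                 mcmc = mcmc),
            class = "pipeline_config")
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  cfg$output_dir <- NULL  # where outputs land does not change what they are
  writeBin(serialize(unclass(cfg), NULL, version = 2), f)
  unname(tools::md5sum(f))
}

#' Run the full dose-adjustment pipeline
#'
#' Executes the analysis stages in order — load and validate, apply
#' exclusions, estimate activity scores (phenotype-factor model and
#' derivation, unless a fixed map is configured), screen study properties
#' (optional), fit the slope model under each configured prior regime, and
#' tabulate per-substance slopes and per-phenotype adjusted doses — and
#' writes machine-readable outputs to the configured directory:
#' `scores.csv`, `screening.csv`, `comparison.csv`, `adjusted_doses.csv`,
#' `baseline.csv`, `exclusion_log.json`, `diagnostics.json` and
#' `manifest.json` (config hash, seed, versions, per-stage row counts and
#' diagnostics). A failed stage aborts the stages after it with an error
#' naming the stage. Identical configurations reproduce identical tables.
#'
#' @param cfg A [pipeline_config()].
#' @return An object of class `pgx_pipeline`: the manifest plus the in-memory
#'   stage results (`scores`, `screening`, `comparison`, `doses`, `fits`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  mc <- cfg$mcmc
  manifest <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("pgxdose")),
                   r_version = R.version.string, stages = list())

  points <- stage("load", {
    if (is.character(cfg$input)) {
      suppressMessages(read_sampling_points(cfg$input))
    } else {
      validate_sampling_points(cfg$input)
    }
  })
  manifest$stages$load <- list(rows = nrow(points),
                               substances = length(unique(points$substance)))

  model_points <- stage("exclusions", {
    apply_exclusions(points, drop_em = TRUE,
                     drop_substances = cfg$drop_substances)
  })
  excl_log <- exclusion_log(model_points)
  manifest$stages$exclusions <- list(rows = nrow(model_points),
                                     removed = sum(excl_log$removed))

  scores_out <- NULL
  pooling_out <- NULL
  if (identical(cfg$score_map, "derived")) {
    deriv <- stage("activity_scores", {
      # pooling effects are estimated on all rows; the score scale is then
      # derived after excluding the RM-pooled studies to avoid their bias
      pool_fit <- fit_phenotype_factor(model_points, level = cfg$level,
                                       chains = mc$chains, adapt = mc$adapt,
                                       warmup = mc$warmup, iter = mc$iter,
                                       seed = cfg$seed + 7L)
      score_points <- apply_exclusions(model_points, drop_em = FALSE,
                                       drop_rm_pooled = TRUE)
      pf <- fit_phenotype_factor(score_points,
                                 confounders = "pool_im17",
                                 level = cfg$level,
                                 chains = mc$chains, adapt = mc$adapt,
                                 warmup = mc$warmup, iter = mc$iter,
                                 seed = cfg$seed + 11L)
      list(pool_fit = pool_fit, fit = pf,
           deriv = derive_activity_scores(pf))
    })
    map <- deriv$deriv$map
    scores_out <- rbind(deriv$deriv$raw,
                        deriv$deriv$allelic_17)
    pooling_out <- deriv$pool_fit$pooling
    manifest$stages$activity_scores <- list(
      map = as.list(unclass(map)),
      pooling = if (!is.null(pooling_out)) {
        stats::setNames(as.list(pooling_out$median), pooling_out$term)
      },
      reliable = deriv$fit$diagnostics$reliable,
      rhat_max = deriv$fit$diagnostics$rhat_max)
  } else {
    map <- cfg$score_map
    manifest$stages$activity_scores <- list(map = as.list(unclass(map)),
                                            source = "fixed")
  }
  if (!is.null(scores_out)) {
    utils::write.csv(scores_out, file.path(cfg$output_dir, "scores.csv"),
                     row.names = FALSE)
  }
  if (!is.null(pooling_out)) {
    utils::write.csv(pooling_out[, c("term", "median", "lower", "upper")],
                     file.path(cfg$output_dir, "pooling_effects.csv"),
                     row.names = FALSE)
  }

  screening <- NULL
  if (!is.null(cfg$screen)) {
    screening <- stage("screening", {
      screen_study_properties(model_points, scores = map,
                              properties = cfg$screen,
                              level = cfg$level, chains = mc$chains,
                              adapt = mc$adapt, warmup = mc$warmup,
                              iter = mc$iter, seed = cfg$seed + 23L)
    })
    utils::write.csv(as.data.frame(screening),
                     file.path(cfg$output_dir, "screening.csv"),
                     row.names = FALSE)
    manifest$stages$screening <- list(
      included = screening$property[screening$include])
  }

  fits <- list()
  comparison <- stage("fits", {
    if (length(cfg$regimes) >= 2) {
      cmp <- compare_regimes(model_points, priors = cfg$regimes,
                             baseline_points = points, scores = map,
                             confounders = cfg$confounders,
                             level = cfg$level, chains = mc$chains,
                             adapt = mc$adapt, warmup = mc$warmup,
                             iter = mc$iter, seed = cfg$seed + 37L)
      fits <- attr(cmp, "fits")
      cmp
    } else {
      fit <- fit_adjustment(model_points, prior = cfg$regimes,
                            scores = map, confounders = cfg$confounders,
                            level = cfg$level, chains = mc$chains,
                            adapt = mc$adapt, warmup = mc$warmup,
                            iter = mc$iter, seed = cfg$seed + 37L)
      fits <- stats::setNames(list(fit), cfg$regimes)
      tab <- fit$slopes[, c("term", "median", "lower", "upper")]
      names(tab)[1] <- "substance"
      tab$regime <- cfg$regimes
      tab$reliable <- fit$diagnostics$reliable
      tab
    }
  })
  utils::write.csv(as.data.frame(comparison),
                   file.path(cfg$output_dir, "comparison.csv"),
                   row.names = FALSE)
  manifest$stages$fits <- lapply(fits, function(f) {
    if (inherits(f, "error")) {
      list(error = conditionMessage(f))
    } else {
      list(reliable = f$diagnostics$reliable,
           rhat_max = f$diagnostics$rhat_max,
           ess_min = f$diagnostics$ess_min)
    }
  })

  doses <- stage("predictions", {
    ok <- names(fits)[!vapply(fits, inherits, logical(1), "error")]
    do.call(rbind, lapply(ok, function(rg) {
      f <- fits[[rg]]
      per_sub <- lapply(colnames(f$draws$beta), function(sub) {
        p <- stats::predict(f, substance = sub, map = map)
        p$regime <- rg
        p
      })
      do.call(rbind, per_sub)
    }))
  })
  utils::write.csv(as.data.frame(doses),
                   file.path(cfg$output_dir, "adjusted_doses.csv"),
                   row.names = FALSE)
  utils::write.csv(weighted_mean_baseline(points),
                   file.path(cfg$output_dir, "baseline.csv"),
                   row.names = FALSE)

  jsonlite::write_json(
    list(rules = excl_log),
    file.path(cfg$output_dir, "exclusion_log.json"), auto_unbox = TRUE)
  jsonlite::write_json(manifest$stages,
                       file.path(cfg$output_dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$created <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(list(manifest = manifest, scores = scores_out,
                 screening = screening, comparison = comparison,
                 doses = doses, fits = fits,
                 output_dir = cfg$output_dir),
            class = "pgx_pipeline")
}

#' @export
print.pgx_pipeline <- function(x, ...) {
  cat("pgxdose pipeline run (seed ", x$manifest$seed, ", hash ",
      substr(x$manifest$config_hash, 1, 8), ")\n", sep = "")
  cat("Outputs in ", x$output_dir, ":\n  ", sep = "")
  cat(paste(list.files(x$output_dir), collapse = ", "), "\n")
  invisible(x)
}
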