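#' Traditional weighted-means dose adjustments
#'
#' The "means model" used by existing pharmacogenetic dose recommendations:
#' for every (substance, phenotype) cell with data, the sample-size-weighted
#' mean adjustment `sum(n_i y_i) / sum(n_i)` over the studies in that cell.
#' Weights act only within a cell — no information is pooled across
#' phenotypes or substances, so cells without data are simply absent (the
#' means model cannot extrapolate to unobserved phenotype groups).
#'
#' @param points A `sampling_points` data.frame; EM rows are allowed and
#'   trivially yield 0.
#' @return A data.frame with one row per observed cell: `substance`,
#'   `phenotype`, `adjustment` (weighted mean, percentage points),
#'   `dose_pct` (100 + adjustment), `total_n`, `n_studies`.
#' @export
weighted_mean_baseline <- function(points) {
  stopifnot(is.data.frame(points))
  if (nrow(points) == 0) {
    return(data.frame(substance = character(0), phenotype = character(0),
                      adjustment = numeric(0), dose_pct = numeric(0),
                      total_n = integer(0), n_studies = integer(0)))
  }
  key <- interaction(points$substance, points$phenotype, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(points)), key), function(idx) {
    p <- points[idx, , drop = FALSE]
    wm <- sum(p$n * p$adjustment) / sum(p$n)
    data.frame(substance = p$substance[1], phenotype = p$phenotype[1],
               adjustment = wm, dose_pct = 100 + wm,
               total_n = sum(p$n), n_studies = length(idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$substance,
                   match(out$phenotype, PHENOTYPES)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit and compare the four prior regimes on identical data
#'
#' Refits the adjustment model under each requested prior regime with the
#' same design and the same seed stream, and collects per-substance slope
#' summaries side by side, optionally with the weighted-means baseline per
#' phenotype cell. A regime whose sampler fails is annotated and the
#' remaining regimes are still reported.
#'
#' @param data A `sampling_points` table or [build_design()] object.
#' @param priors Regimes to fit (default all four).
#' @param baseline_points Optional unfiltered sampling points from which the
#'   weighted-means baseline is computed (attached as attribute
#'   `"baseline"`).
#' @param ... Passed to [fit_adjustment()] (scores, confounders, MCMC
#'   settings, `seed`, ...).
#' @return A data.frame of class `regime_comparison`: `substance`, `regime`,
#'   `median`, `lower`, `upper`, `n_studies`, `total_n`, `reliable`. The
#'   individual fits are attached as attribute `"fits"`.
#' @export
compare_regimes <- function(data,
                            priors = c("fixed", "gaussian", "horseshoe",
                                       "reg_horseshoe"),
                            baseline_points = NULL, ...) {
  stopifnot(length(priors) >= 2)
  fits <- list()
  tabs <- list()
  for (pr in priors) {
    fit <- tryCatch(fit_adjustment(data, prior = pr, ...),
                    error = function(e) e)
    fits[[pr]] <- fit
    if (inherits(fit, "error")) {
      warning("regime '", pr, "' failed: ", conditionMessage(fit),
              call. = FALSE)
      next
    }
    rows <- fit$design$rows
    per_sub <- split(seq_len(nrow(rows)), rows$substance)
    tab <- fit$slopes[, c("term", "median", "lower", "upper")]
    names(tab)[1] <- "substance"
    tab$regime <- pr
    tab$n_studies <- vapply(per_sub[tab$substance], function(idx) {
      length(unique(rows$study_id[idx]))
    }, integer(1))
    tab$total_n <- vapply(per_sub[tab$substance], function(idx) {
      sum(rows$n[idx])
    }, numeric(1))
    tab$reliable <- fit$diagnostics$reliable
    tabs[[pr]] <- tab
  }
  if (length(tabs) == 0) stop("all regimes failed", call. = FALSE)
  out <- do.call(rbind, tabs)
  out <- out[, c("substance", "regime", "median", "lower", "upper",
                 "n_studies", "total_n", "reliable")]
  rownames(out) <- NULL
  if (!is.null(baseline_points)) {
    attr(out, "baseline") <- weighted_mean_baseline(baseline_points)
  }
  attr(out, "fits") <- fits
  class(out) <- c("regime_comparison", "data.frame")
  out
}

#' @export
print.regime_comparison <- function(x, digits = 1, ...) {
  cat("Per-substance activity-score slopes by prior regime ",
      "(posterior medians):\n", sep = "")
  wide <- stats::reshape(as.data.frame(x)[, c("substance", "regime", "median")],
                         idvar = "substance", timevar = "regime",
                         direction = "wide")
  names(wide) <- sub("^median\\.", "", names(wide))
  wide[-1] <- lapply(wide[-1], round, digits)
  print(wide, row.names = FALSE)
  invisible(x)
}
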