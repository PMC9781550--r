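## Screening of study properties that may bias the activity-score slope.

## Map a sampling-point field to a 0/1 contrast column. Enumerated design
## fields become the contrasts actually of interest in this literature:
## pk_param -> AUC/CL versus Css/MR, population -> healthy vs patients,
## dosing -> SD vs MD, id_method -> phenotyping vs genotyping.
property_column <- function(points, property) {
  switch(property,
    pool_rm17 = , pool_im17 = , pool_em2 = , pool_em17 =
      as.numeric(points[[property]]),
    pk_param = as.numeric(points$pk_param %in% c("AUC", "CL")),
    population = as.numeric(points$population == "healthy"),
    dosing = as.numeric(points$dosing == "SD"),
    id_method = as.numeric(points$id_method == "phenotyping"),
    stop("unknown study property '", property, "'; valid: ",
         paste(c(FLAG_FIELDS, "pk_param", "population", "dosing",
                 "id_method"), collapse = ", "), call. = FALSE)
  )
}

#' Screen study properties for effects on the activity-score slope
#'
#' For each named study property, fits a flat-prior model with an overall
#' activity-score slope plus a property-by-score interaction (the change in
#' slope, in percentage points per activity-score unit, for rows with the
#' property), together with the RM-pooling group-level confounder, the
#' study random effect, and the sample-size-weighted residual variance. A
#' property is recommended for inclusion in the final confounder set when
#' its interaction interval excludes zero; the RM-pooling flag is always
#' carried regardless, since its group-level bias is established upstream.
#'
#' @param points A `sampling_points` data.frame (EM rows dropped
#'   automatically).
#' @param scores An [activity_score_map()].
#' @param properties Character vector of properties to screen; any of
#'   `pool_em17`, `pool_em2`, `pool_im17`, `pk_param` (AUC/CL vs Css),
#'   `population`, `dosing`, `id_method`.
#' @param confounders Group-level confounders kept in every screen
#'   (default `"pool_rm17"`).
#' @param study_effect,level,chains,adapt,warmup,iter,seed MCMC settings.
#' @return A data.frame of class `property_screen`: one row per property
#'   with the interaction effect (`median`, `lower`, `upper`), an
#'   `excludes_zero` indicator and the `include` recommendation.
#' @export
screen_study_properties <- function(points, scores = activity_score_map(),
                                    properties = c("pool_em17", "pool_em2",
                                                   "pk_param", "population",
                                                   "dosing"),
                                    confounders = "pool_rm17",
                                    study_effect = TRUE, level = 0.9,
                                    chains = 3, adapt = 1000, warmup = 1000,
                                    iter = 2000, seed = 1) {
  if (any(points$phenotype == "EM")) {
    points <- apply_exclusions(points, drop_em = TRUE)
  }
  s <- unname(unclass(scores)[points$phenotype])
  out <- NULL
  for (k in seq_along(properties)) {
    prop <- properties[k]
    v <- property_column(points, prop)
    if (length(unique(v)) < 2) {
      warning("property '", prop, "' is constant in these data; skipped",
              call. = FALSE)
      next
    }
    Z <- cbind(slope = s, interaction = s * v)
    summ <- flat_regression(points, Z, confounders, study_effect, level,
                            chains, adapt, warmup, iter, seed + k)
    row <- indexed_summary(summ, "b", colnames(Z))[2, , drop = FALSE]
    row$term <- prop
    out <- rbind(out, row)
  }
  if (is.null(out)) stop("no screenable properties", call. = FALSE)
  names(out)[1] <- "property"
  out$excludes_zero <- out$lower > 0 | out$upper < 0
  out$include <- out$excludes_zero
  rownames(out) <- NULL
  class(out) <- c("property_screen", "data.frame")
  out
}

#' @export
print.property_screen <- function(x, digits = 2, ...) {
  cat("Study-property screening (slope interactions, percentage points\n",
      "per activity-score unit):\n", sep = "")
  tab <- as.data.frame(x)[, c("property", "median", "lower", "upper",
                              "include")]
  tab[2:4] <- lapply(tab[2:4], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
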