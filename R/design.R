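#' Phenotype activity-score map
#'
#' A mapping from metabolizer phenotype to numeric CYP2C19 activity score,
#' anchored at EM = 0 and scaled so IM = -1 (one inactive allele). The
#' default map is the rounded working map derived from the phenotype-factor
#' model: PM -2, IM -1, EM 0, RM 0.8, UM 1.6 (UM is always twice RM, two
#' *17 alleles versus one).
#'
#' @param pm,im,em,rm,um Scores per phenotype group. `em` must be 0 and the
#'   ordering PM < IM < EM < RM < UM must hold.
#' @return A named numeric vector of class `activity_score_map`.
#' @export
activity_score_map <- function(pm = -2, im = -1, em = 0, rm = 0.8, um = 2 * rm) {
  scores <- c(PM = pm, IM = im, EM = em, RM = rm, UM = um)
  if (scores[["EM"]] != 0) {
    stop("activity scores are EM-anchored: em must be 0", call. = FALSE)
  }
  if (!all(diff(scores[PHENOTYPES]) > 0)) {
    stop("activity scores must be ordered PM < IM < EM < RM < UM",
         call. = FALSE)
  }
  structure(scores, class = "activity_score_map")
}

#' @export
print.activity_score_map <- function(x, ...) {
  cat("CYP2C19 activity-score map (EM-anchored, IM = -1):\n")
  print(unclass(x))
  invisible(x)
}

## Confounder coding: a named character vector, names = sampling-point flag
## fields, values "flag" (0/1 column) or "interaction" (flag x activity score).
check_confounder_spec <- function(confounders) {
  if (is.null(confounders) || length(confounders) == 0) return(NULL)
  if (is.null(names(confounders)) || any(!nzchar(names(confounders)))) {
    # bare character vector means plain flag coding
    confounders <- stats::setNames(rep("flag", length(confounders)),
                                   confounders)
  }
  bad <- setdiff(names(confounders), FLAG_FIELDS)
  if (length(bad) > 0) {
    stop("unknown confounder field(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(FLAG_FIELDS, collapse = ", "), ")", call. = FALSE)
  }
  if (!all(confounders %in% c("flag", "interaction"))) {
    stop("confounder coding must be 'flag' or 'interaction'", call. = FALSE)
  }
  confounders
}

#' Build the model design matrices
#'
#' Turns a filtered sampling-point collection into the quantities of the
#' adjustment model `y = X beta + R theta + e`: `y` the vector of percent
#' adjustments, `X` the activity-score-by-substance predictor matrix (row i,
#' column d holds the activity score of row i's phenotype if column d is its
#' substance, else 0 — exactly one nonzero entry per row), `R` the confounder
#' matrix, and `n` the sample sizes entering the two-component residual
#' variance. The design has no intercept: the EM reference is pinned at zero
#' adjustment, and EM rows must have been removed beforehand.
#'
#' @param points A `sampling_points` data.frame with no EM rows.
#' @param scores An [activity_score_map()].
#' @param confounders Either a character vector of flag fields coded as 0/1
#'   columns (default `"pool_rm17"`), or a named vector mapping flag fields
#'   to a coding, `"flag"` or `"interaction"` (flag times activity score).
#'   `NULL` for no confounders.
#' @return An object of class `adj_design`: a list with `y`, `X`, `R`, `n`,
#'   `rows` (the source sampling points), `substances` (column order of `X`)
#'   and `confounders`.
#' @export
build_design <- function(points, scores = activity_score_map(),
                         confounders = "pool_rm17") {
  stopifnot(is.data.frame(points))
  if (any(points$phenotype == "EM")) {
    stop("EM rows must be removed before building the design ",
         "(see apply_exclusions)", call. = FALSE)
  }
  if (nrow(points) == 0) stop("no sampling points", call. = FALSE)
  missing_ph <- setdiff(unique(points$phenotype), names(scores))
  if (length(missing_ph) > 0) {
    stop("no activity score for phenotype(s): ",
         paste(missing_ph, collapse = ", "), call. = FALSE)
  }
  confounders <- check_confounder_spec(confounders)

  substances <- sort(unique(points$substance))
  N <- nrow(points)
  sc <- unname(unclass(scores)[points$phenotype])
  X <- matrix(0, N, length(substances),
              dimnames = list(NULL, substances))
  X[cbind(seq_len(N), match(points$substance, substances))] <- sc

  empty <- colSums(X != 0) == 0
  if (any(empty)) {
    warning("dropping substance column(s) with no nonzero entries: ",
            paste(substances[empty], collapse = ", "), call. = FALSE)
    X <- X[, !empty, drop = FALSE]
    substances <- substances[!empty]
  }

  if (is.null(confounders)) {
    R <- matrix(0, N, 0)
  } else {
    R <- sapply(names(confounders), function(f) {
      v <- as.numeric(points[[f]])
      if (confounders[[f]] == "interaction") v * sc else v
    })
    R <- matrix(R, nrow = N,
                dimnames = list(NULL, ifelse(confounders == "interaction",
                                             paste0(names(confounders), ":score"),
                                             names(confounders))))
    # an all-zero confounder column is completely unidentified
    dead <- colSums(R != 0) == 0
    if (any(dead)) {
      warning("dropping confounder column(s) with no nonzero entries: ",
              paste(colnames(R)[dead], collapse = ", "), call. = FALSE)
      R <- R[, !dead, drop = FALSE]
      confounders <- confounders[!dead]
    }
  }

  structure(list(
    y = points$adjustment,
    X = X,
    R = R,
    n = points$n,
    rows = points,
    substances = substances,
    confounders = confounders
  ), class = "adj_design")
}

#' @export
print.adj_design <- function(x, ...) {
  cat("Adjustment-model design: ", length(x$y), " sampling points, ",
      length(x$substances), " substances, ", ncol(x$R),
      " confounder column(s)\n", sep = "")
  invisible(x)
}
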