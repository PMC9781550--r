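#' @keywords internal
"_PACKAGE"

## Canonical column layout of a sampling-point table. One row = one study's
## reported percent dose adjustment for a (substance, phenotype) pair,
## relative to the EM reference (EM = 0; adjusted dose = 100 + adjustment).

PHENOTYPES <- c("PM", "IM", "EM", "RM", "UM")
PK_PARAMS <- c("AUC", "CL", "Css", "MR")
POPULATIONS <- c("healthy", "patients")
DOSINGS <- c("SD", "MD")
ID_METHODS <- c("phenotyping", "genotyping")
FLAG_FIELDS <- c("pool_rm17", "pool_im17", "pool_em2", "pool_em17")

SP_COLUMNS <- c(
  "study_id", "substance", "phenotype", "adjustment", "n",
  FLAG_FIELDS, "pk_param", "population", "dosing", "id_method"
)

#' Validate a sampling-point table
#'
#' Checks and normalises a long-format table of sampling points: one row per
#' (study x substance x phenotype group), holding the percent dose adjustment
#' relative to the EM phenotype, the group sample size, and study-design
#' flags. Enumerated fields are matched case-insensitively; substance tokens
#' are trimmed and case-folded ("Mianserine" and "mianserin " both become
#' "mianserin"); blank or missing design flags default to 0 with a warning
#' (older studies predate the *17 allele and simply lack the distinction).
#'
#' @param x A data.frame with (at least) the canonical columns: `study_id`,
#'   `substance`, `phenotype` (PM/IM/EM/RM/UM), `adjustment` (percentage
#'   points, EM = 0), `n` (group sample size, >= 1), the 0/1 design flags
#'   `pool_rm17`, `pool_im17`, `pool_em2`, `pool_em17`, and the design fields
#'   `pk_param` (AUC/CL/Css/MR), `population` (healthy/patients), `dosing`
#'   (SD/MD), `id_method` (phenotyping/genotyping).
#' @return A validated data.frame of class `sampling_points` with normalised
#'   columns in canonical order.
#' @export
validate_sampling_points <- function(x) {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SP_COLUMNS, names(x))
  if (length(missing_cols) > 0) {
    stop("sampling-point table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[SP_COLUMNS]

  x$study_id <- as.character(x$study_id)
  x$substance <- normalize_substance(x$substance)
  x$phenotype <- match_enum(x$phenotype, PHENOTYPES, "phenotype")
  x$pk_param <- match_enum(x$pk_param, PK_PARAMS, "pk_param")
  x$population <- match_enum(x$population, POPULATIONS, "population")
  x$dosing <- match_enum(x$dosing, DOSINGS, "dosing")
  x$id_method <- match_enum(x$id_method, ID_METHODS, "id_method")

  x$adjustment <- as.numeric(x$adjustment)
  if (any(!is.finite(x$adjustment))) {
    stop("non-finite adjustment in row(s): ",
         paste(which(!is.finite(x$adjustment)), collapse = ", "), call. = FALSE)
  }
  x$n <- as.numeric(x$n)
  bad_n <- !is.finite(x$n) | x$n < 1 | x$n != floor(x$n)
  if (any(bad_n)) {
    stop("sample size n must be a positive integer; offending row(s): ",
         paste(which(bad_n), collapse = ", "), call. = FALSE)
  }
  x$n <- as.integer(x$n)

  for (f in FLAG_FIELDS) {
    v <- x[[f]]
    blank <- is.na(v) | (is.character(v) & !nzchar(trimws(as.character(v))))
    if (any(blank)) {
      warning(sum(blank), " blank value(s) in flag '", f,
              "' defaulted to 0", call. = FALSE)
      v[blank] <- 0
    }
    v <- as.numeric(v)
    if (any(!v %in% c(0, 1))) {
      stop("flag '", f, "' must be 0/1; offending row(s): ",
           paste(which(!v %in% c(0, 1)), collapse = ", "), call. = FALSE)
    }
    x[[f]] <- as.integer(v)
  }

  rownames(x) <- NULL
  class(x) <- c("sampling_points", "data.frame")
  x
}

normalize_substance <- function(s) {
  s <- tolower(trimws(as.character(s)))
  # the literature uses both spellings; fold to one token
  s[s == "mianserine"] <- "mianserin"
  s[s == "doxepin"] <- "doxepine"
  s
}

match_enum <- function(v, levels, field) {
  v <- trimws(as.character(v))
  idx <- match(tolower(v), tolower(levels))
  if (any(is.na(idx))) {
    bad <- unique(v[is.na(idx)])
    stop("unknown ", field, " token(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(levels, collapse = "/"), ")",
         call. = FALSE)
  }
  levels[idx]
}

#' Read a sampling-point table from CSV
#'
#' Reads an RFC-4180 CSV with a header naming all canonical sampling-point
#' fields and validates it with [validate_sampling_points()]. An empty table
#' under a valid header is accepted with a warning.
#'
#' @param file Path to the CSV file.
#' @return A `sampling_points` data.frame.
#' @export
read_sampling_points <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (nrow(x) == 0) {
    warning("sampling-point table '", file, "' is empty", call. = FALSE)
    missing_cols <- setdiff(SP_COLUMNS, names(x))
    if (length(missing_cols) > 0) {
      stop("sampling-point table lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    x <- x[SP_COLUMNS]
    class(x) <- c("sampling_points", "data.frame")
    return(x)
  }
  out <- validate_sampling_points(x)
  message("read ", nrow(out), " sampling points across ",
          length(unique(out$substance)), " substances")
  out
}

#' Write a sampling-point table to CSV
#'
#' The canonical CSV round-trips: re-reading the file yields an identical
#' collection field-by-field.
#'
#' @param x A `sampling_points` data.frame.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_sampling_points <- function(x, file) {
  utils::write.csv(as.data.frame(x)[SP_COLUMNS], file, row.names = FALSE)
  invisible(file)
}

#' Apply study-exclusion rules
#'
#' Filters a sampling-point collection by the standard exclusion rules used
#' before modelling: dropping EM reference rows (they are not independent
#' data), dropping substances with no visible CYP2C19 pathway, and dropping
#' rows from studies that pooled *17/*17 carriers into the RM group. Row
#' order of survivors is preserved and the operation is idempotent.
#'
#' @param points A `sampling_points` data.frame.
#' @param drop_em Drop EM phenotype rows (default `TRUE`).
#' @param drop_substances Character vector of substances to drop entirely
#'   (e.g. the non-substrates `c("mianserin", "maprotiline", "fluoxetine",
#'   "fluvoxamine")`); an unknown substance yields a warning, not an error.
#' @param drop_rm_pooled Drop rows flagged `pool_rm17 = 1` (default `FALSE`).
#' @return The surviving `sampling_points` rows, with an exclusion log
#'   attached as attribute `"exclusion_log"` (a data.frame of rule and rows
#'   removed); retrieve it with [exclusion_log()].
#' @export
apply_exclusions <- function(points, drop_em = TRUE, drop_substances = NULL,
                             drop_rm_pooled = FALSE) {
  stopifnot(inherits(points, "sampling_points") || is.data.frame(points))
  log <- data.frame(rule = character(0), removed = integer(0),
                    stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(points))

  if (drop_em) {
    hit <- keep & points$phenotype == "EM"
    log <- rbind(log, data.frame(rule = "drop_em_rows", removed = sum(hit)))
    keep <- keep & !hit
  }
  if (!is.null(drop_substances)) {
    subs <- normalize_substance(drop_substances)
    unknown <- setdiff(subs, unique(points$substance))
    if (length(unknown) > 0) {
      warning("exclusion rule names unknown substance(s): ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    hit <- keep & points$substance %in% subs
    log <- rbind(log, data.frame(rule = "drop_substances", removed = sum(hit)))
    keep <- keep & !hit
  }
  if (drop_rm_pooled) {
    hit <- keep & points$pool_rm17 == 1
    log <- rbind(log, data.frame(rule = "drop_pool_rm17", removed = sum(hit)))
    keep <- keep & !hit
  }

  out <- points[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sampling_points", "data.frame")
  attr(out, "exclusion_log") <- log
  out
}

#' Retrieve the exclusion log attached by [apply_exclusions()]
#' @param x A filtered `sampling_points` object.
#' @return A data.frame with columns `rule` and `removed`.
#' @export
exclusion_log <- function(x) {
  lg <- attr(x, "exclusion_log")
  if (is.null(lg)) {
    lg <- data.frame(rule = character(0), removed = integer(0))
  }
  lg
}

#' Substances the source literature reports as lacking a CYP2C19 pathway
#'
#' The default exclusion set used when estimating activity scores: drugs
#' where no CYP2C19 effect is visible in vivo. `include_zotepine = TRUE`
#' extends the set with zotepine, which some summaries group with the
#' non-substrates.
#'
#' @param include_zotepine Also drop zotepine (default `FALSE`).
#' @return Character vector of substance tokens.
#' @export
non_substrate_substances <- function(include_zotepine = FALSE) {
  out <- c("mianserin", "maprotiline", "fluoxetine", "fluvoxamine")
  if (include_zotepine) out <- c(out, "zotepine")
  out
}
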