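#' Characteristics of the included CYP2C19 studies
#'
#' The packaged table of the 51 published pharmacokinetic studies on
#' psychotropic CYP2C19 substrates underlying the dose-adjustment analysis:
#' one row per study with the drug, the pharmacokinetic parameter reported
#' (AUC, CL or 1/CL, Css, metabolic ratio), the study population and dosing
#' design, the dose as printed in the source (free text, stored only), the
#' metabolizer identification method, and a reference key. Per-group
#' adjustments and sample sizes are not part of this table; for a modelling
#' dataset with those fields see [simulate_example_dataset()].
#'
#' @return A data.frame with 51 rows (18 substances) and columns `drug`,
#'   `parameter`, `population`, `dosing`, `dose`, `id_method`, `reference`.
#' @export
study_characteristics <- function() {
  f <- system.file("extdata", "cyp2c19_studies.csv", package = "pgxdose",
                   mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
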