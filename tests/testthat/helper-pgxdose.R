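# Build a minimal valid sampling-point table from per-row vectors.
make_points <- function(substance, phenotype, adjustment, n,
                        study_id = paste0("S", seq_along(substance)),
                        pool_rm17 = 0L, pool_im17 = 0L, pool_em2 = 0L,
                        pool_em17 = 0L, pk_param = "AUC",
                        population = "healthy", dosing = "SD",
                        id_method = "genotyping") {
  validate_sampling_points(data.frame(
    study_id = study_id, substance = substance, phenotype = phenotype,
    adjustment = adjustment, n = n, pool_rm17 = pool_rm17,
    pool_im17 = pool_im17, pool_em2 = pool_em2, pool_em17 = pool_em17,
    pk_param = pk_param, population = population, dosing = dosing,
    id_method = id_method, stringsAsFactors = FALSE
  ))
}

# Short-chain fit for unit tests (reliability warnings are expected noise
# at these lengths and are silenced; assertions are on values).
quick_fit <- function(data, prior, seed, ...) {
  suppressWarnings(fit_adjustment(data, prior = prior, chains = 2,
                                  adapt = 400, warmup = 400, iter = 1200,
                                  seed = seed, ...))
}

quick_factor <- function(points, seed, ...) {
  suppressWarnings(fit_phenotype_factor(points, chains = 2, adapt = 400,
                                        warmup = 400, iter = 1200,
                                        seed = seed, ...))
}
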