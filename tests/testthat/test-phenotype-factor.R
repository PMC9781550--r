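test_that("score derivation reproduces the published rescaling arithmetic", {
  # group medians chosen so the ratios give the published working values
  med <- c(IM = -25, PM = -49, RM = 17.5, UM = 43.75)
  ds <- derive_activity_scores(med)
  raw <- setNames(ds$raw$median, ds$raw$term)
  expect_equal(raw[["EM"]], 0)
  expect_equal(raw[["IM"]], -1)
  expect_equal(raw[["PM"]], -1.96)
  expect_equal(raw[["RM"]], 0.70)
  expect_equal(raw[["UM"]], 1.75)
  # one *17 allele: mean of RM and half the UM estimate
  expect_equal(ds$allelic_17$median, (0.70 + 1.75 / 2) / 2)
  # rounded working map: PM -2, RM 0.8, UM 1.6
  expect_equal(unname(unclass(ds$map)[c("PM", "IM", "EM", "RM", "UM")]),
               c(-2, -1, 0, 0.8, 1.6))
})

test_that("derived scores are exactly invariant to rescaling all adjustments", {
  med <- c(IM = -25, PM = -49, RM = 17.5, UM = 43.75)
  for (k in c(0.2, 1, 3.7)) {
    expect_equal(derive_activity_scores(k * med)$raw,
                 derive_activity_scores(med)$raw)
  }
})

test_that("a symmetric RM = UM/2 case derives without rounding drift", {
  ds <- derive_activity_scores(c(IM = -20, PM = -40, RM = 10, UM = 20))
  expect_equal(ds$allelic_17$median, 0.5)
  expect_equal(unname(unclass(ds$map)[c("RM", "UM")]), c(0.5, 1.0))
})

test_that("the derivation refuses an undefined or missing IM scale", {
  expect_error(derive_activity_scores(c(IM = 1e-9, PM = -40)), "undefined")
  expect_error(derive_activity_scores(c(PM = -40, RM = 10)), "IM group absent")
  expect_error(derive_activity_scores(c(IM = -20, PM = -40)), "neither RM nor UM")
})

test_that("group means are recovered on synthetic data with known truth", {
  # true group means {PM -50, IM -25, RM 15, UM 30} via a shared slope of 25
  # and scores {-2, -1, 0.6, 1.2}; 40 studies of n = 50, no confounders
  cfg <- generator_config(
    slopes = setNames(rep(25, 10), sprintf("d%02d", 1:10)),
    studies_per_substance = rep(4, 10), n_range = c(50, 50),
    score_map = activity_score_map(rm = 0.6),
    conf_probs = c(pool_rm17 = 0, pool_im17 = 0, pool_em2 = 0,
                   pool_em17 = 0),
    seed = 71)
  sim <- simulate_sampling_points(cfg)
  pts <- apply_exclusions(sim$points, drop_em = TRUE)
  fit <- quick_factor(pts, seed = 72, confounders = NULL)
  est <- setNames(fit$groups$median, fit$groups$term)
  truth <- c(PM = -50, IM = -25, RM = 15, UM = 30)
  for (g in names(truth)) {
    # group-mean standard error is ~ sigma_row / sqrt(rows in group)
    rows <- sum(pts$phenotype == g)
    se <- sqrt(55^2 / 50 + 20^2) / sqrt(rows)
    expect_lt(abs(est[[g]] - truth[[g]]), 4 * se)
  }
  # interval ordering invariant
  expect_true(all(fit$groups$lower <= fit$groups$median))
  expect_true(all(fit$groups$median <= fit$groups$upper))
})

test_that("phenotype levels with no rows are reported absent, not zero", {
  pts <- make_points(rep("a", 6), rep(c("PM", "IM"), 3),
                     c(-40, -20, -38, -22, -41, -19), rep(30, 6),
                     study_id = paste0("S", 1:6))
  fit <- quick_factor(pts, seed = 5, confounders = NULL,
                      study_effect = FALSE)
  expect_setequal(fit$groups$term, c("PM", "IM"))
  expect_false("UM" %in% fit$groups$term)
})

test_that("constant confounder columns are dropped with a warning", {
  pts <- make_points(rep("a", 4), rep(c("PM", "IM"), 2),
                     c(-40, -20, -38, -22), rep(30, 4))
  expect_warning(
    fit <- fit_phenotype_factor(pts, confounders = "pool_rm17",
                                study_effect = FALSE, chains = 1,
                                adapt = 200, warmup = 200, iter = 400,
                                seed = 2),
    "constant"
  )
  expect_null(fit$pooling)
})
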