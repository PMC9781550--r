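test_that("linearity diagnostics pass linear truth and flag injected curvature", {
  base <- list(
    slopes = setNames(rep(22, 10), sprintf("d%02d", 1:10)),
    studies_per_substance = rep(5, 10), n_range = c(40, 40),
    conf_probs = c(pool_rm17 = 0, pool_im17 = 0, pool_em2 = 0,
                   pool_em17 = 0)
  )
  lin <- simulate_sampling_points(do.call(generator_config,
                                          c(base, seed = 61)))
  pts <- apply_exclusions(lin$points, drop_em = TRUE)
  dl <- suppressWarnings(check_linearity(pts, confounders = NULL,
                                         chains = 2, adapt = 400,
                                         warmup = 400, iter = 1200,
                                         seed = 62))
  expect_setequal(dl$term, c("linear", "quadratic", "cubic",
                             "slope_17_extra"))
  for (tm in c("quadratic", "cubic", "slope_17_extra")) {
    expect_false(dl$excludes_zero[dl$term == tm])
  }

  curved <- simulate_sampling_points(do.call(generator_config,
                                             c(base, quadratic = 25,
                                               seed = 63)))
  ptsq <- apply_exclusions(curved$points, drop_em = TRUE)
  dq <- suppressWarnings(check_linearity(ptsq, confounders = NULL,
                                         chains = 2, adapt = 400,
                                         warmup = 400, iter = 1200,
                                         seed = 64))
  expect_true(dq$excludes_zero[dq$term == "quadratic"])
})

test_that("polynomial terms are reported absent with too few score levels", {
  pts <- make_points(rep("a", 8), rep(c("PM", "IM"), 4),
                     rnorm(8, rep(c(-40, -20), 4), 5), rep(30, 8))
  expect_warning(
    dl <- check_linearity(pts, confounders = NULL, study_effect = FALSE,
                          chains = 1, adapt = 200, warmup = 200,
                          iter = 400, seed = 65),
    "fewer than 3 distinct"
  )
  expect_false("quadratic" %in% dl$term)
})

test_that("the transformation check keeps the raw scale for additive truth and prefers log for multiplicative truth", {
  base <- list(
    slopes = setNames(rep(30, 8), sprintf("d%02d", 1:8)),
    studies_per_substance = rep(6, 8), n_range = c(40, 40),
    conf_probs = c(pool_rm17 = 0, pool_im17 = 0, pool_em2 = 0,
                   pool_em17 = 0)
  )
  addv <- simulate_sampling_points(do.call(generator_config,
                                           c(base, seed = 66)))
  tc <- suppressWarnings(check_log_transform(
    apply_exclusions(addv$points, drop_em = TRUE), confounders = NULL,
    chains = 2, adapt = 400, warmup = 400, iter = 1000, seed = 67))
  expect_identical(tc$verdict, "raw")
  expect_lt(abs(tc$skew_raw), 0.5)

  mult <- simulate_sampling_points(do.call(generator_config,
                                           c(base, multiplicative = TRUE,
                                             seed = 68)))
  tm <- suppressWarnings(check_log_transform(
    apply_exclusions(mult$points, drop_em = TRUE), confounders = NULL,
    chains = 2, adapt = 400, warmup = 400, iter = 1000, seed = 69))
  expect_identical(tm$verdict, "log")
  expect_gt(abs(tm$skew_raw), abs(tm$skew_log))
})
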