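test_that("identical config and seed give a bit-identical dataset", {
  cfg <- generator_config(n_substances = 6, seed = 31)
  a <- simulate_sampling_points(cfg)
  b <- simulate_sampling_points(cfg)
  expect_identical(a$points, b$points)
  expect_identical(a$truth$slopes, b$truth$slopes)
  cfg2 <- generator_config(n_substances = 6, seed = 32)
  expect_false(identical(simulate_sampling_points(cfg2)$points, a$points))
})

test_that("EM rows carry adjustment 0 and flagged-zero substances have slope 0", {
  sim <- simulate_sampling_points(generator_config(n_substances = 10,
                                                   seed = 8))
  em <- sim$points[sim$points$phenotype == "EM", ]
  expect_gt(nrow(em), 0)
  expect_true(all(em$adjustment == 0))
  expect_true(all(sim$truth$slopes[sim$truth$slopes == 0] == 0))
})

test_that("the zero-slope fraction matches the configured mixture rate", {
  cfg <- generator_config(n_substances = 2000, prop_nonzero = 0.5,
                          studies_per_substance = c(1, 1), seed = 9)
  sim <- simulate_sampling_points(cfg)
  frac0 <- mean(sim$truth$slopes == 0)
  se <- sqrt(0.25 / 2000)
  expect_lt(abs(frac0 - 0.5), 2 * se)
})

test_that("marginal moments follow the generative model", {
  # a zero-slope substance with no confounders: y averages to 0
  cfg <- generator_config(slopes = c(nullsub = 0),
                          studies_per_substance = c(200, 200),
                          n_range = c(50, 50),
                          conf_probs = c(pool_rm17 = 0, pool_im17 = 0,
                                         pool_em2 = 0, pool_em17 = 0),
                          seed = 13)
  sim <- simulate_sampling_points(cfg)
  y <- sim$points$adjustment[sim$points$phenotype != "EM"]
  sd_row <- sqrt(55^2 / 50 + 20^2)
  expect_lt(abs(mean(y)), 3 * sd_row / sqrt(length(y)))

  # with sigma_w = sigma_b, n = 1 rows have variance 2 sigma^2
  v <- sampling_point_variance(1, 30, 30)
  expect_equal(v, 2 * 30^2)
})

test_that("sample sizes respect the configured range and pooled studies lack UM rows", {
  sim <- simulate_sampling_points(generator_config(n_substances = 30,
                                                   seed = 17))
  expect_true(all(sim$points$n >= 1 & sim$points$n <= 507))
  pooled_studies <- unique(sim$points$study_id[sim$points$pool_rm17 == 1])
  if (length(pooled_studies) > 0) {
    pooled_rows <- sim$points[sim$points$study_id %in% pooled_studies, ]
    expect_false(any(pooled_rows$phenotype == "UM"))
  }
})

test_that("recovery_report is exact for a degenerate self-comparison", {
  sim <- simulate_sampling_points(generator_config(n_substances = 4,
                                                   seed = 23))
  pts <- apply_exclusions(sim$points, drop_em = TRUE)
  subs <- sort(unique(pts$substance))
  # a degenerate 'posterior' equal to the truth
  fake <- structure(list(
    slopes = data.frame(term = subs,
                        median = unname(sim$truth$slopes[subs]),
                        lower = unname(sim$truth$slopes[subs]),
                        upper = unname(sim$truth$slopes[subs])),
    variance = NULL,
    draws = list(beta = matrix(rep(sim$truth$slopes[subs], each = 2),
                               2, dimnames = list(NULL, subs))),
    diagnostics = list(reliable = TRUE)
  ), class = "adjfit")
  rep <- recovery_report(sim$truth, fake)
  expect_equal(rep$aggregate$rmse, 0)
  expect_equal(rep$aggregate$coverage, 1)
  expect_true(all(rep$per_substance$bias == 0))
})
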