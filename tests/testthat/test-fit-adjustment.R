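test_that("fixed-effects posterior means match the weighted-least-squares closed form", {
  # 30-point design over 3 substances with known residual scales
  set.seed(14)
  pts <- make_points(
    substance = rep(c("a", "b", "c"), each = 10),
    phenotype = sample(c("PM", "IM", "RM", "UM"), 30, replace = TRUE),
    adjustment = 0, n = sample(c(2, 5, 10, 50, 200), 30, replace = TRUE),
    pool_rm17 = rbinom(30, 1, 0.3),
    study_id = paste0("S", 1:30)
  )
  sm <- activity_score_map()
  true_beta <- c(a = 30, b = 0, c = -15)
  sigma_w <- 40; sigma_b <- 15
  sc <- unname(unclass(sm)[pts$phenotype])
  mu <- true_beta[pts$substance] * sc + 25 * pts$pool_rm17
  pts$adjustment <- mu + rnorm(30, 0, sqrt(sigma_w^2 / pts$n + sigma_b^2))
  pts <- validate_sampling_points(as.data.frame(pts))

  d <- build_design(pts, sm, confounders = "pool_rm17")
  fit <- suppressWarnings(fit_adjustment(d, prior = "fixed",
      fix_variance = c(sigma_w = sigma_w, sigma_b = sigma_b),
      chains = 2, adapt = 500, warmup = 500, iter = 3000, seed = 15))

  # independent oracle: generalized least squares with the same weights and
  # the same proper-but-flat prior precision
  Z <- cbind(d$X, d$R)
  W <- diag(1 / (sigma_w^2 / d$n + sigma_b^2))
  A <- t(Z) %*% W %*% Z + diag(1e-6, ncol(Z))
  bhat <- drop(solve(A, t(Z) %*% W %*% d$y))

  est <- c(fit$slopes$mean, fit$theta$mean)
  ess <- c(fit$slopes$ess, fit$theta$ess)
  sds <- apply(cbind(fit$draws$beta, fit$draws$theta), 2, sd)
  mcse <- sds / sqrt(ess)
  expect_true(all(abs(est - bhat) < 3 * mcse + 1e-8))

  # and the GLS posterior covariance is matched in scale too
  expect_equal(unname(sds), unname(sqrt(diag(solve(A)))), tolerance = 0.15)
})

test_that("adjusted-dose predictions transform the slope draws directly", {
  pts <- make_points(c("a", "a"), c("PM", "IM"), c(-40, -20), c(20, 20))
  fit <- quick_fit(pts, "fixed", seed = 3, confounders = NULL)
  # degenerate posterior: every slope draw equal to +20
  fit$draws$beta[] <- 20
  p <- predict(fit, "a", phenotype = c("PM", "EM", "UM"))
  expect_equal(p$dose_pct, c(100 + 20 * -2, 100, 100 + 20 * 1.6))
  expect_equal(p$lower, p$dose_pct)  # zero-width for a degenerate posterior

  # symmetric draws: median dose 132% at UM, interval symmetric about it
  fit$draws$beta[] <- 20 + rep(c(-3, -1, 0, 1, 3), length.out =
                                 nrow(fit$draws$beta))
  pu <- predict(fit, "a", score = 1.6)
  expect_equal(pu$dose_pct, 132, tolerance = 1e-8)
  expect_equal(pu$upper - pu$dose_pct, pu$dose_pct - pu$lower,
               tolerance = 1e-6)
  expect_error(predict(fit, "nosuch"), "known substances|fitted substances")
})

test_that("EM prediction is exactly 100% with a zero-width interval in every regime", {
  pts <- make_points(c("a", "a", "a"), c("PM", "IM", "RM"),
                     c(-40, -20, 15), c(20, 20, 20))
  for (pr in c("fixed", "gaussian", "horseshoe", "reg_horseshoe")) {
    fit <- quick_fit(pts, pr, seed = 4, confounders = NULL)
    p <- suppressWarnings(predict(fit, "a", phenotype = "EM"))
    expect_identical(p$dose_pct, 100)
    expect_identical(p$lower, 100)
    expect_identical(p$upper, 100)
  }
})

test_that("a lone small study with a large effect is shrunk toward zero", {
  # dense, unambiguous substances plus one single-study n=8 outlier
  set.seed(6)
  dense <- make_points(
    substance = rep(c("d1", "d2", "d3"), each = 8),
    phenotype = rep(c("PM", "IM", "RM", "UM"), 6),
    adjustment = rnorm(24, rep(c(-2, -1, 0.8, 1.6), 6) * 10, 8),
    n = rep(100, 24), study_id = paste0("S", rep(1:12, each = 2))
  )
  lone <- make_points("sparse", c("PM", "IM"), c(-130, -65), c(8, 8),
                      study_id = c("SX", "SX"))
  pts <- validate_sampling_points(rbind(as.data.frame(dense),
                                        as.data.frame(lone)))
  ffix <- quick_fit(pts, "fixed", seed = 7, confounders = NULL)
  fhs <- quick_fit(pts, "reg_horseshoe", seed = 7, confounders = NULL)
  expect_lt(abs(coef(fhs)[["sparse"]]), abs(coef(ffix)[["sparse"]]))
})

test_that("fit objects expose coherent methods and summaries", {
  sim <- simulate_sampling_points(generator_config(n_substances = 5,
                                                   seed = 41))
  pts <- apply_exclusions(sim$points, drop_em = TRUE)
  fit <- quick_fit(pts, "gaussian", seed = 42)
  expect_s3_class(fit, "adjfit")
  expect_named(coef(fit), sort(unique(pts$substance)), ignore.order = TRUE)
  expect_true(all(fit$slopes$lower <= fit$slopes$median))
  expect_true(all(fit$slopes$median <= fit$slopes$upper))
  expect_equal(length(residuals(fit)), nrow(pts))
  expect_equal(fitted(fit) + residuals(fit), pts$adjustment)
  expect_output(print(fit), "Per-substance slopes")
  expect_output(summary(fit), "Diagnostics")
  expect_true(all(c("tau") %in% fit$shrinkage$term))
  # shrinkage fields only exist where the regime defines them
  ffix <- quick_fit(pts, "fixed", seed = 42)
  expect_null(ffix$shrinkage)
})

test_that("doubling n increases a point's weight but never past the sigma_b bound", {
  w <- function(n) 1 / sampling_point_variance(n, 40, 15)
  n <- c(1, 2, 8, 64, 512)
  expect_true(all(w(2 * n) > w(n)))
  expect_true(all(w(2 * n) < 1 / 15^2))
})
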