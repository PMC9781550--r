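test_that("the score map is EM-anchored and ordered", {
  m <- activity_score_map()
  expect_identical(unname(m[c("PM", "IM", "EM", "RM", "UM")]),
                   c(-2, -1, 0, 0.8, 1.6))
  expect_error(activity_score_map(em = 1), "EM-anchored")
  expect_error(activity_score_map(pm = -1, im = -2), "ordered")
})

test_that("X matches an independent double-loop construction cell by cell", {
  pts <- make_points(
    substance = c("a", "a", "a", "b", "b", "b"),
    phenotype = c("PM", "IM", "UM", "IM", "RM", "PM"),
    adjustment = c(-40, -20, 30, -25, 10, -45),
    n = c(5, 10, 3, 8, 2, 7)
  )
  scores <- activity_score_map(pm = -2, im = -1, rm = 0.8, um = 1.6)
  d <- build_design(pts, scores, confounders = NULL)

  # brute force: loop every cell independently of the vectorised builder
  subs <- d$substances
  Xref <- matrix(0, nrow(pts), length(subs), dimnames = list(NULL, subs))
  for (i in seq_len(nrow(pts))) {
    for (j in seq_along(subs)) {
      if (pts$substance[i] == subs[j]) {
        Xref[i, j] <- unclass(scores)[[pts$phenotype[i]]]
      }
    }
  }
  expect_equal(unname(d$X), unname(Xref))
  expect_equal(d$y, pts$adjustment)
  expect_equal(d$n, pts$n)
})

test_that("every X row has one nonzero entry and no column is all zero", {
  for (s in 1:5) {
    sim <- simulate_sampling_points(generator_config(n_substances = 5,
                                                     seed = 100 + s))
    pts <- apply_exclusions(sim$points, drop_em = TRUE)
    d <- build_design(pts, confounders = NULL)
    expect_true(all(rowSums(d$X != 0) == 1))
    expect_true(all(colSums(d$X != 0) > 0))
  }
})

test_that("row permutation permutes the matrices with identical columns", {
  sim <- simulate_sampling_points(generator_config(n_substances = 4,
                                                   seed = 5))
  pts <- apply_exclusions(sim$points, drop_em = TRUE)
  d1 <- build_design(pts)
  set.seed(1)
  perm <- sample(nrow(pts))
  d2 <- build_design(pts[perm, ])
  expect_identical(d1$substances, d2$substances)
  expect_equal(unname(d2$X), unname(d1$X[perm, ]))
  expect_equal(d2$y, d1$y[perm])
  expect_equal(unname(d2$R), unname(d1$R[perm, , drop = FALSE]))
})

test_that("EM rows are rejected and degenerate columns are dropped", {
  em <- make_points(c("a", "a"), c("EM", "IM"), c(0, -20), c(5, 5))
  expect_error(build_design(em), "EM rows")

  pts <- make_points(c("a", "b"), c("IM", "IM"), c(-20, -10), c(5, 5),
                     pool_rm17 = 0L)
  expect_warning(d <- build_design(pts, confounders = "pool_rm17"),
                 "no nonzero entries")
  expect_equal(ncol(d$R), 0)
})

test_that("confounder coding supports flags and score interactions", {
  pts <- make_points(c("a", "a"), c("UM", "PM"), c(50, -40), c(5, 5),
                     pool_em17 = c(1L, 0L))
  d <- build_design(pts, confounders = c(pool_em17 = "flag"))
  expect_equal(unname(d$R[, 1]), c(1, 0))
  di <- build_design(pts, confounders = c(pool_em17 = "interaction"))
  expect_equal(unname(di$R[, 1]), c(1.6, 0))
  expect_error(build_design(pts, confounders = "not_a_field"),
               "unknown confounder")
})
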