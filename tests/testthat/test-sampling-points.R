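test_that("validation normalises tokens and enforces the schema", {
  pts <- make_points(c("Mianserine", "escitalopram "), c("em", "pm"),
                     c(0, -60), c(10, 5))
  expect_s3_class(pts, "sampling_points")
  expect_equal(pts$substance, c("mianserin", "escitalopram"))
  expect_equal(pts$phenotype, c("EM", "PM"))

  base <- as.data.frame(make_points("a", "IM", -20, 10))
  expect_error(validate_sampling_points(base[, -match("n", names(base))]),
               "lacks column.*n")
  bad_n <- base; bad_n$n <- 0
  expect_error(validate_sampling_points(bad_n), "positive integer")
  bad_ph <- base; bad_ph$phenotype <- "XM"
  expect_error(validate_sampling_points(bad_ph), "unknown phenotype.*XM")
  bad_adj <- base; bad_adj$adjustment <- NA
  expect_error(validate_sampling_points(bad_adj), "non-finite")
})

test_that("blank design flags default to 0 with a warning", {
  base <- as.data.frame(make_points("a", "IM", -20, 10))
  base$pool_em17 <- NA
  expect_warning(out <- validate_sampling_points(base), "defaulted to 0")
  expect_identical(out$pool_em17, 0L)
})

test_that("CSV round-trip reproduces the collection field-by-field", {
  sim <- simulate_sampling_points(generator_config(n_substances = 4,
                                                   seed = 11))
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_sampling_points(sim$points, f)
  back <- suppressMessages(read_sampling_points(f))
  expect_equal(as.data.frame(back), as.data.frame(sim$points))
})

test_that("an empty table with a valid header loads with a warning", {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_sampling_points(make_points("a", "IM", -20, 10)[0, ], f)
  expect_warning(out <- read_sampling_points(f), "empty")
  expect_equal(nrow(out), 0)
})

test_that("exclusion rules filter as specified, log removals, and are idempotent", {
  set.seed(3)
  sim <- simulate_sampling_points(generator_config(n_substances = 6,
                                                   seed = 21))
  pts <- sim$points
  pts$substance[pts$substance == "substance_01"] <- "mianserin"
  pts$substance[pts$substance == "substance_02"] <- "fluoxetine"

  # only two of the four non-substrates exist in this fixture; the warning
  # about the others is exercised below with an explicit expectation
  out <- suppressWarnings(
    apply_exclusions(pts, drop_em = TRUE,
                     drop_substances = non_substrate_substances()))
  expect_false(any(out$phenotype == "EM"))
  expect_false(any(out$substance %in% c("mianserin", "fluoxetine")))
  lg <- exclusion_log(out)
  expect_equal(lg$removed[lg$rule == "drop_em_rows"],
               sum(pts$phenotype == "EM"))
  # rules apply sequentially: the substance rule sees only non-EM survivors
  expect_equal(lg$removed[lg$rule == "drop_substances"],
               sum(pts$substance %in% c("mianserin", "fluoxetine") &
                     pts$phenotype != "EM"))

  # unknown substance in a rule warns and removes nothing
  expect_warning(out2 <- apply_exclusions(pts, drop_em = FALSE,
                                          drop_substances = "nosuchdrug"),
                 "unknown substance")
  expect_equal(nrow(out2), nrow(pts))

  # flagged-row rule: survivors are exactly the unflagged rows
  ten <- make_points(rep("a", 10), rep("RM", 10), rnorm(10, 15), rep(20, 10),
                     pool_rm17 = c(1, 1, 1, rep(0, 7)))
  surv <- apply_exclusions(ten, drop_em = FALSE, drop_rm_pooled = TRUE)
  expect_equal(nrow(surv), 7)

  # idempotence: applying the same rules twice leaves the rows unchanged
  twice <- suppressWarnings(
    apply_exclusions(out, drop_em = TRUE,
                     drop_substances = non_substrate_substances()))
  attr(twice, "exclusion_log") <- attr(out, "exclusion_log") <- NULL
  expect_equal(as.data.frame(twice), as.data.frame(out))
})

test_that("the packaged study-characteristics table has the published shape", {
  tab <- study_characteristics()
  expect_equal(nrow(tab), 51)
  expect_equal(length(unique(tab$drug)), 18)
  expect_true(all(c("drug", "parameter", "population", "dosing", "dose",
                    "id_method", "reference") %in% names(tab)))
})
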