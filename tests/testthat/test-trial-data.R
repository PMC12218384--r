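test_that("CSV round-trip reproduces the dataset field for field", {
  x <- make_small_trial()
  path <- tempfile(fileext = ".csv")
  write_trial_data(x, path)
  y <- read_trial_data(path)
  expect_equal(y$participants, x$participants)
  expect_equal(y$assessments[order(names(y$assessments))],
               x$assessments[order(names(x$assessments))])
  expect_equal(y$timepoints, x$timepoints)
  expect_equal(y$currency_year, x$currency_year)

  # and for a larger generated trial with missing cells
  sim <- simulate_trial(trial_params(), seed = 3)
  p2 <- tempfile(fileext = ".csv")
  write_trial_data(sim$data, p2)
  z <- read_trial_data(p2)
  expect_equal(z$participants, sim$data$participants)
  expect_equal(z$assessments[names(sim$data$assessments)],
               sim$data$assessments, tolerance = 1e-12)
})

test_that("reader counts, schema mapping and empty-cell semantics", {
  path <- write_small_trial_csv()
  x <- read_trial_data(path)
  expect_equal(nrow(x$participants), 4L)
  expect_equal(nrow(x$assessments), 12L)

  # schema mapping renames a source column to its canonical name
  raw <- read.csv(path, check.names = FALSE)
  names(raw)[names(raw) == "utility"] <- "eq5d_index"
  p2 <- tempfile(fileext = ".csv")
  write.csv(raw, p2, row.names = FALSE, na = "")
  y <- read_trial_data(p2, schema = c(utility = "eq5d_index"))
  expect_equal(y$assessments$utility, x$assessments$utility)

  # empty cells are missing, never zero
  raw$utility <- raw$eq5d_index
  raw$eq5d_index <- NULL
  raw$utility[2] <- NA
  p3 <- tempfile(fileext = ".csv")
  write.csv(raw, p3, row.names = FALSE, na = "")
  z <- read_trial_data(p3)
  expect_true(is.na(z$assessments$utility[
    z$assessments$participant_id == raw$participant_id[2] &
      z$assessments$timepoint_months == raw$timepoint_months[2]]))
  expect_false(any(z$assessments$utility == 0, na.rm = TRUE))
})

test_that("validation rejects out-of-range and malformed records precisely", {
  x <- make_small_trial()

  # missing required column named in the error
  path <- write_small_trial_csv()
  raw <- read.csv(path, check.names = FALSE)
  raw$arm <- NULL
  p2 <- tempfile(fileext = ".csv")
  write.csv(raw, p2, row.names = FALSE, na = "")
  expect_error(read_trial_data(p2), "arm")

  # duplicate (participant, timepoint)
  a <- x$assessments
  expect_error(trial_data(x$participants, rbind(a, a[1, ])), "duplicate")

  # EQ-5D level out of range cites the offending rows
  a2 <- x$assessments
  a2$eq5d_mo <- 1L
  a2$eq5d_sc <- 1L
  a2$eq5d_ua <- 1L
  a2$eq5d_pd <- 1L
  a2$eq5d_ad <- 1L
  a2$eq5d_mo[5] <- 6L
  expect_error(trial_data(x$participants, a2), "eq5d_mo.*5")

  # range violations are rejected, never coerced
  a3 <- x$assessments; a3$utility[1] <- 1.4
  expect_error(trial_data(x$participants, a3), "utility")
  a4 <- x$assessments; a4$ru_gp_visit[1] <- -1L
  expect_error(trial_data(x$participants, a4), "nonnegative")
  a5 <- x$assessments; a5$hours_missed_7d[1] <- 169
  expect_error(trial_data(x$participants, a5), "hours")
  p_bad <- x$participants; p_bad$age[1] <- 16L
  expect_error(trial_data(p_bad, x$assessments), "18")
  p_bad2 <- x$participants; p_bad2$imd_quintile[1] <- 7L
  expect_error(trial_data(p_bad2, x$assessments), "imd")
})

test_that("missingness report reproduces the arm-imbalanced pattern", {
  # complete dataset: zero missing everywhere
  r0 <- missingness_summary(make_small_trial())
  expect_equal(r0$by_arm$missing, c(0L, 0L))
  expect_equal(sum(r0$by_participant$any_missing), 0L)

  # generator calibrated to the 1-vs-36 imbalance reproduces it exactly
  sim <- simulate_trial(trial_params(), seed = 11)
  r <- missingness_summary(sim$data)
  expect_equal(r$by_arm$expected[r$by_arm$arm == "control"], 354L)
  expect_equal(r$by_arm$expected[r$by_arm$arm == "intervention"], 348L)
  expect_equal(r$by_arm$missing[r$by_arm$arm == "control"], 1L)
  expect_equal(r$by_arm$missing[r$by_arm$arm == "intervention"], 36L)

  # unknown variable errors
  expect_error(missingness_summary(sim$data, "nope"), "unknown variable")

  # a participant missing every utility counts once in the any-missing flag
  x <- make_small_trial()
  x$assessments$utility[x$assessments$participant_id == "A"] <- NA
  r2 <- missingness_summary(x)
  expect_equal(sum(r2$by_participant$any_missing), 1L)
  expect_equal(r2$by_participant$n_missing[r2$by_participant$participant_id == "A"], 3L)

  # counts invariant under row reordering of the input
  path <- tempfile(fileext = ".csv")
  write_trial_data(sim$data, path)
  raw <- read.csv(path, check.names = FALSE)
  set.seed(5)
  raw <- raw[sample(nrow(raw)), ]
  p2 <- tempfile(fileext = ".csv")
  write.csv(raw, p2, row.names = FALSE, na = "")
  r3 <- missingness_summary(read_trial_data(p2))
  expect_equal(r3$by_arm$missing, r$by_arm$missing)

  # report writers round-trip
  csvp <- tempfile(fileext = ".csv")
  write_missingness_report(r, csvp)
  expect_equal(read.csv(csvp)$missing, r$by_arm$missing)
})
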