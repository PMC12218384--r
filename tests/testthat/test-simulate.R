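test_that("ground truth follows closed-form arithmetic", {
  # AUC weights 1/4,1/2,1/4: effects (0.08, 0.04) give a naive 0.05; the
  # exact truth is marginally lower because of the ceiling mass at u = 1
  tr <- trial_truth(trial_params())
  expect_equal(tr$components$naive_delta_effect, 0.05)
  # the ceiling mass at u = 1 shrinks the realised mean effect slightly
  expect_lt(tr$delta_effect, 0.05)
  expect_gt(tr$delta_effect, 0.045)

  # independent Monte Carlo oracle for the censored-shift expectation
  p <- trial_params()
  cal <- trialcua:::cnorm_calibrate(p$utility_mean, p$utility_sd,
                                    -0.532, 1)
  set.seed(1)
  L <- rnorm(2e6, cal$mu + p$utility_drift[["m3"]], cal$sigma)
  y0 <- pmin(pmax(L, -0.532), 1)
  y1 <- pmin(y0 + 0.08, 1)
  mc_gain <- mean(y1) - mean(y0)
  closed <- trialcua:::shifted_cnorm_mean(cal$mu + p$utility_drift[["m3"]],
                                          cal$sigma, -0.532, 1, 0.08) -
    trialcua:::cnorm_mean(cal$mu + p$utility_drift[["m3"]], cal$sigma,
                          -0.532, 1)
  expect_equal(closed, mc_gain, tolerance = 1e-3)

  # with bounds far away the clamp correction vanishes
  wide <- trial_params(utility_bounds = c(-50, 50), utility_mean = 0.478)
  expect_equal(trial_truth(wide)$delta_effect, 0.05, tolerance = 1e-10)

  # healthcare saving of GBP 260 against a GBP 1000 charge: NHS/PSS 740
  expect_equal(unname(tr$delta_cost[["nhs_pss"]]), 740)

  # null scenario: zero effect, cost difference is the charge alone
  tr0 <- trial_truth(trial_params("null"))
  expect_equal(tr0$delta_effect, 0)
  expect_equal(unname(tr0$delta_cost[["nhs_pss"]]), 1000)

  # societal truth subtracts productivity and food savings
  expect_equal(tr$delta_cost[["societal"]],
               tr$delta_cost[["nhs_pss"]] + tr$components$productivity +
                 tr$components$food)
  expect_lt(tr$delta_cost[["societal"]], 0)   # cost-saving scenario
  expect_lt(trial_truth(trial_params("dominant_societal"))$delta_cost[["societal"]],
            tr$delta_cost[["societal"]])

  expect_error(trial_params(utility_mean = 2), "utility_mean|inside")
  expect_error(trial_params(nonsense = 1), "unknown parameter")
})

test_that("generated trials have the configured structure", {
  sim <- simulate_trial(trial_params(), seed = 50)
  d <- sim$data
  expect_equal(sum(d$participants$arm == "control"), 118L)
  expect_equal(sum(d$participants$arm == "intervention"), 116L)
  expect_equal(nrow(d$assessments), 702L)
  # sex split near 85.5% female (3 binomial SEs)
  p_f <- mean(d$participants$sex == "female")
  expect_lt(abs(p_f - 0.855), 3 * sqrt(0.855 * 0.145 / 234))
  # utilities within the value-set range, costs and counts nonnegative
  expect_true(all(d$assessments$utility >= -0.532 &
                    d$assessments$utility <= 1, na.rm = TRUE))
  ru <- as.matrix(d$assessments[grep("^ru_", names(d$assessments))])
  expect_true(all(ru >= 0, na.rm = TRUE))
  # exact masked counts per arm
  r <- missingness_summary(d)
  expect_equal(r$by_arm$missing, c(1L, 36L))
})

test_that("generation is deterministic and masking never alters kept values", {
  pth1 <- tempfile(fileext = ".csv"); pth2 <- tempfile(fileext = ".csv")
  write_trial_data(simulate_trial(trial_params(), seed = 77)$data, pth1)
  write_trial_data(simulate_trial(trial_params(), seed = 77)$data, pth2)
  expect_identical(readLines(pth1), readLines(pth2))

  # complete-then-mask: unmasked twin shares every observed value
  masked <- simulate_trial(trial_params(), seed = 78)$data
  full <- simulate_trial(trial_params(missing_counts =
                                        c(control = 0L, intervention = 0L)),
                         seed = 78)$data
  keep <- !is.na(masked$assessments$utility)
  expect_identical(masked$assessments$utility[keep],
                   full$assessments$utility[keep])
  expect_identical(masked$participants, full$participants)
})

test_that("large-sample moments match the generator parameters", {
  p <- trial_params(n_control = 12500L, n_intervention = 12500L,
                    missing_counts = c(control = 0L, intervention = 0L))
  sim <- simulate_trial(p, seed = 60)
  d <- sim$data
  n <- 25000
  a0 <- d$assessments[d$assessments$timepoint_months == 0, ]

  # baseline utility: observed-scale moments are the calibration targets
  expect_lt(abs(mean(a0$utility) - 0.478), 3 * 0.255 / sqrt(n))
  expect_lt(abs(sd(a0$utility) - 0.255), 0.005)

  # baseline healthcare cost means by arm (skewed: allow 3 SEs of a
  # heavy-tailed mean, empirical SD from the sample itself)
  bk <- assemble_costs(d)
  b0 <- bk[bk$timepoint_months == 0, ]
  for (armname in c("control", "intervention")) {
    x <- b0$healthcare_cost[b0$arm == armname]
    target <- unname(p$baseline_cost_mean[[armname]])
    expect_lt(abs(mean(x) - target), 3 * sd(x) / sqrt(length(x)))
  }

  # follow-up arm contrast in healthcare cost near the configured effect
  b3 <- bk[bk$timepoint_months == 3, ]
  dc <- mean(b3$healthcare_cost[b3$arm == "intervention"]) -
    mean(b3$healthcare_cost[b3$arm == "control"])
  se <- sqrt(var(b3$healthcare_cost[b3$arm == "intervention"]) / 12500 +
               var(b3$healthcare_cost[b3$arm == "control"]) / 12500)
  expect_lt(abs(dc - (-130)), 3 * se)

  # hours among employed: censored-normal calibration hits the target
  emp <- d$participants$participant_id[
    d$participants$employment_status %in% c("full_time", "part_time")]
  h0 <- a0$hours_missed_7d[a0$participant_id %in% emp]
  expect_lt(abs(mean(h0) - 10.5), 3 * 14.3 / sqrt(length(h0)))
  expect_lt(abs(sd(h0) - 14.3), 0.4)

  # age and IMD mix
  expect_lt(abs(mean(d$participants$age) - 46.3), 3 * 9.85 / sqrt(n))
  imd_share <- as.numeric(table(d$participants$imd_quintile) / n)
  expect_lt(max(abs(imd_share - p$imd_probs)), 0.01)
})

test_that("full pipeline recovers a null effect on a large trial", {
  p <- trial_params("null", n_control = 2500L, n_intervention = 2500L)
  sim <- simulate_trial(p, seed = 70)
  d <- completed_datasets(sim, m = 1, seed = 1)[[1]]
  fit <- sur_fit(sur_formulas("nhs_pss"), d)
  idx <- length(fit$coefficients$cost) +
    match("armintervention", names(fit$coefficients$effect))
  se <- sqrt(diag(fit$vcov))[idx]
  expect_lt(abs(fit$coefficients$effect[["armintervention"]]), 3 * se)
})

test_that("EQ-5D emission mode exercises the mapping path coherently", {
  p <- trial_params(n_control = 30L, n_intervention = 30L,
                    missing_counts = c(control = 0L, intervention = 0L),
                    emit_eq5d = TRUE)
  sim <- simulate_trial(p, seed = 81)
  a <- sim$data$assessments
  expect_true(all(c("eq5d_mo", "eq5d_ad") %in% names(a)))
  vs <- synthetic_value_set()
  mapped <- map_eq5d_to_utility(a[, eq5d_cols <- c("eq5d_mo", "eq5d_sc",
                                                   "eq5d_ua", "eq5d_pd",
                                                   "eq5d_ad")], vs)
  expect_equal(mapped, a$utility)
})
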