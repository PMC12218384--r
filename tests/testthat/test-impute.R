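test_that("complete data yield m identical copies and no provenance", {
  df <- data.frame(arm = rep(c("a", "b"), each = 10),
                   x = rnorm(20), y = rnorm(20), z = runif(20))
  mi <- impute_mice(df, variables = c("y", "z"), predictors = "x",
                    by = "arm", m = 4, seed = 2)
  expect_equal(mi$m, 4L)
  for (i in 1:4) expect_identical(mi$imputations[[i]], df)
  expect_null(mi$provenance)
})

test_that("imputation is deterministic and never alters observed cells", {
  sim <- simulate_trial(trial_params(), seed = 21)
  bk <- assemble_costs(sim$data)
  tab <- trialcua:::build_analysis_table(sim$data, bk)
  vars <- attr(tab, "wave_vars")
  run <- function(seed) impute_mice(tab, variables = vars,
                                    predictors = c("age", "sex",
                                                   "imd_quintile",
                                                   "primary_symptom"),
                                    by = "arm", m = 3, maxit = 5,
                                    seed = seed)
  a <- run(7); b <- run(7); c3 <- run(8)
  expect_identical(a$imputations, b$imputations)
  expect_false(identical(a$imputations, c3$imputations))

  # observed cells identical across imputations and to the input
  obs <- !a$where
  M0 <- as.matrix(tab[vars])
  for (i in 1:3) {
    Mi <- as.matrix(a$imputations[[i]][vars])
    expect_identical(Mi[obs], M0[obs])
    expect_false(anyNA(Mi))
  }

  # PMM keeps imputed values inside the observed support: utilities within
  # the value-set range, costs nonnegative
  for (i in 1:3) {
    Mi <- as.matrix(a$imputations[[i]][vars])
    ucols <- grep("^u_", colnames(Mi))
    expect_true(all(Mi[, ucols] >= -0.594 & Mi[, ucols] <= 1))
    expect_true(all(Mi[, -ucols] >= 0))
  }

  # provenance covers every imputed cell once per imputation
  expect_equal(nrow(a$provenance), 3L * sum(a$where))
  pp <- tempfile(fileext = ".csv")
  write_imputation_provenance(a, pp)
  expect_equal(nrow(read.csv(pp)), nrow(a$provenance))
})

test_that("arms are imputed independently of each other's data", {
  sim <- simulate_trial(trial_params(), seed = 33)
  bk <- assemble_costs(sim$data)
  tab <- trialcua:::build_analysis_table(sim$data, bk)
  vars <- attr(tab, "wave_vars")
  preds <- c("age", "sex", "imd_quintile", "primary_symptom")
  a <- impute_mice(tab, vars, preds, by = "arm", m = 2, maxit = 5, seed = 5)

  # perturb the intervention arm's observed utilities; control imputations
  # must not move
  tab2 <- tab
  ivn <- tab2$arm == "intervention"
  tab2$u_3[ivn] <- pmin(tab2$u_3[ivn] + 0.1, 1)
  b <- impute_mice(tab2, vars, preds, by = "arm", m = 2, maxit = 5, seed = 5)
  ctl <- tab$arm == "control"
  for (i in 1:2)
    expect_identical(a$imputations[[i]][ctl, vars],
                     b$imputations[[i]][ctl, vars])
})

test_that("degenerate missingness patterns are rejected", {
  df <- data.frame(arm = rep(c("a", "b"), each = 6),
                   x = rnorm(12), y = c(rep(NA, 6), rnorm(6)))
  expect_error(impute_mice(df, "y", "x", by = "arm", m = 2),
               "entirely missing")
  df2 <- data.frame(arm = rep(c("a", "b"), each = 10),
                    x = rnorm(20),
                    y = c(rnorm(4), rep(NA, 6), rnorm(10)))
  expect_error(impute_mice(df2, "y", "x", by = "arm", m = 2), "exceeds")
  expect_error(impute_mice(df2, "y", "missing_col", m = 2), "not in data")
})

test_that("MAR imputation recovers the generating means within Monte Carlo error", {
  # follow-up utilities masked MAR (more missing at low baseline utility in
  # the intervention arm); after PMM imputation the per-arm means should sit
  # near the complete-data means
  delta <- numeric(5)
  for (r in 1:5) {
    seed <- 200 + r
    sim_m <- simulate_trial(trial_params(), seed = seed)
    sim_f <- simulate_trial(trial_params(missing_counts =
                                           c(control = 0L,
                                             intervention = 0L)),
                            seed = seed)
    bk <- assemble_costs(sim_m$data)
    tab <- trialcua:::build_analysis_table(sim_m$data, bk)
    mi <- impute_mice(tab, attr(tab, "wave_vars"),
                      c("age", "sex", "imd_quintile", "primary_symptom"),
                      by = "arm", m = 5, maxit = 5, seed = seed)
    imp_mean <- mean(sapply(mi$imputations, function(d)
      mean(d$u_3[d$arm == "intervention"])))
    full_mean <- mean(sim_f$data$assessments$utility[
      sim_f$data$assessments$timepoint_months == 3][
        sim_f$data$participants$arm == "intervention"])
    delta[r] <- imp_mean - full_mean
  }
  # mean utility ~0.55, sd ~0.25, n=116: Monte Carlo tolerance
  expect_lt(abs(mean(delta)), 0.03)
})

test_that("under MCAR, pooled estimates are unbiased versus complete-data analysis", {
  # reduced-scale simulation: n=200 trials, m=5 imputations, point estimates
  # only (unbiasedness is a property of the estimates, not the bootstrap)
  nrep <- 60
  diff_de <- numeric(nrep)
  f <- sur_formulas("nhs_pss")
  for (r in seq_len(nrep)) {
    seed <- 4000 + r
    pm <- trial_params(n_control = 100L, n_intervention = 100L,
                       mar_slope = 0,
                       missing_counts = c(control = 15L, intervention = 15L))
    sim <- simulate_trial(pm, seed = seed)
    # complete-data analysis on the unmasked twin (same seed, same draws)
    pf <- trial_params(n_control = 100L, n_intervention = 100L,
                       missing_counts = c(control = 0L, intervention = 0L))
    simf <- simulate_trial(pf, seed = seed)
    cd_f <- completed_datasets(simf, m = 1, seed = seed)
    fit_f <- sur_fit(f, cd_f[[1]])

    bk <- assemble_costs(sim$data)
    tab <- trialcua:::build_analysis_table(sim$data, bk)
    mi <- impute_mice(tab, attr(tab, "wave_vars"),
                      c("age", "sex", "imd_quintile", "primary_symptom"),
                      by = "arm", m = 5, maxit = 5, seed = seed)
    cd <- lapply(mi$imputations, trialcua:::derive_outcomes,
                 timepoints = c(0, 3, 6), intervention_cost = 1000,
                 include_baseline_in_total = FALSE)
    de_m <- mean(sapply(cd, function(d)
      sur_fit(f, d)$coefficients$effect[["armintervention"]]))
    diff_de[r] <- de_m -
      fit_f$coefficients$effect[["armintervention"]]
  }
  mcse <- sd(diff_de) / sqrt(nrep)
  expect_lt(abs(mean(diff_de)), 3 * mcse + 0.002)
})
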