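# small in-code fixtures shared across test files

# minimal complete 4-participant trial with hand-checkable values
make_small_trial <- function() {
  participants <- data.frame(
    participant_id = c("A", "B", "C", "D"),
    arm = c("control", "control", "intervention", "intervention"),
    age = c(40L, 55L, 35L, 60L),
    sex = c("female", "male", "female", "female"),
    imd_quintile = c(1L, 3L, 5L, 2L),
    ethnicity = "white",
    primary_symptom = c("fatigue", "pain", "fatigue", "breathlessness"),
    employment_status = c("full_time", "unemployed", "part_time", "full_time"),
    stringsAsFactors = FALSE)
  grid <- expand.grid(participant_id = participants$participant_id,
                      timepoint_months = c(0, 3, 6),
                      stringsAsFactors = FALSE)
  assessments <- data.frame(
    grid,
    utility = round(seq(0.30, 0.85, length.out = 12), 3),
    ru_gp_visit = rep(c(2L, 0L, 1L, 0L), 3),
    ru_ae_visit = rep(c(0L, 1L, 0L, 0L), 3),
    medication_cost = rep(c(10, 0, 5, 20), 3),
    hours_missed_7d = rep(c(8, 0, 4, 0), 3),
    food_cost_7d = rep(c(60, 80, 70, 90), 3),
    household_size = rep(c(2L, 1L, 2L, 3L), 3),
    stringsAsFactors = FALSE)
  trial_data(participants, assessments)
}

write_small_trial_csv <- function(path = tempfile(fileext = ".csv")) {
  write_trial_data(make_small_trial(), path)
  path
}

# value-set CSV fixture written on the fly
write_value_set_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("state,utility", rows), path)
  path
}

# a moderate simulated trial shared by estimation tests (complete data)
sim_complete_trial <- function(seed = 101, n_per_arm = 117) {
  p <- trial_params(n_control = n_per_arm, n_intervention = n_per_arm,
                    missing_counts = c(control = 0L, intervention = 0L))
  simulate_trial(p, seed = seed)
}

# completed analysis datasets (with outcomes) for SUR/bootstrap tests
completed_datasets <- function(sim, m = 1, seed = 1) {
  bk <- assemble_costs(sim$data)
  tab <- trialcua:::build_analysis_table(sim$data, bk)
  mi <- impute_mice(tab, variables = attr(tab, "wave_vars"),
                    predictors = c("age", "sex", "imd_quintile",
                                   "primary_symptom"),
                    by = "arm", m = m, maxit = 5, seed = seed)
  lapply(mi$imputations, trialcua:::derive_outcomes,
         timepoints = sim$data$timepoints, intervention_cost = 1000,
         include_baseline_in_total = FALSE)
}

sur_formulas <- function(perspective = "nhs_pss") {
  list(cost = stats::as.formula(paste0(
         "total_", perspective, " ~ arm + age + sex + imd_quintile + ",
         "primary_symptom + baseline_cost_", perspective)),
       effect = qaly ~ arm + age + sex + imd_quintile + primary_symptom +
         baseline_utility)
}
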