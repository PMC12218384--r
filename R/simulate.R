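#' Parameters for the synthetic two-arm trial generator
#'
#' Defaults emulate a remotely delivered weight-management trial in a
#' long-COVID population: n = 118 + 116, low baseline utility (observed
#' mean 0.478, SD 0.255 on the crosswalk scale, clamped to [-0.532, 1]
#' with a ceiling mass at 1), an intervention utility gain at 3 months that
#' narrows by 6 months (+0.08 / +0.04), right-skewed healthcare costs
#' (baseline arm means GBP 652 / 893; gamma-frailty counts dominated by
#' rare expensive hospitalisations), a follow-up healthcare saving of
#' GBP 130 per wave in the intervention arm, zero-inflated work-loss hours,
#' per-household food spending, and missing-at-random assessment-level
#' missingness concentrated in the intervention arm (1 vs 36 masked
#' observations), with missingness probability increasing as baseline
#' utility falls.
#'
#' @param scenario `"paper_like"` (defaults as above), `"null"` (all arm
#'   effects zero, no masking) or `"dominant_societal"` (stronger
#'   productivity savings).
#' @param ... named overrides of any default listed below.
#' @return An object of class `trial_params` (a validated list).
#' @export
trial_params <- function(scenario = c("paper_like", "null",
                                      "dominant_societal"), ...) {
  scenario <- match.arg(scenario)
  p <- list(
    n_control = 118L,
    n_intervention = 116L,
    timepoints = c(0, 3, 6),
    # utilities (observed-scale moments; latent scale calibrated internally)
    utility_mean = 0.478,
    utility_sd = 0.255,
    utility_bounds = c(-0.532, 1),
    utility_cor = 0.6,            # within-person across waves
    utility_drift = c(m3 = 0.006, m6 = 0.010),   # secular change, both arms
    utility_effect = c(m3 = 0.08, m6 = 0.04),    # additive intervention gain
    # healthcare resource-use costs
    baseline_cost_mean = c(control = 652, intervention = 893),
    followup_cost_mean = 885,
    cost_effect = c(m3 = -130, m6 = -130),       # intervention arm, follow-up
    cost_frailty_shape = 0.5,     # gamma frailty: smaller = more skew
    resource_shares = c(hospitalisation = 0.50, outpatient = 0.16,
                        day_hospital = 0.06, ae_visit = 0.05,
                        gp_visit = 0.10, gp_phone = 0.03,
                        physiotherapist = 0.05, occupational_therapist = 0.02,
                        nurse_visit = 0.02, community_nurse = 0.01),
    medication_mean = 30, medication_sd = 40,
    # productivity (employed participants only)
    hours_mean = 10.5, hours_sd = 14.3,          # observed-scale, censored at 0
    hours_effect = c(m3 = 3.5, m6 = 3.5),        # latent-scale reduction
    # food
    food_weekly_mean = 70, food_weekly_sd = 35,
    food_effect = c(m3 = 18, m6 = 18),           # household-weekly reduction
    household_lambda = 1.0,                      # size = 1 + Poisson
    # covariates (cohort mix)
    p_female = 0.855,
    age_mean = 46.3, age_sd = 9.85, age_range = c(18, 80),
    imd_probs = c(0.132, 0.188, 0.192, 0.218, 0.270),
    symptom_probs = c(pain = 0.120, breathlessness = 0.158, fatigue = 0.538,
                      anxiety_depression = 0.013, other = 0.171),
    ethnicity_probs = c(white = 0.902, south_asian = 0.043,
                        other_asian = 0.021, black = 0.009, other_mixed = 0.025),
    employment_probs = c(full_time = 0.432, part_time = 0.295,
                         retired = 0.026, student = 0.004,
                         unemployed = 0.073, other = 0.170),
    # missingness (assessment-level, follow-up waves, exact per-arm counts)
    missing_counts = c(control = 1L, intervention = 36L),
    mar_slope = -2,               # logit weight on centred baseline utility
    emit_eq5d = FALSE)

  if (scenario == "null") {
    p$utility_effect[] <- 0; p$cost_effect[] <- 0
    p$hours_effect[] <- 0; p$food_effect[] <- 0
    p$missing_counts[] <- 0L
  } else if (scenario == "dominant_societal") {
    p$hours_effect[] <- 7
    p$food_effect[] <- 30
  }
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  p$scenario <- scenario

  stopifnot(p$n_control >= 1, p$n_intervention >= 1,
            p$utility_sd >= 0, p$hours_sd >= 0,
            p$utility_cor >= 0, p$utility_cor <= 1,
            all(p$resource_shares >= 0),
            abs(sum(p$resource_shares) - 1) < 1e-8,
            all(p$missing_counts >= 0),
            p$utility_mean > p$utility_bounds[1],
            p$utility_mean < p$utility_bounds[2])
  structure(p, class = "trial_params")
}

auc_weights <- function(timepoints) {
  t <- as.numeric(timepoints)
  k <- length(t)
  stopifnot(k >= 2)
  w <- numeric(k)
  w[1] <- (t[2] - t[1]) / 2
  w[k] <- (t[k] - t[k - 1]) / 2
  if (k > 2) w[2:(k - 1)] <- (t[3:k] - t[1:(k - 2)]) / 2
  w / (t[k] - t[1])
}

## expected hourly wage over the generator's covariate mix (integer ages,
## normal rounded then clamped inside the edge bands)
expected_hourly_wage <- function(params, wages) {
  t <- wages$table
  e <- 0
  for (s in c("female", "male")) {
    ps <- if (s == "female") params$p_female else 1 - params$p_female
    b <- t[t$sex == s, ]
    b <- b[order(b$age_low), ]
    lo <- stats::pnorm(b$age_low - 0.5, params$age_mean, params$age_sd)
    hi <- stats::pnorm(b$age_high + 0.5, params$age_mean, params$age_sd)
    pb <- hi - lo
    pb[1] <- hi[1]                      # clamped lower tail
    pb[length(pb)] <- 1 - lo[length(pb)]
    e <- e + ps * sum(pb * b$weekly_wage)
  }
  e / wages$standard_weekly_hours
}

#' Analytic ground truth implied by generator parameters
#'
#' Closed-form expected incremental QALY and cost, exactly as the generator
#' realises them: utility effects are evaluated through censored-normal
#' means (respecting the clamp at the value-set bounds, so slightly below
#' the naive AUC-weighted sum of effects when the ceiling binds), combined
#' with the trapezoid AUC weights; cost effects add the per-wave healthcare
#' savings to the intervention charge; productivity savings use the
#' censored-at-zero hours means, the employment rate and the expected
#' hourly wage; food savings use the expected per-person share
#' E[1/household size].
#'
#' @param params a [trial_params] object.
#' @param intervention_cost,period_weeks costing settings (defaults 1000, 13).
#' @param wages wage table used downstream (default [synthetic_wage_table()]).
#' @return Object of class `trial_truth`: list with `delta_effect`,
#'   `delta_cost` (named: nhs_pss, societal) and a `components` breakdown.
#' @export
trial_truth <- function(params, intervention_cost = 1000, period_weeks = 13,
                        wages = synthetic_wage_table()) {
  stopifnot(inherits(params, "trial_params"))
  a <- params$utility_bounds[1]; b <- params$utility_bounds[2]
  cal <- cnorm_calibrate(params$utility_mean, params$utility_sd, a, b)
  w <- auc_weights(params$timepoints)
  fw <- seq_along(params$timepoints)[-1]     # follow-up waves
  de <- 0
  for (j in seq_along(fw)) {
    mu <- cal$mu + params$utility_drift[j]
    de <- de + w[fw[j]] *
      (shifted_cnorm_mean(mu, cal$sigma, a, b, params$utility_effect[j]) -
         cnorm_mean(mu, cal$sigma, a, b))
  }

  dc_health <- sum(params$cost_effect)
  dc_nhs <- intervention_cost + dc_health

  hcal <- cnorm_calibrate(params$hours_mean, params$hours_sd, 0, 168)
  p_emp <- sum(params$employment_probs[c("full_time", "part_time")])
  ehw <- expected_hourly_wage(params, wages)
  dc_prod <- sum(vapply(seq_along(fw), function(j) {
    p_emp * ehw * period_weeks *
      (cnorm_mean(hcal$mu - params$hours_effect[j], hcal$sigma, 0, 168) -
         cnorm_mean(hcal$mu, hcal$sigma, 0, 168))
  }, numeric(1)))

  lam <- params$household_lambda
  e_inv_size <- if (lam > 0) (1 - exp(-lam)) / lam else 1
  dc_food <- sum(-params$food_effect) * e_inv_size * period_weeks

  structure(list(
    delta_effect = unname(de),
    delta_cost = c(nhs_pss = unname(dc_nhs),
                   societal = unname(dc_nhs + dc_prod + dc_food)),
    components = list(intervention = intervention_cost,
                      healthcare = dc_health, productivity = dc_prod,
                      food = dc_food,
                      naive_delta_effect = sum(w[fw] * params$utility_effect),
                      expected_hourly_wage = ehw,
                      employment_rate = p_emp),
    auc_weights = w), class = "trial_truth")
}

#' @export
print.trial_truth <- function(x, ...) {
  cat("Generator ground truth:\n",
      "  delta QALY (time-weighted mean scale): ",
      format(x$delta_effect, digits = 5), "\n",
      "  delta cost NHS/PSS:  GBP ", format(x$delta_cost[["nhs_pss"]]), "\n",
      "  delta cost societal: GBP ",
      format(round(x$delta_cost[["societal"]], 2)), "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic two-arm trial
#'
#' Complete-then-mask design: full outcomes for every participant and wave
#' are drawn first; the missing-at-random mask is applied second
#' (assessment-level, follow-up waves, exact per-arm counts, selection
#' probability logistic in baseline utility); ground truth is recorded from
#' the pre-mask population expectation via [trial_truth()]. Deterministic
#' under `seed`.
#'
#' @param params a [trial_params] object.
#' @param seed integer seed.
#' @param value_set value set used when `params$emit_eq5d` is `TRUE`
#'   (responses are emitted by nearest-utility state lookup).
#' @return List with elements `data` (a [trial_data]) and `truth`
#'   (a `trial_truth`).
#' @export
simulate_trial <- function(params = trial_params(), seed = 1L,
                           value_set = NULL) {
  stopifnot(inherits(params, "trial_params"))
  set.seed(as.integer(seed))
  n <- params$n_control + params$n_intervention
  arm <- rep(c("control", "intervention"),
             c(params$n_control, params$n_intervention))
  id <- sprintf("P%04d", seq_len(n))

  participants <- data.frame(
    participant_id = id,
    arm = arm,
    age = as.integer(clamp(round(stats::rnorm(n, params$age_mean,
                                              params$age_sd)),
                           params$age_range[1], params$age_range[2])),
    sex = ifelse(stats::runif(n) < params$p_female, "female", "male"),
    imd_quintile = sample(1:5, n, TRUE, params$imd_probs),
    ethnicity = sample(names(params$ethnicity_probs), n, TRUE,
                       params$ethnicity_probs),
    primary_symptom = sample(names(params$symptom_probs), n, TRUE,
                             params$symptom_probs),
    employment_status = sample(names(params$employment_probs), n, TRUE,
                               params$employment_probs),
    stringsAsFactors = FALSE)
  employed <- participants$employment_status %in% c("full_time", "part_time")
  ivn <- arm == "intervention"

  tp <- params$timepoints
  K <- length(tp)
  a <- params$utility_bounds[1]; bb <- params$utility_bounds[2]
  cal <- cnorm_calibrate(params$utility_mean, params$utility_sd, a, bb)
  sb <- sqrt(params$utility_cor) * cal$sigma
  se <- sqrt(1 - params$utility_cor) * cal$sigma
  bi <- stats::rnorm(n, 0, sb)
  drift <- c(0, params$utility_drift)
  effect <- c(0, params$utility_effect)
  # the arm effect shifts the censored control-scale utility and is then
  # re-clamped: participants at the ceiling cannot gain further, and the
  # implied mean effect stays in closed form (see trial_truth)
  U <- sapply(seq_len(K), function(k) {
    base <- clamp(cal$mu + drift[k] + bi + stats::rnorm(n, 0, se), a, bb)
    clamp(base + effect[k] * ivn, a, bb)
  })

  # healthcare counts: gamma frailty x Poisson per item, fresh per wave so
  # that the structural baseline arm imbalance cannot leak into the
  # adjusted follow-up contrast
  uc <- uk_unit_costs()$table
  items <- names(params$resource_shares)
  missing_items <- setdiff(items, uc$item)
  if (length(missing_items))
    stop("resource_shares name item(s) not in the unit-cost table: ",
         paste(missing_items, collapse = ", "))
  unit <- uc$unit_cost[match(items, uc$item)]
  k_sh <- params$cost_frailty_shape
  wave_mean <- function(k) {
    if (k == 1L) unname(params$baseline_cost_mean[arm])
    else params$followup_cost_mean + params$cost_effect[k - 1L] * ivn
  }
  RU <- vector("list", K)
  for (k in seq_len(K)) {
    g <- stats::rgamma(n, shape = k_sh, rate = k_sh)
    M <- wave_mean(k)
    cnt <- sapply(seq_along(items), function(j) {
      stats::rpois(n, g * M * params$resource_shares[j] / unit[j])
    })
    colnames(cnt) <- paste0("ru_", items)
    RU[[k]] <- cnt
  }

  med_shape <- (params$medication_mean / params$medication_sd)^2
  med_rate <- params$medication_mean / params$medication_sd^2
  MED <- matrix(stats::rgamma(n * K, med_shape, med_rate), n, K)

  hcal <- cnorm_calibrate(params$hours_mean, params$hours_sd, 0, 168)
  heff <- c(0, params$hours_effect)
  H <- sapply(seq_len(K), function(k) {
    h <- clamp(stats::rnorm(n, hcal$mu - heff[k] * ivn, hcal$sigma), 0, 168)
    ifelse(employed, h, 0)
  })

  f_sd <- params$food_weekly_sd
  feff <- c(0, params$food_effect)
  FC <- sapply(seq_len(K), function(k) {
    m <- pmax(params$food_weekly_mean - feff[k] * ivn, 1)
    stats::rgamma(n, shape = (m / f_sd)^2, rate = m / f_sd^2)
  })
  hh <- 1L + stats::rpois(n, params$household_lambda)

  rows <- vector("list", K)
  for (k in seq_len(K)) {
    df <- data.frame(participant_id = id, timepoint_months = tp[k],
                     utility = U[, k], stringsAsFactors = FALSE)
    if (isTRUE(params$emit_eq5d)) {
      vs <- value_set %||% synthetic_value_set()
      idx <- vapply(U[, k], function(u) which.min(abs(vs$mapping - u)),
                    integer(1))
      st <- names(vs$mapping)[idx]
      lev <- do.call(rbind, lapply(strsplit(st, ""), as.integer))
      colnames(lev) <- eq5d_columns()
      df <- cbind(df, lev)
      df$utility <- unname(vs$mapping[idx])   # keep responses and utility coherent
    }
    df <- cbind(df, RU[[k]])
    df$medication_cost <- MED[, k]
    df$hours_missed_7d <- H[, k]
    df$food_cost_7d <- FC[, k]
    df$household_size <- hh
    rows[[k]] <- df
  }
  assessments <- do.call(rbind, rows)

  # MAR mask: exact per-arm counts over follow-up assessment cells, drawn
  # with probability increasing in (mar_slope-signed) baseline utility
  u0 <- U[, 1]
  mask_cols <- setdiff(names(assessments),
                       c("participant_id", "timepoint_months", "household_size"))
  for (whicharm in c("control", "intervention")) {
    cnt <- params$missing_counts[[whicharm]]
    if (cnt == 0) next
    pid <- id[arm == whicharm]
    cells <- expand.grid(participant_id = pid, timepoint_months = tp[-1],
                         stringsAsFactors = FALSE)
    if (cnt > nrow(cells))
      stop("missing_counts exceed available follow-up cells for ", whicharm)
    wgt <- stats::plogis(params$mar_slope *
                           (u0[match(cells$participant_id, id)] -
                              params$utility_mean))
    pick <- sample.int(nrow(cells), cnt, prob = wgt)
    sel <- match(paste(cells$participant_id[pick],
                       cells$timepoint_months[pick]),
                 paste(assessments$participant_id,
                       assessments$timepoint_months))
    assessments[sel, mask_cols] <- NA
  }

  dat <- trial_data(participants, assessments, timepoints = tp,
                    currency_year = 2022L)
  list(data = dat, truth = trial_truth(params), params = params,
       seed = as.integer(seed))
}
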