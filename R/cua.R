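#' Within-trial cost-utility analysis
#'
#' Runs the full estimation chain on a trial dataset: EQ-5D mapping (when
#' responses are supplied), per-wave costing under NHS/PSS and societal
#' perspectives, multiple imputation by chained equations separately by
#' arm, AUC QALY and total-cost construction on each completed dataset,
#' seemingly-unrelated-regression estimation of the adjusted incremental
#' cost and QALY, nonparametric bootstrap nested within each imputation,
#' Rubin's-rules pooling, and decision outputs (ICER, INMB, CEAC, plane).
#'
#' Cost totals cover the trial period (the two follow-up recall windows)
#' plus the one-off intervention charge; baseline-window costs and baseline
#' utility enter as regression adjusters, not as outcome components (set
#' `include_baseline_in_total = TRUE` to add the baseline window to the
#' outcome as well). QALYs are on the time-weighted-mean (annualised
#' utility) scale; multiply by the horizon in years for literal QALYs.
#'
#' @param data a [trial_data] object.
#' @param unit_costs a [unit_cost_table] (default the packaged 2022 table).
#' @param wages a [wage_table] (default the packaged synthetic table).
#' @param value_set a `value_set`, needed only when EQ-5D responses must be
#'   mapped (default [synthetic_value_set()] when required).
#' @param intervention_cost one-off charge per intervention participant
#'   (default 1000).
#' @param period_weeks recall extrapolation factor (default 13).
#' @param m,maxit,donors imputation settings (defaults 10, 10, 5).
#' @param B bootstrap replicates per imputation (default 5000).
#' @param seed master seed for imputation and bootstrap.
#' @param lambda_grid CEAC thresholds (default 0 to 50,000 step 500).
#' @param headline_lambda thresholds for headline INMB/CEAC readouts
#'   (default 20,000 and 30,000).
#' @param perspectives subset of `c("nhs_pss", "societal")`.
#' @param include_baseline_in_total include the baseline recall window in
#'   the cost outcome (default FALSE).
#' @param stratify_by_arm stratified bootstrap resampling (default TRUE).
#' @return Object of class `cua`; see [print.cua()], [summary.cua()],
#'   [coef.cua()], [plot.cua()].
#' @export
cua <- function(data,
                unit_costs = uk_unit_costs(),
                wages = synthetic_wage_table(),
                value_set = NULL,
                intervention_cost = 1000,
                period_weeks = 13,
                m = 10L, maxit = 10L, donors = 5L,
                B = 5000L, seed = 1L,
                lambda_grid = seq(0, 50000, by = 500),
                headline_lambda = c(20000, 30000),
                perspectives = c("nhs_pss", "societal"),
                include_baseline_in_total = FALSE,
                stratify_by_arm = TRUE) {
  stopifnot(inherits(data, "trial_data"))
  perspectives <- match.arg(perspectives, several.ok = TRUE)

  data <- ensure_utilities(data, value_set)
  breakdown <- assemble_costs(data, unit_costs, wages,
                              intervention_cost = intervention_cost,
                              period_weeks = period_weeks)
  tab <- build_analysis_table(data, breakdown)
  missingness <- missingness_summary(data, "utility")

  wave_vars <- attr(tab, "wave_vars")
  mi <- impute_mice(tab, variables = wave_vars,
                    predictors = c("age", "sex", "imd_quintile",
                                   "primary_symptom"),
                    by = "arm", m = m, maxit = maxit, donors = donors,
                    seed = substream_seed(seed, "impute"))

  completed <- lapply(mi$imputations, function(d)
    derive_outcomes(d, data$timepoints, intervention_cost,
                    include_baseline_in_total))

  base_rhs <- "arm + age + sex + imd_quintile + primary_symptom"
  results <- list()
  for (persp in perspectives) {
    costvar <- paste0("total_", persp)
    blvar <- paste0("baseline_cost_", persp)
    formulas <- list(
      cost = stats::as.formula(paste(costvar, "~", base_rhs, "+", blvar)),
      effect = stats::as.formula(paste("qaly ~", base_rhs,
                                       "+ baseline_utility")))
    fits <- lapply(completed, sur_fit, formulas = formulas)
    est <- t(vapply(fits, function(f)
      c(delta_cost = f$coefficients$cost[["armintervention"]],
        delta_effect = f$coefficients$effect[["armintervention"]]),
      numeric(2)))
    cloud <- bootstrap_cloud(completed, formulas, B = B, seed = seed,
                             stratify = if (stratify_by_arm) "arm" else NULL)
    wcov <- cloud_within_cov(cloud)
    df_com <- nrow(completed[[1]]) -
      length(attr(stats::terms(formulas$effect), "term.labels")) - 1
    pooled <- rubin_pool(est, within_cov = wcov, df_com = df_com)

    pci <- apply(as.matrix(cloud[c("delta_cost", "delta_effect")]), 2,
                 stats::quantile, probs = c(0.025, 0.975))
    results[[persp]] <- list(
      pooled = pooled,
      percentile_ci = t(pci),
      icer = icer(pooled$point[["delta_cost"]],
                  pooled$point[["delta_effect"]]),
      inmb = inmb_with_ci(pooled, headline_lambda),
      ceac = ceac(cloud, lambda_grid),
      plane = plane_export(cloud, max(headline_lambda)),
      cloud = cloud,
      formulas = formulas,
      fits = fits)
  }

  structure(list(results = results, missingness = missingness,
                 perspectives = perspectives,
                 settings = list(m = m, maxit = maxit, donors = donors,
                                 B = B, seed = seed,
                                 intervention_cost = intervention_cost,
                                 period_weeks = period_weeks,
                                 lambda_grid = lambda_grid,
                                 headline_lambda = headline_lambda,
                                 include_baseline_in_total =
                                   include_baseline_in_total,
                                 currency_year = data$currency_year),
                 n = nrow(data$participants),
                 call = match.call()),
            class = "cua")
}

## map EQ-5D responses to utilities where needed; responses take precedence
## over a supplied utility column (with a warning) when both are present
ensure_utilities <- function(data, value_set = NULL) {
  a <- data$assessments
  eq <- eq5d_columns()
  have_eq <- all(eq %in% names(a))
  if (!have_eq) {
    if (!"utility" %in% names(a))
      stop("dataset has neither a utility column nor EQ-5D response columns")
    return(data)
  }
  vs <- value_set %||% synthetic_value_set()
  resp <- as.matrix(a[eq])
  complete <- stats::complete.cases(resp)
  mapped <- rep(NA_real_, nrow(a))
  if (any(complete))
    mapped[complete] <- map_eq5d_to_utility(resp[complete, , drop = FALSE], vs)
  if ("utility" %in% names(a)) {
    conflict <- complete & !is.na(a$utility) &
      abs(a$utility - mapped) > 1e-12
    if (any(conflict))
      warning(sum(conflict), " assessment(s) had both EQ-5D responses and a ",
              "utility value; responses take precedence")
    a$utility <- ifelse(complete, mapped, a$utility)
  } else {
    a$utility <- mapped
  }
  data$assessments <- a
  data
}

## wide analysis table: one row per participant, per-wave component columns
build_analysis_table <- function(data, breakdown) {
  p <- data$participants
  tp <- data$timepoints
  bkey <- paste(breakdown$participant_id, breakdown$timepoint_months)
  akey <- paste(data$assessments$participant_id,
                data$assessments$timepoint_months)
  tab <- data.frame(participant_id = p$participant_id,
                    arm = factor(p$arm, c("control", "intervention")),
                    age = p$age,
                    sex = factor(p$sex, c("female", "male")),
                    imd_quintile = factor(p$imd_quintile, 1:5),
                    primary_symptom = factor(p$primary_symptom),
                    stringsAsFactors = FALSE)
  wave_vars <- character()
  for (k in seq_along(tp)) {
    sfx <- paste0("_", tp[k])
    rowb <- match(paste(p$participant_id, tp[k]), bkey)
    rowa <- match(paste(p$participant_id, tp[k]), akey)
    tab[[paste0("u", sfx)]] <- data$assessments$utility[rowa]
    tab[[paste0("hc", sfx)]] <- breakdown$healthcare_cost[rowb]
    tab[[paste0("med", sfx)]] <- breakdown$medication_cost[rowb]
    tab[[paste0("prod", sfx)]] <- breakdown$productivity_cost[rowb]
    tab[[paste0("food", sfx)]] <- breakdown$food_cost[rowb]
    wave_vars <- c(wave_vars, paste0(c("u", "hc", "med", "prod", "food"), sfx))
  }
  attr(tab, "wave_vars") <- wave_vars
  attr(tab, "timepoints") <- tp
  tab
}

## QALY and perspective totals from a completed (imputed) analysis table
derive_outcomes <- function(d, timepoints, intervention_cost,
                            include_baseline_in_total = FALSE) {
  w <- auc_weights(timepoints)
  ucols <- paste0("u_", timepoints)
  d$qaly <- drop(as.matrix(d[ucols]) %*% w)
  fu <- timepoints[-1]
  sum_waves <- function(prefixes, waves) {
    cols <- as.vector(outer(prefixes, waves, function(p, t)
      paste0(p, "_", t)))
    rowSums(as.matrix(d[cols]))
  }
  iv <- ifelse(d$arm == "intervention", intervention_cost, 0)
  waves_nhs <- if (include_baseline_in_total) timepoints else fu
  d$total_nhs_pss <- iv + sum_waves(c("hc", "med"), waves_nhs)
  d$total_societal <- d$total_nhs_pss +
    sum_waves(c("prod", "food"), waves_nhs)
  t0 <- timepoints[1]
  d$baseline_utility <- d[[paste0("u_", t0)]]
  d$baseline_cost_nhs_pss <- d[[paste0("hc_", t0)]] + d[[paste0("med_", t0)]]
  d$baseline_cost_societal <- d$baseline_cost_nhs_pss +
    d[[paste0("prod_", t0)]] + d[[paste0("food_", t0)]]
  d
}

## INMB point, CI and significance from the pooled bivariate estimate
inmb_with_ci <- function(pooled, lambdas, level = 0.95) {
  dc <- pooled$point[["delta_cost"]]
  de <- pooled$point[["delta_effect"]]
  cv <- pooled$cov
  df <- min(pooled$df)
  out <- lapply(lambdas, function(l) {
    point <- inmb(dc, de, l)
    v <- l^2 * cv["delta_effect", "delta_effect"] +
      cv["delta_cost", "delta_cost"] -
      2 * l * cv["delta_cost", "delta_effect"]
    q <- stats::qt(1 - (1 - level) / 2, df)
    c(lambda = l, inmb = point, lower = point - q * sqrt(v),
      upper = point + q * sqrt(v))
  })
  as.data.frame(do.call(rbind, out))
}

#' @export
print.cua <- function(x, ...) {
  cat("Within-trial cost-utility analysis (n = ", x$n, ", m = ",
      x$settings$m, " imputations, B = ", x$settings$B,
      " bootstrap replicates)\n", sep = "")
  for (persp in x$perspectives) {
    r <- x$results[[persp]]
    p <- r$pooled
    lab <- if (persp == "nhs_pss") "NHS/PSS" else "Societal"
    cat("\n", lab, " perspective:\n", sep = "")
    cat(sprintf("  QALY difference: %.7f (95%% CI %.7f to %.7f)\n",
                p$point[["delta_effect"]], p$ci["delta_effect", 1],
                p$ci["delta_effect", 2]))
    cat(sprintf("  Cost difference: %.2f (95%% CI %.2f to %.2f)\n",
                p$point[["delta_cost"]], p$ci["delta_cost", 1],
                p$ci["delta_cost", 2]))
    ic <- r$icer
    ictxt <- switch(ic$label,
                    value = paste0("GBP ",
                                   formatC(round(ic$ratio), big.mark = ",",
                                           format = "d"), "/QALY"),
                    dominant = "Dominant", dominated = "Dominated",
                    undefined = "Undefined")
    cat("  ICER: ", ictxt, "\n", sep = "")
    for (i in seq_len(nrow(r$inmb))) {
      row <- r$inmb[i, ]
      cat(sprintf("  INMB at GBP %s/QALY: %d\n",
                  formatC(row$lambda, big.mark = ",", format = "d"),
                  round(row$inmb)))
    }
    hl <- x$settings$headline_lambda
    pr <- r$ceac$probability[match(hl, r$ceac$lambda)]
    ok <- !is.na(pr)
    if (any(ok))
      cat("  P(cost-effective): ",
          paste(sprintf("%.0f%% at GBP %s", 100 * pr[ok],
                        formatC(hl[ok], big.mark = ",", format = "d")),
                collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.cua <- function(object, ...) {
  out <- list(n = object$n, settings = object$settings,
              missingness = object$missingness,
              perspectives = object$perspectives)
  out$table <- do.call(rbind, lapply(object$perspectives, function(persp) {
    r <- object$results[[persp]]
    data.frame(perspective = persp,
               delta_cost = r$pooled$point[["delta_cost"]],
               dc_lower = r$pooled$ci["delta_cost", 1],
               dc_upper = r$pooled$ci["delta_cost", 2],
               delta_effect = r$pooled$point[["delta_effect"]],
               de_lower = r$pooled$ci["delta_effect", 1],
               de_upper = r$pooled$ci["delta_effect", 2],
               icer = if (r$icer$label == "value") r$icer$ratio else NA,
               icer_label = r$icer$label,
               prob_cost_saving = r$ceac$probability[r$ceac$lambda == 0],
               row.names = NULL)
  }))
  out$quadrant_shares <- lapply(object$results, function(r)
    r$plane$quadrant_shares)
  class(out) <- "summary.cua"
  out
}

#' @export
print.summary.cua <- function(x, ...) {
  cat("Within-trial cost-utility analysis, n =", x$n, "\n\n")
  print(x$table, row.names = FALSE, digits = 6)
  cat("\nBootstrap cloud quadrant shares (NE dearer/more effective, SE dominant):\n")
  for (p in names(x$quadrant_shares)) {
    cat("  ", p, ": ", paste(names(x$quadrant_shares[[p]]),
                             sprintf("%.2f", x$quadrant_shares[[p]]),
                             collapse = ", "), "\n", sep = "")
  }
  cat("\n")
  print(x$missingness)
  invisible(x)
}

#' @export
coef.cua <- function(object, ...) {
  unlist(lapply(object$perspectives, function(p) {
    r <- object$results[[p]]
    stats::setNames(r$pooled$point[c("delta_cost", "delta_effect")],
                    paste0(c("delta_cost_", "delta_effect_"), p))
  }))
}

#' @export
confint.cua <- function(object, parm, level = 0.95, ...) {
  out <- do.call(rbind, lapply(object$perspectives, function(p) {
    ci <- object$results[[p]]$pooled$ci
    rownames(ci) <- paste0(rownames(ci), "_", p)
    ci
  }))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Write a cost-utility summary to JSON
#'
#' Machine-readable summary per perspective: pooled incremental cost and
#' QALY with Rubin's-rules and percentile CIs, ICER (ratio and label),
#' INMB at the headline thresholds, headline CEAC points, and quadrant
#' shares. Values are written unrounded.
#'
#' @param fit a `cua` object.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_cua_summary <- function(fit, path) {
  stopifnot(inherits(fit, "cua"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for JSON output")
  hl <- fit$settings$headline_lambda
  out <- lapply(fit$results, function(r) {
    list(delta_cost = unname(r$pooled$point[["delta_cost"]]),
         delta_cost_ci = unname(r$pooled$ci["delta_cost", ]),
         delta_effect = unname(r$pooled$point[["delta_effect"]]),
         delta_effect_ci = unname(r$pooled$ci["delta_effect", ]),
         percentile_ci = list(
           delta_cost = unname(r$percentile_ci["delta_cost", ]),
           delta_effect = unname(r$percentile_ci["delta_effect", ])),
         icer = list(ratio = r$icer$ratio, label = r$icer$label,
                     quadrant = r$icer$quadrant),
         inmb = r$inmb,
         ceac_headline = r$ceac[r$ceac$lambda %in% c(0, hl), ],
         quadrant_shares = as.list(r$plane$quadrant_shares))
  })
  out$settings <- fit$settings[c("m", "B", "seed", "intervention_cost",
                                 "period_weeks", "currency_year")]
  out$n <- fit$n
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Plot cost-effectiveness plane or acceptability curve
#'
#' @param x a `cua` object.
#' @param type `"plane"` or `"ceac"`.
#' @param perspective which perspective to plot (default the first fitted).
#' @param lambda threshold line drawn on the plane (default 30000).
#' @param ... passed to the underlying plot call.
#' @return `x`, invisibly.
#' @export
plot.cua <- function(x, type = c("plane", "ceac"),
                     perspective = x$perspectives[1], lambda = 30000, ...) {
  type <- match.arg(type)
  r <- x$results[[perspective]]
  if (is.null(r)) stop("perspective '", perspective, "' was not fitted")
  lab <- if (perspective == "nhs_pss") "NHS/PSS" else "Societal"
  if (type == "plane") {
    pts <- r$plane$points
    graphics::plot(pts$delta_effect, pts$delta_cost,
                   pch = 16, cex = 0.3,
                   col = grDevices::adjustcolor("steelblue", 0.3),
                   xlab = "Incremental QALYs",
                   ylab = "Incremental cost (GBP)",
                   main = paste("Cost-effectiveness plane,", lab), ...)
    graphics::abline(h = 0, v = 0, col = "grey50")
    graphics::abline(a = 0, b = lambda, lty = 2)
    graphics::points(r$pooled$point[["delta_effect"]],
                     r$pooled$point[["delta_cost"]],
                     pch = 3, cex = 1.5, lwd = 2, col = "red")
  } else {
    graphics::plot(r$ceac$lambda, r$ceac$probability, type = "l", lwd = 2,
                   ylim = c(0, 1),
                   xlab = "Willingness to pay (GBP/QALY)",
                   ylab = "P(cost-effective)",
                   main = paste("CEAC,", lab), ...)
    graphics::abline(h = c(0, 0.5, 1), col = "grey80", lty = 3)
  }
  invisible(x)
}
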