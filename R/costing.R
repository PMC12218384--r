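#' Unit-cost table
#'
#' @param table data.frame with columns `item` (unique), `unit_cost`
#'   (GBP per unit, >= 0) and optionally `label`, `source`.
#' @param currency_year integer year the costs are expressed in.
#' @return An object of class `unit_cost_table`.
#' @export
unit_cost_table <- function(table, currency_year = 2022L) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (!all(c("item", "unit_cost") %in% names(table)))
    stop("unit-cost table needs columns 'item' and 'unit_cost'")
  if (anyDuplicated(table$item))
    stop("duplicate item(s): ",
         paste(unique(table$item[duplicated(table$item)]), collapse = ", "))
  if (any(!is.finite(table$unit_cost)) || any(table$unit_cost < 0))
    stop("unit costs must be finite and nonnegative")
  structure(list(table = table, currency_year = as.integer(currency_year)),
            class = "unit_cost_table")
}

#' Packaged 2022 NHS/PSS unit costs
#'
#' The healthcare unit costs used throughout (GP visit GBP 42 through
#' outpatient appointment GBP 165), with sources (PSSRU, NHS reference
#' costs, Scottish Health Service costs, literature). 2022 GBP.
#'
#' @return A [unit_cost_table].
#' @export
uk_unit_costs <- function() {
  path <- system.file("extdata", "unit_costs_2022.csv", package = "trialcua",
                      mustWork = TRUE)
  unit_cost_table(utils::read.csv(path, stringsAsFactors = FALSE), 2022L)
}

#' @export
print.unit_cost_table <- function(x, ...) {
  cat("Unit-cost table (", x$currency_year, " GBP), ",
      nrow(x$table), " items\n", sep = "")
  print(x$table[setdiff(names(x$table), "source")], row.names = FALSE)
  invisible(x)
}

#' Age- and sex-specific weekly wage table
#'
#' @param table data.frame with columns `sex`, `age_low`, `age_high`,
#'   `weekly_wage`. Age bands must not overlap within sex.
#' @param standard_weekly_hours hours a full working week represents;
#'   converts weekly wages to hourly rates (default 37.5).
#' @return An object of class `wage_table`.
#' @export
wage_table <- function(table, standard_weekly_hours = 37.5) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  req <- c("sex", "age_low", "age_high", "weekly_wage")
  if (!all(req %in% names(table)))
    stop("wage table needs columns: ", paste(req, collapse = ", "))
  if (any(table$weekly_wage < 0)) stop("wages must be nonnegative")
  for (s in unique(table$sex)) {
    b <- table[table$sex == s, ]
    b <- b[order(b$age_low), ]
    if (any(b$age_low[-1] <= b$age_high[-nrow(b)]))
      stop("overlapping age bands for sex '", s, "'")
  }
  structure(list(table = table,
                 standard_weekly_hours = standard_weekly_hours),
            class = "wage_table")
}

#' Packaged synthetic 2022 wage table
#'
#' Age- and sex-banded average weekly wages of plausible 2022 UK magnitude.
#' These are synthetic placeholder values (the national statistics tables
#' are data, not code); substitute the real ONS figures via [wage_table()]
#' for real analyses.
#'
#' @inheritParams wage_table
#' @return A [wage_table].
#' @export
synthetic_wage_table <- function(standard_weekly_hours = 37.5) {
  path <- system.file("extdata", "wages_synthetic_2022.csv",
                      package = "trialcua", mustWork = TRUE)
  wage_table(utils::read.csv(path, stringsAsFactors = FALSE),
             standard_weekly_hours)
}

weekly_wage_lookup <- function(wages, age, sex) {
  t <- wages$table
  idx <- mapply(function(a, s) {
    i <- which(t$sex == s & t$age_low <= a & a <= t$age_high)
    if (length(i) != 1L) NA_integer_ else i
  }, age, sex)
  if (anyNA(idx))
    stop("age/sex outside wage-table coverage: ",
         paste(utils::head(paste0(sex[is.na(idx)], " ", age[is.na(idx)]), 5),
               collapse = ", "))
  t$weekly_wage[idx]
}

#' Cost a resource-use profile
#'
#' Sum of count x unit cost over items. In strict mode an item with a
#' positive count that is absent from the table is an error; in permissive
#' mode unmatched items are skipped and returned in an attribute.
#'
#' @param resource_use named numeric vector (or 1-row data.frame) of counts,
#'   names matching `item` in the table (a leading `ru_` prefix is
#'   stripped).
#' @param costs a [unit_cost_table].
#' @param strict error on unmatched items (default TRUE).
#' @return Total cost in GBP; permissive mode attaches attribute
#'   `unmatched`.
#' @export
cost_resource_use <- function(resource_use, costs, strict = TRUE) {
  stopifnot(inherits(costs, "unit_cost_table"))
  if (is.data.frame(resource_use)) resource_use <- unlist(resource_use[1, ])
  items <- sub("^ru_", "", names(resource_use))
  counts <- as.numeric(resource_use)
  if (length(counts) == 0) return(0)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  pos <- which(!is.na(counts) & counts > 0)
  unmatched <- setdiff(items[pos], costs$table$item)
  if (length(unmatched) && strict)
    stop("resource item(s) not in unit-cost table: ",
         paste(unmatched, collapse = ", "))
  keep <- !is.na(counts) & items %in% costs$table$item
  total <- sum(counts[keep] *
                 costs$table$unit_cost[match(items[keep], costs$table$item)])
  if (!strict && length(unmatched)) attr(total, "unmatched") <- unmatched
  total
}

#' Productivity cost by the human-capital method
#'
#' Hours of work missed in a 7-day recall, valued at the age- and
#' sex-specific hourly wage (weekly wage / standard weekly hours) and
#' extrapolated over the recall-covered period.
#'
#' @param hours_missed_7d hours missed in the preceding 7 days (0-168).
#' @param age,sex participant covariates for the wage lookup (vectorised).
#' @param wages a [wage_table].
#' @param period_weeks weeks the 7-day recall is extrapolated over
#'   (default 13, i.e. a 3-month assessment interval).
#' @return Cost in GBP (vectorised over participants).
#' @export
productivity_cost <- function(hours_missed_7d, age, sex, wages,
                              period_weeks = 13) {
  stopifnot(inherits(wages, "wage_table"))
  if (any(hours_missed_7d < 0 | hours_missed_7d > 168, na.rm = TRUE))
    stop("hours_missed_7d must be within [0, 168]")
  hourly <- weekly_wage_lookup(wages, age, sex) / wages$standard_weekly_hours
  hours_missed_7d * hourly * period_weeks
}

#' Per-person food cost
#'
#' Weekly household food expenditure divided by household size, extrapolated
#' over the assessment period. A missing or zero household size is an
#' error, never a silent divide-by-one.
#'
#' @param weekly_household_cost GBP per week for the household.
#' @param household_size integer >= 1.
#' @param period_weeks extrapolation factor (default 13).
#' @return Per-person cost in GBP (vectorised).
#' @export
food_cost <- function(weekly_household_cost, household_size, period_weeks = 13) {
  bad <- !is.na(weekly_household_cost) &
    (is.na(household_size) | household_size < 1)
  if (any(bad))
    stop("household_size missing or < 1 where food cost is observed")
  (weekly_household_cost / household_size) * period_weeks
}

#' Assemble per-participant, per-timepoint cost breakdowns
#'
#' Converts each assessment's resource-use counts, medication cost, work
#' loss and food recall into period costs. The intervention charge is
#' applied once (at baseline) to intervention-arm participants. Missing
#' component inputs propagate as `NA` (for downstream imputation), never as
#' zero; participants not in employment contribute a zero (not missing)
#' productivity cost.
#'
#' Perspective totals: `nhs_pss_total = healthcare + medication +
#' intervention`; `societal_total = nhs_pss_total + productivity + food`.
#'
#' @param data a [trial_data] object.
#' @param costs a [unit_cost_table]; its `currency_year` must equal the
#'   dataset's.
#' @param wages a [wage_table].
#' @param intervention_cost GBP charged once per intervention-arm
#'   participant (default 1000).
#' @param period_weeks recall extrapolation factor (default 13).
#' @param employed_statuses employment_status values treated as employed for
#'   productivity costing (default full/part time).
#' @return data.frame of class `cost_breakdown`: one row per participant x
#'   timepoint with component costs and perspective totals.
#' @export
assemble_costs <- function(data, costs = uk_unit_costs(),
                           wages = synthetic_wage_table(),
                           intervention_cost = 1000,
                           period_weeks = 13,
                           employed_statuses = c("full_time", "part_time")) {
  stopifnot(inherits(data, "trial_data"), inherits(costs, "unit_cost_table"),
            inherits(wages, "wage_table"))
  if (costs$currency_year != data$currency_year)
    stop("currency-year mismatch: unit costs are ", costs$currency_year,
         ", dataset is ", data$currency_year)
  p <- data$participants
  a <- data$assessments
  ru_cols <- grep("^ru_", names(a), value = TRUE)
  pi <- match(a$participant_id, p$participant_id)

  # healthcare: NA if the whole resource-use block is missing for that row
  hc <- vapply(seq_len(nrow(a)), function(i) {
    cnt <- unlist(a[i, ru_cols, drop = FALSE])
    if (length(cnt) == 0 || all(is.na(cnt))) return(NA_real_)
    cost_resource_use(cnt[!is.na(cnt)], costs)
  }, numeric(1))

  med <- if ("medication_cost" %in% names(a)) a$medication_cost else
    rep(0, nrow(a))
  iv <- ifelse(p$arm[pi] == "intervention" & a$timepoint_months == data$timepoints[1],
               intervention_cost, 0)

  employed <- p$employment_status[pi] %in% employed_statuses
  prod <- rep(NA_real_, nrow(a))
  if ("hours_missed_7d" %in% names(a)) {
    obs <- !is.na(a$hours_missed_7d)
    prod[obs] <- productivity_cost(a$hours_missed_7d[obs], p$age[pi][obs],
                                   p$sex[pi][obs], wages, period_weeks)
  }
  prod[!employed] <- 0  # WPAI absenteeism applies to workers only

  food <- rep(NA_real_, nrow(a))
  if (all(c("food_cost_7d", "household_size") %in% names(a))) {
    obs <- !is.na(a$food_cost_7d)
    food[obs] <- food_cost(a$food_cost_7d[obs], a$household_size[obs],
                           period_weeks)
  }

  out <- data.frame(
    participant_id = a$participant_id,
    arm = p$arm[pi],
    timepoint_months = a$timepoint_months,
    healthcare_cost = hc,
    medication_cost = med,
    intervention_cost = iv,
    productivity_cost = prod,
    food_cost = food,
    row.names = NULL)
  out$nhs_pss_total <- out$healthcare_cost + out$medication_cost +
    out$intervention_cost
  out$societal_total <- out$nhs_pss_total + out$productivity_cost +
    out$food_cost
  attr(out, "currency_year") <- costs$currency_year
  attr(out, "period_weeks") <- period_weeks
  class(out) <- c("cost_breakdown", "data.frame")
  out
}
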