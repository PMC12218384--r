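#' Trial dataset container
#'
#' Participant-level data for a two-arm trial with repeated assessments.
#' `participants` holds one row per participant (randomisation covariates);
#' `assessments` one row per participant x timepoint with EQ-5D responses
#' and/or utility, resource-use counts (columns prefixed `ru_`), 7-day work
#' loss and food-cost recall, and pre-priced medication cost. Empty cells in
#' the source CSV become `NA` (missing), never zero: zeros are always data.
#'
#' @param participants data.frame with columns `participant_id`, `arm`
#'   (`"control"`/`"intervention"`), `age`, `sex` (`"female"`/`"male"`),
#'   `imd_quintile` (1-5), `ethnicity`, `primary_symptom`,
#'   `employment_status`.
#' @param assessments data.frame with columns `participant_id`,
#'   `timepoint_months`, and any of `eq5d_mo`, `eq5d_sc`, `eq5d_ua`,
#'   `eq5d_pd`, `eq5d_ad`, `utility`, `hours_missed_7d`, `food_cost_7d`,
#'   `household_size`, `medication_cost`, plus one `ru_<item>` count column
#'   per resource item.
#' @param timepoints ordered numeric vector of scheduled month offsets
#'   (default `c(0, 3, 6)`).
#' @param currency_year integer year costs are expressed in (default 2022).
#' @return An object of class `trial_data`.
#' @export
trial_data <- function(participants, assessments,
                       timepoints = c(0, 3, 6), currency_year = 2022L) {
  participants <- as.data.frame(participants, stringsAsFactors = FALSE)
  assessments <- as.data.frame(assessments, stringsAsFactors = FALSE)

  req_p <- c("participant_id", "arm", "age", "sex", "imd_quintile",
             "ethnicity", "primary_symptom", "employment_status")
  miss <- setdiff(req_p, names(participants))
  if (length(miss))
    stop("participants is missing required column(s): ",
         paste(miss, collapse = ", "))
  req_a <- c("participant_id", "timepoint_months")
  miss <- setdiff(req_a, names(assessments))
  if (length(miss))
    stop("assessments is missing required column(s): ",
         paste(miss, collapse = ", "))

  participants$participant_id <- as.character(participants$participant_id)
  assessments$participant_id <- as.character(assessments$participant_id)

  if (anyDuplicated(participants$participant_id))
    stop("duplicate participant_id in participants")

  # randomisation covariates must be non-missing
  for (v in c("arm", "age", "sex", "imd_quintile", "primary_symptom")) {
    if (anyNA(participants[[v]]))
      stop("randomisation covariate '", v, "' contains missing values")
  }
  if (!all(participants$arm %in% c("control", "intervention")))
    stop("arm must be 'control' or 'intervention'")
  if (!all(participants$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'")
  if (any(participants$age < 18))
    stop("age must be >= 18 (adult trial population)")
  if (!all(participants$imd_quintile %in% 1:5))
    stop("imd_quintile must be an integer in 1..5")
  sym <- c("pain", "breathlessness", "fatigue", "anxiety_depression", "other")
  if (!all(participants$primary_symptom %in% sym))
    stop("primary_symptom must be one of: ", paste(sym, collapse = ", "))

  unknown <- setdiff(assessments$participant_id, participants$participant_id)
  if (length(unknown))
    stop("assessments reference unknown participant(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  key <- paste(assessments$participant_id, assessments$timepoint_months)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (participant, timepoint) record: ", d)
  }
  if (!all(assessments$timepoint_months %in% timepoints))
    stop("assessments contain timepoint_months outside the schedule (",
         paste(timepoints, collapse = ", "), ")")

  eq_cols <- eq5d_columns()
  have_eq <- eq_cols[eq_cols %in% names(assessments)]
  for (v in have_eq) {
    bad <- which(!is.na(assessments[[v]]) & !(assessments[[v]] %in% 1:5))
    if (length(bad))
      stop("EQ-5D level out of range 1..5 in column '", v,
           "', assessment row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if ("utility" %in% names(assessments)) {
    bad <- which(!is.na(assessments$utility) &
                   (assessments$utility < -0.594 | assessments$utility > 1))
    if (length(bad))
      stop("utility outside [-0.594, 1] in assessment row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  for (v in grep("^ru_", names(assessments), value = TRUE)) {
    x <- assessments[[v]]
    bad <- which(!is.na(x) & (x < 0 | x != round(x)))
    if (length(bad))
      stop("resource-use counts must be nonnegative integers; column '", v,
           "', row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if ("hours_missed_7d" %in% names(assessments)) {
    x <- assessments$hours_missed_7d
    bad <- which(!is.na(x) & (x < 0 | x > 168))
    if (length(bad))
      stop("hours_missed_7d outside [0, 168] in row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  for (v in intersect(c("food_cost_7d", "medication_cost"), names(assessments))) {
    bad <- which(!is.na(assessments[[v]]) & assessments[[v]] < 0)
    if (length(bad))
      stop("'", v, "' must be nonnegative; row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  if ("household_size" %in% names(assessments)) {
    x <- assessments$household_size
    bad <- which(!is.na(x) & (x < 1 | x != round(x)))
    if (length(bad))
      stop("household_size must be an integer >= 1; row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
  }

  # canonical order: participants as given; assessments by participant,
  # then timepoint (round-trips and reports are order-invariant)
  rownames(participants) <- NULL
  ord <- order(match(assessments$participant_id, participants$participant_id),
               assessments$timepoint_months)
  assessments <- assessments[ord, , drop = FALSE]
  rownames(assessments) <- NULL

  structure(
    list(participants = participants,
         assessments = assessments,
         timepoints = as.numeric(timepoints),
         currency_year = as.integer(currency_year)),
    class = "trial_data")
}

eq5d_columns <- function() c("eq5d_mo", "eq5d_sc", "eq5d_ua", "eq5d_pd", "eq5d_ad")

#' @export
print.trial_data <- function(x, ...) {
  n <- table(factor(x$participants$arm, c("control", "intervention")))
  cat("Trial dataset: ", nrow(x$participants), " participants (",
      n[["control"]], " control, ", n[["intervention"]], " intervention), ",
      nrow(x$assessments), " assessments at months ",
      paste(x$timepoints, collapse = "/"),
      "; costs in ", x$currency_year, " GBP\n", sep = "")
  invisible(x)
}

#' Read long-format trial data from CSV
#'
#' One row per participant x assessment. Participant-level covariates are
#' repeated on each row and checked for consistency. Unknown columns whose
#' names start with `ru_` are collected as resource-use counts. Empty cells
#' are read as missing (`NA`), never as zero.
#'
#' @param path CSV file path (UTF-8, header row required).
#' @param schema optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(utility = "eq5d_index")`.
#' @param timepoints,currency_year passed to [trial_data()].
#' @return A [trial_data] object.
#' @export
read_trial_data <- function(path, schema = NULL,
                            timepoints = c(0, 3, 6), currency_year = 2022L) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(raw))
        stop("schema maps '", canon, "' to absent column '", src, "'")
      names(raw)[names(raw) == src] <- canon
    }
  }
  req <- c("participant_id", "arm", "timepoint_months", "age", "sex",
           "imd_quintile", "ethnicity", "primary_symptom", "employment_status")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("required column(s) missing from ", path, ": ",
         paste(miss, collapse = ", "))

  p_cols <- c("participant_id", "arm", "age", "sex", "imd_quintile",
              "ethnicity", "primary_symptom", "employment_status")
  parts <- unique(raw[p_cols])
  if (anyDuplicated(parts$participant_id))
    stop("participant-level covariates differ across rows of the same participant")
  a_cols <- setdiff(names(raw), setdiff(p_cols, "participant_id"))
  trial_data(parts, raw[a_cols],
             timepoints = timepoints, currency_year = currency_year)
}

#' Write trial data to long-format CSV
#'
#' Inverse of [read_trial_data()]: `read_trial_data(write_trial_data(x, f))`
#' reproduces `x` field for field. Missing values are written as empty cells.
#'
#' @param data a [trial_data] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_data <- function(data, path) {
  stopifnot(inherits(data, "trial_data"))
  long <- merge(data$participants, data$assessments,
                by = "participant_id", sort = FALSE)
  ord <- order(match(long$participant_id, data$participants$participant_id),
               long$timepoint_months)
  long <- long[ord, , drop = FALSE]
  front <- c("participant_id", "arm", "timepoint_months")
  long <- long[c(front, setdiff(names(long), front))]
  utils::write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Summarise missingness by arm, variable and participant
#'
#' Counts missing person-timepoint observations per arm over the named
#' assessment variables, against the expected number of observations
#' (participants x scheduled timepoints); an assessment row absent from the
#' data counts as missing for every variable. Also reports, per variable,
#' how many participants have at least one missing observation.
#'
#' @param data a [trial_data] object.
#' @param variables character vector of assessment variable names
#'   (default `"utility"`).
#' @return An object of class `missingness_report`: list with `by_arm`
#'   (data.frame variable x arm: expected, missing), `by_participant`
#'   (data.frame participant_id, arm, n_missing, any_missing), and `total`.
#' @export
missingness_summary <- function(data, variables = "utility") {
  stopifnot(inherits(data, "trial_data"))
  known <- setdiff(names(data$assessments), c("participant_id", "timepoint_months"))
  bad <- setdiff(variables, known)
  if (length(bad))
    stop("unknown variable(s): ", paste(bad, collapse = ", "))

  p <- data$participants
  grid <- expand.grid(participant_id = p$participant_id,
                      timepoint_months = data$timepoints,
                      stringsAsFactors = FALSE)
  grid$arm <- p$arm[match(grid$participant_id, p$participant_id)]
  a <- data$assessments
  akey <- paste(a$participant_id, a$timepoint_months)
  gkey <- paste(grid$participant_id, grid$timepoint_months)
  row_of <- match(gkey, akey)

  arms <- c("control", "intervention")
  by_arm <- do.call(rbind, lapply(variables, function(v) {
    vals <- a[[v]][row_of]            # NA where row absent or cell missing
    data.frame(variable = v, arm = arms,
               expected = as.integer(table(factor(grid$arm, arms))),
               missing = as.integer(tapply(is.na(vals),
                                           factor(grid$arm, arms), sum)),
               row.names = NULL)
  }))

  # person-timepoints where any of the named variables is missing
  miss_mat <- sapply(variables, function(v) is.na(a[[v]][row_of]))
  miss_any <- rowSums(matrix(miss_mat, nrow = nrow(grid))) > 0
  by_part <- data.frame(
    participant_id = p$participant_id,
    arm = p$arm,
    n_missing = as.integer(tapply(miss_any,
                                  factor(grid$participant_id,
                                         p$participant_id), sum)),
    row.names = NULL)
  by_part$any_missing <- by_part$n_missing > 0

  structure(list(by_arm = by_arm, by_participant = by_part,
                 variables = variables,
                 total = c(expected = nrow(grid),
                           missing = sum(miss_any))),
            class = "missingness_report")
}

#' @export
print.missingness_report <- function(x, ...) {
  cat("Missingness over variable(s): ",
      paste(x$variables, collapse = ", "), "\n", sep = "")
  print(x$by_arm, row.names = FALSE)
  cat(sum(x$by_participant$any_missing),
      "participant(s) with at least one missing observation\n")
  invisible(x)
}

#' Write a missingness report to CSV or JSON
#'
#' @param report a `missingness_report`.
#' @param path output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_missingness_report <- function(report, path) {
  stopifnot(inherits(report, "missingness_report"))
  if (grepl("\\.json$", path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required for JSON output")
    jsonlite::write_json(list(by_arm = report$by_arm,
                              by_participant = report$by_participant),
                         path, dataframe = "rows", auto_unbox = TRUE)
  } else {
    utils::write.csv(report$by_arm, path, row.names = FALSE)
  }
  invisible(path)
}
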