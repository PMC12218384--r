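#' Load an EQ-5D-5L value set from CSV
#'
#' A value set maps each 5-digit EQ-5D-5L health state (e.g. `"21132"`:
#' mobility, self-care, usual activities, pain/discomfort,
#' anxiety/depression) to a utility. Published crosswalk tariffs are
#' distributed by their authors as data files; this loader accepts any CSV
#' with columns `state` and `utility`. Partial (fixture) sets are allowed;
#' looking up an absent state is then an error, never a silent default.
#'
#' @param path CSV with columns `state` (5-character string of digits 1-5)
#'   and `utility` (decimal, at most 1).
#' @return An object of class `value_set`: list with `name`, `mapping`
#'   (named numeric vector keyed by state), `floor`, `ceiling`.
#' @export
load_value_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(state = "character"))
  if (!all(c("state", "utility") %in% names(tab)))
    stop("value-set CSV must have columns 'state' and 'utility'")
  value_set(stats::setNames(tab$utility, tab$state),
            name = sub("\\.csv$", "", basename(path)))
}

#' Construct a value set from a named utility vector
#'
#' @param mapping named numeric vector: names are 5-digit states, values
#'   utilities.
#' @param name label for the set.
#' @return A `value_set` object.
#' @export
value_set <- function(mapping, name = "value_set") {
  states <- names(mapping)
  if (is.null(states) || any(!grepl("^[1-5]{5}$", states))) {
    bad <- states[!grepl("^[1-5]{5}$", states)]
    stop("malformed health state(s): ",
         paste(utils::head(bad %||% "<unnamed>", 5), collapse = ", "),
         " (need 5 digits, each 1-5)")
  }
  if (anyDuplicated(states))
    stop("duplicate state(s) in value set: ",
         paste(utils::head(unique(states[duplicated(states)]), 5), collapse = ", "))
  u <- as.numeric(mapping)
  if (any(!is.finite(u))) stop("non-finite utility in value set")
  if (any(u > 1)) stop("utility above 1 in value set")
  if ("11111" %in% states && mapping[["11111"]] != 1)
    stop("state 11111 (perfect health) must map to utility 1")
  structure(list(name = name,
                 mapping = stats::setNames(u, states),
                 floor = min(u), ceiling = 1.0),
            class = "value_set")
}

#' @export
print.value_set <- function(x, ...) {
  cat("EQ-5D-5L value set '", x$name, "': ", length(x$mapping),
      " states, range [", format(x$floor), ", ", format(x$ceiling), "]\n",
      sep = "")
  invisible(x)
}

#' Synthetic complete EQ-5D-5L value set
#'
#' A deterministic additive tariff over all 3125 states for testing and
#' simulation: utility = 1 minus a sum of dimension-specific decrements,
#' scaled so that `11111` maps to 1 (perfect health) and `55555` to -0.532,
#' matching the range of the UK EQ-5D-3L crosswalk scale. It is a synthetic
#' stand-in, not a published tariff; substitute the licensed crosswalk CSV
#' via [load_value_set()] for real analyses.
#'
#' @return A `value_set` with all 3125 states.
#' @export
synthetic_value_set <- function() {
  # maximum (level 5) decrement per dimension, summing to 1.532
  dim_max <- c(mo = 0.350, sc = 0.300, ua = 0.250, pd = 0.350, ad = 0.282)
  # within-dimension severity profile (levels 1..5 as fraction of the max)
  sev <- c(0, 0.20, 0.40, 0.75, 1.00)
  grid <- expand.grid(mo = 1:5, sc = 1:5, ua = 1:5, pd = 1:5, ad = 1:5)
  dec <- as.matrix(sapply(names(dim_max),
                          function(d) dim_max[[d]] * sev[grid[[d]]]))
  u <- 1 - rowSums(dec)
  states <- apply(grid, 1, paste0, collapse = "")
  value_set(stats::setNames(round(u, 4), states), name = "synthetic")
}

#' Map EQ-5D-5L responses to utilities
#'
#' Exact table lookup (no interpolation). Accepts a single 5-vector of
#' levels, a matrix/data.frame with 5 columns (one row per response), or a
#' character vector of 5-digit states.
#'
#' @param responses levels 1-5 per dimension (see above).
#' @param value_set a `value_set`.
#' @return Numeric utility vector.
#' @export
map_eq5d_to_utility <- function(responses, value_set) {
  stopifnot(inherits(value_set, "value_set"))
  if (is.character(responses)) {
    states <- responses
  } else {
    m <- if (is.null(dim(responses))) matrix(responses, nrow = 1)
         else as.matrix(responses)
    if (ncol(m) != 5) stop("responses must have 5 dimensions")
    if (anyNA(m)) stop("incomplete EQ-5D response (NA level); ",
                       "treat partially answered questionnaires as missing upstream")
    if (any(!(m %in% 1:5))) stop("EQ-5D levels must be integers in 1..5")
    states <- apply(m, 1, paste0, collapse = "")
  }
  u <- value_set$mapping[states]
  if (anyNA(u))
    stop("state(s) absent from value set '", value_set$name, "': ",
         paste(utils::head(unique(states[is.na(u)]), 5), collapse = ", "))
  unname(u)
}

#' Area-under-the-curve QALYs from a utility trajectory
#'
#' Trapezoidal area under utility versus time. With assessments at 0, 3 and
#' 6 months, `time_weighted_mean` equals 1/4 u0 + 1/2 u3 + 1/4 u6 (the
#' annualised utility scale on which short-trial QALY tables are usually
#' reported); `total_qaly` multiplies that mean by the elapsed time in
#' years (0.5 for a 6-month horizon).
#'
#' @param utilities numeric utilities, no missing values (impute upstream).
#' @param times month offsets, strictly increasing, same length (>= 2).
#' @param mode `"time_weighted_mean"` (default) or `"total_qaly"`.
#' @return A single number.
#' @export
auc_qaly <- function(utilities, times = c(0, 3, 6),
                     mode = c("time_weighted_mean", "total_qaly")) {
  mode <- match.arg(mode)
  if (length(utilities) != length(times))
    stop("utilities and times must have equal length")
  if (length(utilities) < 2) stop("need at least 2 observations for an AUC")
  if (anyNA(utilities)) stop("missing utility; imputation happens upstream")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  area <- sum(diff(times) * (utilities[-length(utilities)] + utilities[-1]) / 2)
  twm <- area / (times[length(times)] - times[1])
  switch(mode,
         time_weighted_mean = twm,
         total_qaly = twm * (times[length(times)] - times[1]) / 12)
}

#' Per-participant QALYs for a trial dataset
#'
#' Computes [auc_qaly()] for every participant with a complete utility
#' trajectory over the scheduled timepoints; participants with any missing
#' utility get `NA` (imputation is the upstream fix, never silent
#' interpolation here).
#'
#' @param data a [trial_data] object with a `utility` assessment column.
#' @param mode passed to [auc_qaly()].
#' @return data.frame: participant_id, arm, qaly.
#' @export
qaly_table <- function(data, mode = "time_weighted_mean") {
  stopifnot(inherits(data, "trial_data"))
  if (!"utility" %in% names(data$assessments))
    stop("dataset has no 'utility' column; map EQ-5D responses first")
  p <- data$participants
  a <- data$assessments
  akey <- paste(a$participant_id, a$timepoint_months)
  qaly <- vapply(p$participant_id, function(id) {
    u <- a$utility[match(paste(id, data$timepoints), akey)]
    if (anyNA(u)) NA_real_ else auc_qaly(u, data$timepoints, mode)
  }, numeric(1))
  data.frame(participant_id = p$participant_id, arm = p$arm,
             qaly = unname(qaly), row.names = NULL)
}
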