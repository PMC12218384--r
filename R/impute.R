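#' Multiple imputation by chained equations (predictive mean matching)
#'
#' Imputes incomplete numeric analysis variables via chained equations,
#' independently within groups (by trial arm, so that one arm's data can
#' never inform the other's imputations). Each incomplete variable is
#' regressed, in a fixed order (column order of `variables`), on the
#' complete covariates plus the current values of the other analysis
#' variables; imputations are drawn by type-1 predictive mean matching:
#' a Bayesian draw of the regression coefficients produces predictions for
#' the missing rows, each matched to its `donors` nearest observed rows by
#' predicted value (ties broken uniformly at random), and one donor's
#' observed value is copied. Because donors are observed values, imputed
#' utilities stay within the value-set range and imputed costs stay
#' nonnegative without any clamping.
#'
#' The chain runs for a fixed number of sweeps (`maxit`); non-convergence
#' is not detected. Randomness is fully determined by `seed`, with
#' per-group, per-imputation substreams derived deterministically, so
#' results for one arm are invariant to changes in the other arm's data.
#'
#' @param data data.frame; one row per participant.
#' @param variables names of columns to impute (numeric; those without
#'   missing values are used as predictors only).
#' @param predictors names of complete covariate columns (numeric or
#'   factor/character) used in every imputation model.
#' @param by optional name of a grouping column (e.g. `"arm"`); groups are
#'   imputed independently.
#' @param m number of imputed datasets (default 10).
#' @param maxit chained-equation sweeps per imputation (default 10).
#' @param donors PMM donor count (default 5).
#' @param seed master seed (default 1).
#' @param max_missing_frac error if any variable exceeds this missingness
#'   fraction within a group (default 0.5).
#' @return Object of class `mi_data`: list with `imputations` (list of m
#'   completed data.frames), `where` (logical matrix of imputed cells),
#'   `provenance` (long data.frame: row, variable, imputation, value) and
#'   the call settings.
#' @export
impute_mice <- function(data, variables, predictors = character(),
                        by = NULL, m = 10L, maxit = 10L, donors = 5L,
                        seed = 1L, max_missing_frac = 0.5) {
  data <- as.data.frame(data)
  stopifnot(m >= 1, maxit >= 1, donors >= 1)
  miss <- setdiff(c(variables, predictors, by), names(data))
  if (length(miss))
    stop("column(s) not in data: ", paste(miss, collapse = ", "))
  for (v in variables)
    if (!is.numeric(data[[v]]))
      stop("imputation variable '", v, "' must be numeric")
  for (v in predictors)
    if (anyNA(data[[v]]))
      stop("predictor '", v, "' must be complete")

  groups <- if (is.null(by)) list(seq_len(nrow(data)))
            else split(seq_len(nrow(data)), data[[by]])

  where <- is.na(as.matrix(data[variables]))
  rownames(where) <- NULL

  # feasibility checks per group
  for (gname in names(groups) %||% "all") {
    idx <- if (is.null(by)) groups[[1]] else groups[[gname]]
    for (v in variables) {
      nmis <- sum(is.na(data[[v]][idx]))
      nobs <- length(idx) - nmis
      if (nmis == length(idx))
        stop("variable '", v, "' is entirely missing in group '", gname, "'")
      if (nmis > 0 && nobs < 2)
        stop("fewer than 2 complete cases for '", v, "' in group '", gname, "'")
      if (nmis / length(idx) > max_missing_frac)
        stop("missingness of '", v, "' in group '", gname, "' exceeds ",
             round(100 * max_missing_frac), "%")
    }
  }

  imputations <- vector("list", m)
  for (i in seq_len(m)) imputations[[i]] <- data

  if (any(where)) {
    for (gi in seq_along(groups)) {
      idx <- groups[[gi]]
      glabel <- (names(groups) %||% "all")[gi]
      gdat <- data[idx, , drop = FALSE]
      # fixed covariate design for this group
      X_cov <- if (length(predictors))
        stats::model.matrix(~ ., data = gdat[predictors])
      else matrix(1, nrow(gdat), 1)
      for (i in seq_len(m)) {
        set.seed(substream_seed(seed, glabel, i))
        imp <- impute_group_once(gdat, variables, X_cov, maxit, donors)
        imputations[[i]][idx, variables] <- imp
      }
    }
  }

  prov <- NULL
  if (any(where)) {
    cells <- which(where, arr.ind = TRUE)
    prov <- do.call(rbind, lapply(seq_len(m), function(i) {
      data.frame(row = cells[, 1],
                 variable = variables[cells[, 2]],
                 imputation = i,
                 value = as.matrix(imputations[[i]][variables])[cells],
                 row.names = NULL)
    }))
  }

  structure(list(imputations = imputations, where = where,
                 provenance = prov, variables = variables,
                 m = as.integer(m), maxit = as.integer(maxit),
                 donors = as.integer(donors), seed = as.integer(seed),
                 by = by),
            class = "mi_data")
}

## one completed copy of a group's analysis variables
impute_group_once <- function(gdat, variables, X_cov, maxit, donors) {
  n <- nrow(gdat)
  Y <- as.matrix(gdat[variables])
  mis <- is.na(Y)
  incomplete <- which(colSums(mis) > 0)
  # initial fill: random draws from each variable's observed values
  for (j in incomplete) {
    obs <- Y[!mis[, j], j]
    Y[mis[, j], j] <- sample(obs, sum(mis[, j]), replace = TRUE)
  }
  if (!length(incomplete)) return(Y)
  for (it in seq_len(maxit)) {
    for (j in incomplete) {
      X <- cbind(X_cov, Y[, -j, drop = FALSE])
      Y[mis[, j], j] <- pmm_draw(y = Y[, j], ry = !mis[, j], X = X,
                                 donors = donors)
    }
  }
  Y
}

## Bayesian-draw PMM (type-1 matching): predictions for missing rows come
## from a posterior draw of beta, donor predictions from the LS fit.
pmm_draw <- function(y, ry, X, donors = 5L, ridge = 1e-5) {
  Xo <- X[ry, , drop = FALSE]
  yo <- y[ry]
  # drop aliased columns for stability
  qrX <- qr(Xo)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  Xo <- Xo[, keep, drop = FALSE]
  Xm <- X[!ry, keep, drop = FALSE]
  p <- ncol(Xo)
  S <- crossprod(Xo)
  S <- S + diag(ridge * pmax(diag(S), 1), p)
  V <- chol2inv(chol(S))
  beta_hat <- V %*% crossprod(Xo, yo)
  res <- yo - Xo %*% beta_hat
  df <- max(length(yo) - p, 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  beta_star <- beta_hat + t(chol(V)) %*% stats::rnorm(p) * sqrt(sigma2)
  yhat_obs <- drop(Xo %*% beta_hat)
  yhat_mis <- drop(Xm %*% beta_star)
  k <- min(donors, length(yo))
  vapply(yhat_mis, function(pred) {
    d <- abs(yhat_obs - pred)
    pool <- order(d, stats::runif(length(d)))[seq_len(k)]
    yo[pool[sample.int(k, 1)]]
  }, numeric(1))
}

#' @export
print.mi_data <- function(x, ...) {
  cat("Multiply imputed data: m = ", x$m, ", ", sum(x$where),
      " imputed cells over ", length(x$variables), " variable(s)",
      if (!is.null(x$by)) paste0(", grouped by '", x$by, "'"), "\n", sep = "")
  invisible(x)
}

#' Write imputation provenance to CSV
#'
#' One row per imputed cell per imputation: row index, variable,
#' imputation index, imputed value.
#'
#' @param mi an `mi_data` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_imputation_provenance <- function(mi, path) {
  stopifnot(inherits(mi, "mi_data"))
  utils::write.csv(mi$provenance %||%
                     data.frame(row = integer(), variable = character(),
                                imputation = integer(), value = numeric()),
                   path, row.names = FALSE)
  invisible(path)
}
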