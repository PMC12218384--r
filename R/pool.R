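#' Nonparametric bootstrap of SUR arm effects within each imputed dataset
#'
#' For each completed dataset, draws `B` resamples of participants with
#' replacement (stratified by arm by default, preserving arm sizes),
#' refits the SUR system on each resample, and records the arm
#' coefficients of the cost and effect equations. Replicates are tagged
#' with their imputation index; the full cloud therefore has `m x B` rows.
#' Deterministic under `seed` (per-imputation substreams), and resample
#' indices depend only on `seed`, `B` and the sample size, so clouds for
#' different cost outcomes drawn with the same seed share resamples.
#'
#' @param completed an `mi_data` object or a list of complete data.frames.
#' @param formulas named list `list(cost = ..., effect = ...)` of SUR
#'   equations; each must contain the arm indicator.
#' @param B bootstrap replicates per imputation.
#' @param seed master seed.
#' @param stratify name of the stratification column (default `"arm"`), or
#'   `NULL` for unstratified resampling; unstratified resamples that lose
#'   an arm entirely are discarded and redrawn (counted in attribute
#'   `n_redrawn`).
#' @param coef name of the arm coefficient (default `"armintervention"`).
#' @param identity internal test hook: use the identity resample (the
#'   cloud then equals the m point estimates, repeated B times).
#' @return data.frame of class `incremental_cloud` with columns
#'   `imputation`, `replicate`, `delta_cost`, `delta_effect`.
#' @export
bootstrap_cloud <- function(completed, formulas, B = 5000L, seed = 1L,
                            stratify = "arm", coef = "armintervention",
                            identity = FALSE) {
  stopifnot(B >= 1)
  datasets <- if (inherits(completed, "mi_data")) completed$imputations
              else completed
  if (!is.list(datasets) || !length(datasets))
    stop("'completed' must be an mi_data object or a nonempty list of data.frames")
  if (!all(c("cost", "effect") %in% names(formulas)))
    stop("'formulas' must be a named list with elements 'cost' and 'effect'")

  m <- length(datasets)
  n_redrawn <- 0L
  out <- vector("list", m)
  for (i in seq_len(m)) {
    d <- as.data.frame(datasets[[i]])
    X <- lapply(formulas, function(f) stats::model.matrix(f, d))
    y <- lapply(formulas, function(f)
      stats::model.response(stats::model.frame(f, d)))
    for (e in names(formulas))
      if (!coef %in% colnames(X[[e]]))
        stop("coefficient '", coef, "' not in equation '", e,
             "'; both equations must contain the arm indicator")
    n <- nrow(d)
    strata <- if (is.null(stratify)) NULL else split(seq_len(n), d[[stratify]])
    if (!is.null(strata) && length(strata) < 2)
      stop("stratification column has fewer than 2 levels")
    arm_vec <- if (is.null(stratify)) d$arm else d[[stratify]]

    set.seed(substream_seed(seed, "boot", i))
    dc <- de <- numeric(B)
    for (b in seq_len(B)) {
      if (identity) {
        idx <- seq_len(n)
      } else if (!is.null(strata)) {
        idx <- unlist(lapply(strata, function(s)
          s[sample.int(length(s), length(s), replace = TRUE)]),
          use.names = FALSE)
      } else {
        repeat {
          idx <- sample.int(n, n, replace = TRUE)
          if (length(unique(arm_vec[idx])) > 1) break
          n_redrawn <- n_redrawn + 1L
        }
      }
      fit <- sur_fgls(lapply(X, function(x) x[idx, , drop = FALSE]),
                      lapply(y, function(v) v[idx]))
      dc[b] <- fit$coefficients[["cost"]][[coef]]
      de[b] <- fit$coefficients[["effect"]][[coef]]
    }
    out[[i]] <- data.frame(imputation = i, replicate = seq_len(B),
                           delta_cost = dc, delta_effect = de)
  }
  cloud <- do.call(rbind, out)
  attr(cloud, "B") <- as.integer(B)
  attr(cloud, "m") <- m
  attr(cloud, "seed") <- as.integer(seed)
  attr(cloud, "n_redrawn") <- n_redrawn
  class(cloud) <- c("incremental_cloud", "data.frame")
  cloud
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Point estimate = mean of per-imputation estimates; total variance
#' T = W + (1 + 1/m) B with W the mean within-imputation variance and B the
#' between-imputation variance of the estimates; 95% intervals use the
#' Barnard-Rubin small-sample degrees of freedom. A pooled covariance is
#' produced the same way when within-imputation covariance matrices are
#' supplied.
#'
#' @param estimates numeric matrix, m rows (imputations) x k columns
#'   (components), or a vector for k = 1.
#' @param variances matrix like `estimates` of within-imputation variances.
#' @param within_cov optional list of m within-imputation k x k covariance
#'   matrices (diagonals override `variances` if both given).
#' @param df_com complete-data degrees of freedom for the Barnard-Rubin
#'   adjustment (default `Inf`, reducing to the older large-sample df).
#' @param level confidence level (default 0.95).
#' @return Object of class `pooled_estimate`: `point`, `W`, `B`, `T`,
#'   `df`, `ci` (k x 2), `cov` (pooled covariance, if computable), `m`.
#' @export
rubin_pool <- function(estimates, variances = NULL, within_cov = NULL,
                       df_com = Inf, level = 0.95) {
  est <- as.matrix(estimates)
  m <- nrow(est)
  k <- ncol(est)
  if (m < 1) stop("need at least one imputation (m >= 1)")
  if (!is.null(within_cov)) {
    stopifnot(length(within_cov) == m)
    variances <- t(vapply(within_cov, diag, numeric(k)))
    if (k == 1) variances <- matrix(variances, ncol = 1)
  }
  if (is.null(variances))
    stop("supply 'variances' or 'within_cov'")
  varm <- as.matrix(variances)
  stopifnot(all(dim(varm) == dim(est)), all(varm >= 0))

  point <- colMeans(est)
  W <- colMeans(varm)
  Bv <- if (m > 1) apply(est, 2, stats::var) else rep(0, k)
  Tt <- W + (1 + 1 / m) * Bv

  # Barnard-Rubin degrees of freedom, per component
  df <- vapply(seq_len(k), function(j) {
    if (m == 1 || Bv[j] == 0 || Tt[j] == 0) {
      if (is.finite(df_com)) df_com else Inf
    } else {
      lam <- (1 + 1 / m) * Bv[j] / Tt[j]
      df_old <- (m - 1) / lam^2
      if (is.finite(df_com)) {
        df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lam)
        df_old * df_obs / (df_old + df_obs)
      } else df_old
    }
  }, numeric(1))

  q <- stats::qt(1 - (1 - level) / 2, df)
  ci <- cbind(lower = point - q * sqrt(Tt), upper = point + q * sqrt(Tt))
  rownames(ci) <- colnames(est)

  cov_pooled <- NULL
  if (!is.null(within_cov)) {
    Wc <- Reduce(`+`, within_cov) / m
    Bc <- if (m > 1) stats::cov(est) else matrix(0, k, k)
    cov_pooled <- Wc + (1 + 1 / m) * Bc
  }

  structure(list(point = point, W = W, B = Bv, T = Tt, df = df, ci = ci,
                 cov = cov_pooled, m = m, level = level),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  tab <- data.frame(estimate = x$point, se = sqrt(x$T),
                    lower = x$ci[, 1], upper = x$ci[, 2], df = round(x$df, 1))
  cat("Rubin's-rules pooled estimates (m = ", x$m, ", ",
      100 * x$level, "% CI):\n", sep = "")
  print(round(tab, 6))
  invisible(x)
}

#' Per-imputation covariance of bootstrap replicates
#'
#' The within-imputation covariance of (delta_cost, delta_effect) taken
#' from each imputation's bootstrap replicates; the `within_cov` input to
#' [rubin_pool()].
#'
#' @param cloud an `incremental_cloud`.
#' @return List of m 2x2 covariance matrices, ordered by imputation index.
#' @export
cloud_within_cov <- function(cloud) {
  lapply(split(cloud[c("delta_cost", "delta_effect")], cloud$imputation),
         function(d) stats::cov(as.matrix(d)))
}

#' Write a bootstrap cloud to CSV
#'
#' Unrounded, one row per replicate: imputation, replicate, delta_cost,
#' delta_effect.
#'
#' @param cloud an `incremental_cloud`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path) {
  stopifnot(inherits(cloud, "incremental_cloud"))
  utils::write.csv(as.data.frame(cloud), path, row.names = FALSE)
  invisible(path)
}
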