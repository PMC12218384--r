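#' Seemingly unrelated regression by feasible generalised least squares
#'
#' Fits a system of linear equations with correlated errors across
#' equations for the same individual: (1) equation-by-equation OLS, (2)
#' cross-equation residual covariance from the OLS residuals, (3) one GLS
#' step with that covariance. With identical regressor sets in every
#' equation, the GLS step reproduces OLS exactly; efficiency gains arise
#' when the regressor sets differ, as with a cost equation adjusted for
#' baseline costs and an effect equation adjusted for baseline utility.
#'
#' @param formulas named list of model formulas, one per equation (e.g.
#'   `list(cost = total_cost ~ arm + age, effect = qaly ~ arm + age)`).
#' @param data data.frame with complete cases for all model variables.
#' @return Object of class `sur`: coefficients per equation, residual
#'   covariance `sigma`, joint coefficient covariance `vcov` (GLS), plus
#'   residuals/fitted matrices.
#' @export
sur_fit <- function(formulas, data) {
  if (!is.list(formulas) || length(formulas) < 2)
    stop("'formulas' must be a named list of at least 2 formulas")
  if (is.null(names(formulas)) || any(names(formulas) == ""))
    names(formulas) <- paste0("eq", seq_along(formulas))
  data <- as.data.frame(data)
  allv <- unique(unlist(lapply(formulas, all.vars)))
  miss <- setdiff(allv, names(data))
  if (length(miss)) stop("variable(s) not in data: ", paste(miss, collapse = ", "))
  if (anyNA(data[allv]))
    stop("SUR requires complete data for all model variables; impute first")

  X <- lapply(formulas, function(f) stats::model.matrix(f, data))
  y <- lapply(formulas, function(f)
    stats::model.response(stats::model.frame(f, data)))
  n <- nrow(data)
  for (e in seq_along(X)) {
    q <- qr(X[[e]])
    if (q$rank < ncol(X[[e]])) {
      alias <- colnames(X[[e]])[q$pivot[-seq_len(q$rank)]]
      stop("rank-deficient design in equation '", names(formulas)[e],
           "': collinear column(s) ", paste(alias, collapse = ", "))
    }
    if (n <= ncol(X[[e]]))
      stop("equation '", names(formulas)[e],
           "' has more coefficients than observations")
  }
  fit <- sur_fgls(X, y)
  structure(c(fit,
              list(formulas = formulas, n = n, call = match.call(),
                   eq_names = names(formulas))),
            class = "sur")
}

## FGLS core on prebuilt design matrices; also used by the bootstrap where
## model.matrix overhead would dominate. Aliased columns (e.g. a factor
## level absent from a bootstrap resample) are dropped from the fit.
sur_fgls <- function(X, y) {
  G <- length(X)
  n <- length(y[[1]])
  # step 1: OLS per equation
  beta_ols <- vector("list", G)
  E <- matrix(0, n, G)
  for (e in seq_len(G)) {
    f <- stats::lm.fit(X[[e]], y[[e]])
    if (f$rank < ncol(X[[e]])) {
      keep <- f$qr$pivot[seq_len(f$rank)]
      X[[e]] <- X[[e]][, keep, drop = FALSE]
      f <- stats::lm.fit(X[[e]], y[[e]])
    }
    beta_ols[[e]] <- f$coefficients
    E[, e] <- f$residuals
  }
  # step 2: residual covariance (ML scaling); tiny ridge if degenerate
  sigma <- crossprod(E) / n
  W <- tryCatch(solve(sigma),
                error = function(e)
                  solve(sigma + diag(1e-8 * pmax(diag(sigma), 1), G)))
  p <- vapply(X, ncol, integer(1))
  off <- c(0, cumsum(p))
  M <- matrix(0, sum(p), sum(p))
  v <- numeric(sum(p))
  for (e in seq_len(G)) {
    for (f in seq_len(G)) {
      M[(off[e] + 1):off[e + 1], (off[f] + 1):off[f + 1]] <-
        W[e, f] * crossprod(X[[e]], X[[f]])
      v[(off[e] + 1):off[e + 1]] <- v[(off[e] + 1):off[e + 1]] +
        W[e, f] * crossprod(X[[e]], y[[f]])
    }
  }
  # equilibrate before solving: cost and effect equations live on wildly
  # different scales (pounds^2 vs QALY^2), which otherwise destroys the
  # conditioning of the stacked system
  s <- 1 / sqrt(pmax(diag(M), .Machine$double.eps))
  Ms <- M * tcrossprod(s)
  Msi <- tryCatch(solve(Ms),
                  error = function(e)
                    solve(Ms + diag(1e-10, nrow(Ms))))
  Minv <- Msi * tcrossprod(s)
  beta <- drop(Minv %*% v)
  coefs <- fitted <- resid <- vector("list", G)
  for (e in seq_len(G)) {
    b <- beta[(off[e] + 1):off[e + 1]]
    names(b) <- colnames(X[[e]])
    coefs[[e]] <- b
    fitted[[e]] <- drop(X[[e]] %*% b)
    resid[[e]] <- y[[e]] - fitted[[e]]
  }
  names(coefs) <- names(X)
  list(coefficients = coefs, sigma = sigma, vcov = Minv,
       residuals = do.call(cbind, resid), fitted = do.call(cbind, fitted),
       ols = beta_ols)
}

#' @export
coef.sur <- function(object, ...) object$coefficients

#' @export
vcov.sur <- function(object, ...) object$vcov

#' @export
residuals.sur <- function(object, ...) object$residuals

#' @export
fitted.sur <- function(object, ...) object$fitted

#' @export
print.sur <- function(x, ...) {
  cat("Seemingly unrelated regression (FGLS), n =", x$n, "\n")
  for (e in x$eq_names) {
    cat("\nEquation '", e, "': ", deparse(x$formulas[[e]]), "\n", sep = "")
    print(round(x$coefficients[[e]], 4))
  }
  r <- stats::cov2cor(x$sigma)
  cat("\nResidual cross-equation correlation:",
      round(r[upper.tri(r)], 3), "\n")
  invisible(x)
}

#' @export
summary.sur <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  p <- vapply(object$coefficients, length, integer(1))
  off <- c(0, cumsum(p))
  tabs <- lapply(seq_along(object$coefficients), function(e) {
    b <- object$coefficients[[e]]
    s <- se[(off[e] + 1):off[e + 1]]
    z <- b / s
    data.frame(estimate = b, std_error = s, z = z,
               p_value = 2 * stats::pnorm(-abs(z)))
  })
  names(tabs) <- object$eq_names
  structure(list(coefficients = tabs, sigma = object$sigma, n = object$n,
                 formulas = object$formulas),
            class = "summary.sur")
}

#' @export
print.summary.sur <- function(x, ...) {
  cat("Seemingly unrelated regression (FGLS), n =", x$n, "\n")
  for (e in names(x$coefficients)) {
    cat("\nEquation '", e, "': ", deparse(x$formulas[[e]]), "\n", sep = "")
    print(round(x$coefficients[[e]], 5))
  }
  invisible(x)
}

#' @export
confint.sur <- function(object, parm, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  est <- unlist(object$coefficients)
  q <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(est - q * se, est + q * se)
  colnames(out) <- paste(format(100 * c((1 - level) / 2,
                                        1 - (1 - level) / 2)), "%")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
predict.sur <- function(object, newdata, ...) {
  out <- lapply(seq_along(object$formulas), function(e) {
    f <- object$formulas[[e]]
    X <- stats::model.matrix(stats::delete.response(stats::terms(f)),
                             as.data.frame(newdata))
    drop(X %*% object$coefficients[[e]])
  })
  names(out) <- object$eq_names
  do.call(cbind, out)
}
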