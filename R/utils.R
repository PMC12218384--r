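#' @keywords internal
"_PACKAGE"

## Moments of a normal variable censored (clamped) to [a, b].
## Used by the trial generator: utilities are clamped to the value-set range
## (giving a realistic ceiling mass at 1) and weekly hours to [0, 168], and
## ground truth must be exact under that clamping.

cnorm_mean <- function(mu, sigma, a, b) {
  if (sigma <= 0) return(pmin(pmax(mu, a), b))
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  a * stats::pnorm(al) + b * (1 - stats::pnorm(be)) +
    mu * (stats::pnorm(be) - stats::pnorm(al)) +
    sigma * (stats::dnorm(al) - stats::dnorm(be))
}

cnorm_var <- function(mu, sigma, a, b) {
  if (sigma <= 0) return(0)
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  Z <- stats::pnorm(be) - stats::pnorm(al)
  # E[X^2 1(a<X<b)] for X ~ N(mu, sigma^2)
  ex2 <- (mu^2 + sigma^2) * Z +
    sigma^2 * (ifelse(is.finite(al), al * stats::dnorm(al), 0) -
               ifelse(is.finite(be), be * stats::dnorm(be), 0)) +
    2 * mu * sigma * (stats::dnorm(al) - stats::dnorm(be))
  m2 <- a^2 * stats::pnorm(al) + b^2 * (1 - stats::pnorm(be)) + ex2
  m2 - cnorm_mean(mu, sigma, a, b)^2
}

## Find latent (mu, sigma) such that the clamped variable has the target
## observed mean and sd. Simple damped fixed-point iteration; the map is
## monotone and well-behaved for targets strictly inside (a, b).
cnorm_calibrate <- function(target_mean, target_sd, a, b,
                            tol = 1e-10, maxit = 200L) {
  if (target_mean <= a || target_mean >= b)
    stop("target mean must lie strictly inside the censoring bounds")
  mu <- target_mean
  sigma <- max(target_sd, 1e-6)
  for (i in seq_len(maxit)) {
    m <- cnorm_mean(mu, sigma, a, b)
    s <- sqrt(max(cnorm_var(mu, sigma, a, b), 1e-12))
    mu_new <- mu + (target_mean - m)
    sigma_new <- sigma * target_sd / s
    if (abs(m - target_mean) < tol && abs(s - target_sd) < tol) break
    mu <- mu_new
    sigma <- min(sigma_new, 10 * target_sd)
  }
  if (abs(cnorm_mean(mu, sigma, a, b) - target_mean) > 1e-6)
    stop("censored-normal calibration failed to converge; ",
         "target moments may be infeasible for bounds [", a, ", ", b, "]")
  list(mu = mu, sigma = sigma)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## E[clamp(clamp(X, a, b) + delta, a, b)] for X ~ N(mu, sigma^2): an
## additive shift applied to an already-censored variable, re-censored.
## Equals cnorm_mean on a shrunk interval plus the shift.
shifted_cnorm_mean <- function(mu, sigma, a, b, delta) {
  if (delta >= 0) cnorm_mean(mu, sigma, a, b - delta) + delta
  else cnorm_mean(mu, sigma, a - delta, b) + delta
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## Deterministic substream seeds: independent per-label streams derived from
## one master seed, so e.g. imputing one arm never perturbs the other arm's
## random numbers. Labels are hashed to an integer offset.
substream_seed <- function(seed, label, index = 1L) {
  ch <- utf8ToInt(as.character(label))
  h <- sum(ch * seq_along(ch))
  # double-precision arithmetic: products stay exact below 2^53
  as.integer((as.numeric(seed) * 7919 + (h %% 104729) * 31 + index) %%
               2147483562)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  invisible(x)
}
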