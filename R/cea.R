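#' Incremental cost-effectiveness ratio with dominance labelling
#'
#' Ratio of incremental cost to incremental effect, labelled by quadrant of
#' the cost-effectiveness plane: a positive ratio in the NE quadrant is the
#' conventional ICER; an intervention that is cheaper and more effective is
#' `"dominant"` (no ratio needed); dearer and less effective is
#' `"dominated"`. In the SW quadrant (cheaper, less effective) the ratio is
#' reported with an explicit flag because its decision interpretation
#' reverses (a larger ratio favours the intervention). Zero incremental
#' effect leaves the ratio undefined.
#'
#' @param delta_cost incremental cost (GBP).
#' @param delta_effect incremental effect (QALYs).
#' @return Object of class `icer`: list with `ratio` (GBP/QALY or `NA`),
#'   `label` (`"value"`, `"dominant"`, `"dominated"` or `"undefined"`),
#'   `quadrant` (`"NE"`, `"SE"`, `"NW"`, `"SW"`), and `sw_flag`.
#' @export
icer <- function(delta_cost, delta_effect) {
  if (!is.finite(delta_cost) || !is.finite(delta_effect))
    stop("delta_cost and delta_effect must be finite")
  quadrant <- paste0(if (delta_cost >= 0) "N" else "S",
                     if (delta_effect >= 0) "E" else "W")
  if (delta_effect == 0) {
    out <- list(ratio = NA_real_, label = "undefined")
  } else if (delta_effect > 0 && delta_cost < 0) {
    out <- list(ratio = NA_real_, label = "dominant")
  } else if (delta_effect < 0 && delta_cost > 0) {
    out <- list(ratio = NA_real_, label = "dominated")
  } else {
    out <- list(ratio = delta_cost / delta_effect, label = "value")
  }
  structure(c(out, list(quadrant = quadrant, sw_flag = quadrant == "SW",
                        delta_cost = delta_cost,
                        delta_effect = delta_effect)),
            class = "icer")
}

#' @export
print.icer <- function(x, ...) {
  txt <- switch(x$label,
                value = paste0("GBP ",
                               formatC(round(x$ratio), big.mark = ",",
                                       format = "d"), "/QALY",
                               if (x$sw_flag) " (SW quadrant: intervention cheaper and less effective)"),
                dominant = "Dominant (cheaper, more effective)",
                dominated = "Dominated (dearer, less effective)",
                undefined = "Undefined (zero incremental effect)")
  cat("ICER:", txt, "\n")
  invisible(x)
}

#' Incremental net monetary benefit
#'
#' `lambda * delta_effect - delta_cost` at willingness-to-pay `lambda`
#' (GBP/QALY). Positive INMB means the intervention is cost-effective at
#' that threshold. Vectorised over `lambda`. Unrounded; round to whole
#' pounds for display.
#'
#' @param delta_cost,delta_effect incremental cost (GBP) and effect (QALY).
#' @param lambda willingness-to-pay threshold(s), >= 0.
#' @return Numeric INMB (GBP), same length as `lambda`.
#' @export
inmb <- function(delta_cost, delta_effect, lambda) {
  if (any(lambda < 0)) stop("lambda must be nonnegative")
  lambda * delta_effect - delta_cost
}

#' Cost-effectiveness acceptability curve
#'
#' For each threshold, the fraction of bootstrap replicates with positive
#' net monetary benefit (`lambda * dE - dC > 0`). The net-benefit framing
#' handles all four quadrants without ratio sign ambiguity. Exact ties
#' (NMB of exactly zero) count as not cost-effective. At `lambda = 0` the
#' curve equals the probability of being cost-saving (`dC < 0`).
#'
#' @param cloud an `incremental_cloud` (or data.frame with `delta_cost`,
#'   `delta_effect`).
#' @param lambda_grid strictly increasing nonnegative thresholds.
#' @return data.frame of class `ceac`: `lambda`, `probability`.
#' @export
ceac <- function(cloud, lambda_grid = seq(0, 50000, by = 500)) {
  if (NROW(cloud) == 0) stop("empty cloud")
  if (any(lambda_grid < 0) || any(diff(lambda_grid) <= 0))
    stop("lambda_grid must be nonnegative and strictly increasing")
  pr <- vapply(lambda_grid, function(l)
    mean(l * cloud$delta_effect - cloud$delta_cost > 0), numeric(1))
  structure(data.frame(lambda = lambda_grid, probability = pr),
            class = c("ceac", "data.frame"))
}

#' Cost-effectiveness plane export
#'
#' Per-replicate (dE, dC) points for plotting, quadrant shares, and the
#' threshold-line parameters. Quadrants follow [icer()] orientation (NE:
#' dearer & more effective; SE: dominant; NW: dominated; SW: cheaper &
#' less effective); points on an axis are assigned north/east by the `>=`
#' convention, so shares always sum to exactly 1.
#'
#' @param cloud an `incremental_cloud`.
#' @param lambda threshold whose line (`dC = lambda * dE`) is reported
#'   (default 30000).
#' @return List of class `plane`: `points` (imputation, replicate,
#'   delta_effect, delta_cost), `quadrant_shares` (named, sums to 1),
#'   `lambda`, `prob_below_lambda_line` (replicates with positive NMB).
#' @export
plane_export <- function(cloud, lambda = 30000) {
  if (NROW(cloud) == 0) stop("empty cloud")
  q <- paste0(ifelse(cloud$delta_cost >= 0, "N", "S"),
              ifelse(cloud$delta_effect >= 0, "E", "W"))
  shares <- vapply(c(NE = "NE", SE = "SE", NW = "NW", SW = "SW"),
                   function(z) mean(q == z), numeric(1))
  pts <- data.frame(imputation = cloud$imputation %||% 1L,
                    replicate = cloud$replicate %||% seq_len(NROW(cloud)),
                    delta_effect = cloud$delta_effect,
                    delta_cost = cloud$delta_cost)
  structure(list(points = pts, quadrant_shares = shares, lambda = lambda,
                 prob_below_lambda_line =
                   mean(lambda * cloud$delta_effect - cloud$delta_cost > 0)),
            class = "plane")
}

#' Write a CEAC to CSV
#'
#' @param x a `ceac` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ceac <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
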