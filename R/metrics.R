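#' Familywise error rate from per-iteration false-rejection counts
#'
#' The fraction of Monte-Carlo iterations in which at least one false
#' rejection occurred.
#'
#' @param per_iteration_false_counts non-negative integer vector, one
#'   count per iteration (non-empty).
#' @return the familywise error estimate in \[0, 1\].
#' @examples
#' familywise_error(c(0, 2, 0, 1)) # 0.5
#' @export
familywise_error <- function(per_iteration_false_counts) {
  x <- per_iteration_false_counts
  if (length(x) == 0L) stop("need at least one iteration", call. = FALSE)
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("counts must be non-negative numbers", call. = FALSE)
  }
  mean(x >= 1)
}

#' False discovery rate from average rejection counts
#'
#' The averages-of-counts estimator: average false rejections divided by
#' average discoveries (false + true). When there are no discoveries at
#' all the rate is 0 by convention, which sidesteps per-iteration 0/0
#' cases. Scale-invariant: multiplying both averages by the same positive
#' constant leaves the rate unchanged.
#'
#' @param avg_true_rejections,avg_false_rejections non-negative averages
#'   over iterations.
#' @return the false discovery rate in \[0, 1\].
#' @examples
#' false_discovery_rate(3, 1) # 0.25
#' @export
false_discovery_rate <- function(avg_true_rejections, avg_false_rejections) {
  if (!is.numeric(avg_true_rejections) || !is.numeric(avg_false_rejections) ||
      avg_true_rejections < 0 || avg_false_rejections < 0) {
    stop("averages must be non-negative", call. = FALSE)
  }
  total <- avg_true_rejections + avg_false_rejections
  if (total == 0) return(0)
  avg_false_rejections / total
}

#' Per-policy quadrant averages over the (lambda, rho) grid
#'
#' Splits the ordered-effect grid into four quadrants by the sign of the
#' order weight lambda and a covariance boundary (the "noise floor",
#' default 0.25): Q1 (`lambda < 0`, `rho > boundary`), Q2 (`lambda > 0`,
#' `rho > boundary`), Q3 (`lambda < 0`, `rho < boundary`), Q4
#' (`lambda > 0`, `rho < boundary`). Cells exactly on a boundary
#' (`lambda == 0` or `rho == boundary`) belong to no quadrant. The chosen
#' metric is averaged over each quadrant's cells, per policy.
#'
#' @param grid_results long-format results from
#'   [run_ordered_experiment()].
#' @param metric which metric to average (default `"fdr"`).
#' @param rho_boundary the covariance boundary (default 0.25).
#' @param quadrants which quadrants to report; each requested quadrant
#'   must be covered by at least one grid cell.
#' @return a data frame with columns `policy`, `quadrant`, `value`.
#' @export
quadrant_summary <- function(grid_results, metric = "fdr",
                             rho_boundary = 0.25,
                             quadrants = c("Q1", "Q2", "Q3", "Q4")) {
  quadrants <- match.arg(quadrants, several.ok = TRUE)
  stopifnot(all(c("policy", "lambda", "rho", "metric", "value") %in%
                  names(grid_results)))
  d <- grid_results[grid_results$metric == metric, ]
  quadrant <- rep(NA_character_, nrow(d))
  quadrant[d$lambda < 0 & d$rho > rho_boundary] <- "Q1"
  quadrant[d$lambda > 0 & d$rho > rho_boundary] <- "Q2"
  quadrant[d$lambda < 0 & d$rho < rho_boundary] <- "Q3"
  quadrant[d$lambda > 0 & d$rho < rho_boundary] <- "Q4"
  keep <- !is.na(quadrant) & quadrant %in% quadrants
  d <- d[keep, ]
  quadrant <- quadrant[keep]
  missing_q <- setdiff(quadrants, unique(quadrant))
  if (length(missing_q)) {
    stop("grid has no cells in requested quadrant(s): ",
         paste(missing_q, collapse = ", "), call. = FALSE)
  }
  out <- stats::aggregate(value ~ policy + quadrant,
                          data = cbind(d, quadrant = quadrant), FUN = mean)
  out[order(out$policy, out$quadrant), , drop = FALSE]
}
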