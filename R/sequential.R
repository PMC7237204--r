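#' Run a sequential policy over an ordered sequence of p-values
#'
#' Walks the p-values in the given order, derives each test's threshold
#' from the policy's state machine, and issues one immutable decision per
#' test: rejection uses strict inequality (`p < alpha_i`), and later tests
#' never revise earlier decisions. Thresholds that underflow machine
#' precision are clamped to zero (such a test can never reject) so long
#' sequences always run to completion.
#'
#' @param p_values_in_order numeric vector of p-values in \[0, 1\], in the
#'   order the tests were (or would be) performed.
#' @param policy a sequential [threshold_policy()]: `"uncorrected"`,
#'   `"alpha_debt"`, `"alpha_spending"` or `"alpha_investing"`.
#' @return a decision data frame with columns `index`, `threshold`,
#'   `p_value`, `rejected`.
#' @examples
#' run_sequential(c(0.001, 0.04), threshold_policy("alpha_debt"))
#' @export
run_sequential <- function(p_values_in_order, policy) {
  if (!inherits(policy, "threshold_policy")) {
    stop("'policy' must be a threshold_policy", call. = FALSE)
  }
  if (!is_sequential_policy(policy)) {
    stop("policy '", policy$name, "' is not a sequential procedure",
         call. = FALSE)
  }
  check_pvalues(p_values_in_order)
  m <- length(p_values_in_order)
  thresholds <- sequential_thresholds(policy, p_values_in_order)
  decision_frame(seq_len(m), thresholds, p_values_in_order,
                 p_values_in_order < thresholds)
}

# Threshold sequence for m ordered tests. Uncorrected, alpha-debt and
# alpha-spending thresholds do not depend on the observed p-values and are
# computed in closed form; alpha-investing must walk the sequence because
# each threshold depends on earlier rejections.
sequential_thresholds <- function(policy, p_values) {
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  p <- policy$parameters
  th <- switch(policy$name,
    uncorrected    = rep(p$alpha, m),
    alpha_debt     = p$alpha1 / seq_len(m),
    alpha_spending = p$alpha0 * p$s * (1 - p$s)^(seq_len(m) - 1),
    alpha_investing = {
      out <- numeric(m)
      w <- p$w0
      for (i in seq_len(m)) {
        a <- p$s * w
        if (a < .Machine$double.xmin) a <- 0
        out[i] <- a
        w <- if (p_values[i] < a) w + p$omega else w - a / (1 - a)
      }
      out
    }
  )
  th[th < .Machine$double.xmin] <- 0
  th
}

#' Threshold schedule of a policy
#'
#' The first `n` thresholds a policy would assign, together with the
#' running total. For alpha-debt the running total is the debt ceiling;
#' for alpha-spending it is the cumulative spend (always below the
#' wealth). Alpha-investing thresholds depend on which tests reject, so a
#' rejection sequence must be supplied (default: none reject).
#'
#' @param policy a sequential [threshold_policy()].
#' @param n number of tests.
#' @param rejections optional logical vector of length `n`; used only by
#'   alpha-investing to drive the wealth updates.
#' @return a data frame with columns `index`, `threshold`, `cumulative`.
#' @examples
#' threshold_schedule(threshold_policy("alpha_debt"), 3)
#' @export
threshold_schedule <- function(policy, n, rejections = NULL) {
  if (!inherits(policy, "threshold_policy") || !is_sequential_policy(policy)) {
    stop("'policy' must be a sequential threshold_policy", call. = FALSE)
  }
  check_index(n, "n")
  stopifnot(length(n) == 1L)
  if (is.null(rejections)) rejections <- rep(FALSE, n)
  stopifnot(is.logical(rejections), length(rejections) == n)
  # encode the intended rejection pattern as pseudo p-values: 0 rejects
  # under any positive threshold, 1 never rejects
  pseudo <- ifelse(rejections, 0, 1)
  th <- sequential_thresholds(policy, pseudo)
  data.frame(index = seq_len(n), threshold = th, cumulative = cumsum(th))
}

#' Write decisions to CSV
#'
#' Serialises a decision data frame (columns `index`, `threshold`,
#' `p_value`, `rejected`) as produced by [run_sequential()],
#' [bonferroni_reject()] or [bh_fdr_reject()].
#'
#' @param decisions a decision data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_decisions <- function(decisions, path) {
  stopifnot(all(c("index", "threshold", "p_value", "rejected") %in%
                  names(decisions)))
  utils::write.csv(decisions, path, row.names = FALSE)
  invisible(path)
}
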