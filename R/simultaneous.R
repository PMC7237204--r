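#' Bonferroni correction of a family of p-values
#'
#' Splits the familywise level over the `m` tests: every test is compared
#' against the common threshold `alpha / m`, with strict inequality
#' (`p < alpha / m` rejects). Equivalent to rejecting where the
#' Bonferroni-adjusted p-value from [stats::p.adjust()] falls strictly
#' below `alpha`; the adjusted route is used internally.
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (may be empty).
#' @param alpha familywise level in (0, 1).
#' @return a decision data frame with columns `index`, `threshold`,
#'   `p_value`, `rejected`, one row per input p-value in input order.
#' @examples
#' bonferroni_reject(c(0.001, 0.04), 0.05) # only the first rejected
#' @export
bonferroni_reject <- function(p_values, alpha = 0.05) {
  check_level(alpha, "alpha")
  check_pvalues(p_values)
  m <- length(p_values)
  if (m == 0L) {
    return(decision_frame(integer(0), numeric(0), numeric(0), logical(0)))
  }
  rejected <- stats::p.adjust(p_values, method = "bonferroni") < alpha
  decision_frame(seq_len(m), rep(alpha / m, m), p_values, rejected)
}

#' Benjamini-Hochberg step-up correction of a family of p-values
#'
#' The standard step-up procedure: with the p-values sorted ascending,
#' find the largest rank `r` with `p_(r) <= q * r / m` and reject every
#' test whose p-value is at most `p_(r)` (so tied p-values share the
#' outcome of their highest qualifying rank). The step-up comparison uses
#' `<=`, the procedure's canonical form. Implemented through the
#' Benjamini-Hochberg adjustment of [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (may be empty).
#' @param q target false discovery rate in (0, 1).
#' @return a decision data frame (see [bonferroni_reject()]) in input
#'   order; the `threshold` column holds the realised step-up cutoff
#'   `q * r / m` (0 when nothing is rejected).
#' @examples
#' bh_fdr_reject(c(0.001, 0.012, 0.9), 0.05)
#' @export
bh_fdr_reject <- function(p_values, q = 0.05) {
  check_level(q, "q")
  check_pvalues(p_values)
  m <- length(p_values)
  if (m == 0L) {
    return(decision_frame(integer(0), numeric(0), numeric(0), logical(0)))
  }
  rejected <- stats::p.adjust(p_values, method = "BH") <= q
  r <- sum(rejected)
  decision_frame(seq_len(m), rep(q * r / m, m), p_values, rejected)
}
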