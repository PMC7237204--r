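#' Threshold policies
#'
#' A threshold policy bundles the name of a significance-threshold procedure
#' with its parameters. Sequential policies (`"uncorrected"`, `"alpha_debt"`,
#' `"alpha_spending"`, `"alpha_investing"`) derive a threshold for each test
#' in a sequence; simultaneous policies (`"bonferroni"`, `"bh_fdr"`) correct
#' a whole family of p-values at once.
#'
#' Parameter meanings by policy:
#' \describe{
#'   \item{uncorrected}{`alpha`: the fixed per-test level (default 0.05).}
#'   \item{alpha_debt}{`alpha1`: the first-test level; the i-th test uses
#'     `alpha1 / i`, i.e. a Bonferroni correction for the `i` tests run so
#'     far. The familywise error is allowed to grow under a "debt ceiling",
#'     the running sum of the thresholds.}
#'   \item{alpha_spending}{`alpha0`: the total alpha-wealth; `s`: the
#'     fraction of the remaining wealth spent at each test (default 0.5).
#'     The sum of all thresholds ever spent stays strictly below `alpha0`.}
#'   \item{alpha_investing}{`w0`: the starting wealth; `omega`: the payout
#'     added to the wealth after each rejection (conventionally equal to
#'     the target level, default 0.05); `s`: the fraction of current wealth
#'     invested per test. On rejection the wealth rises by `omega`; on
#'     retention it falls by `alpha_i / (1 - alpha_i)`.}
#'   \item{bonferroni}{`alpha`: the familywise level split over `m` tests.}
#'   \item{bh_fdr}{`q`: the target false discovery rate of the
#'     Benjamini-Hochberg step-up procedure.}
#' }
#'
#' The alpha-investing update here follows the "reward on rejection, pay on
#' retention" form: a rejected test does not additionally pay its own
#' threshold before receiving the payout. Some literature variants deduct
#' the threshold in both branches; see the methods vignette.
#'
#' @param name one of `"uncorrected"`, `"alpha_debt"`, `"alpha_spending"`,
#'   `"alpha_investing"`, `"bonferroni"`, `"bh_fdr"`.
#' @param ... named policy parameters overriding the defaults above. All
#'   level/wealth/fraction parameters must lie in the open interval (0, 1).
#' @return an object of class `threshold_policy`: a list with elements
#'   `name` and `parameters`.
#' @examples
#' threshold_policy("alpha_debt", alpha1 = 0.05)
#' threshold_policy("alpha_investing", w0 = 0.05, omega = 0.05, s = 0.5)
#' @export
threshold_policy <- function(name = c("uncorrected", "alpha_debt",
                                      "alpha_spending", "alpha_investing",
                                      "bonferroni", "bh_fdr"),
                             ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    uncorrected     = list(alpha = 0.05),
    alpha_debt      = list(alpha1 = 0.05),
    alpha_spending  = list(alpha0 = 0.05, s = 0.5),
    alpha_investing = list(w0 = 0.05, omega = 0.05, s = 0.5),
    bonferroni      = list(alpha = 0.05),
    bh_fdr          = list(q = 0.05)
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) {
    stop("unknown parameter(s) for policy '", name, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  params <- utils::modifyList(defaults, override)
  for (nm in names(params)) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v <= 0 || v >= 1) {
      stop("policy parameter '", nm, "' must be a single number in (0, 1)",
           call. = FALSE)
    }
  }
  structure(list(name = name, parameters = params),
            class = "threshold_policy")
}

#' @export
print.threshold_policy <- function(x, ...) {
  cat("<threshold_policy> ", x$name, "\n", sep = "")
  p <- x$parameters
  cat(paste0("  ", names(p), " = ", unlist(p), collapse = "\n"), "\n")
  invisible(x)
}

#' Read a threshold policy from a JSON or YAML configuration block
#'
#' The block must contain a `"policy"` entry naming the procedure; all other
#' entries are passed as parameters, e.g.
#' `{"policy": "alpha_debt", "alpha1": 0.05}`.
#'
#' @param path path to a JSON (`.json`) or YAML (`.yml`/`.yaml`) file.
#' @return a [threshold_policy()].
#' @export
read_policy_config <- function(path) {
  cfg <- if (grepl("\\.(yml|yaml)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configuration requires the 'yaml' package",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$policy)) {
    stop("configuration must name a 'policy'", call. = FALSE)
  }
  do.call(threshold_policy,
          c(list(name = cfg$policy), cfg[setdiff(names(cfg), "policy")]))
}

is_sequential_policy <- function(policy) {
  policy$name %in% c("uncorrected", "alpha_debt", "alpha_spending",
                     "alpha_investing")
}

#' Alpha-debt threshold for the i-th sequential test
#'
#' The i-th sequential test applies a Bonferroni correction that counts all
#' `i` tests performed so far: the threshold is `alpha1 / i`. Earlier
#' decisions are never revisited, so the familywise error accumulates as a
#' controlled "debt" bounded by [debt_ceiling()].
#'
#' @param alpha1 first-test level, in (0, 1).
#' @param i sequential test index (vectorised over positive integers).
#' @return the threshold(s) `alpha1 / i`.
#' @examples
#' alpha_debt_threshold(0.05, 1:3) # 0.05 0.025 0.0166...
#' @export
alpha_debt_threshold <- function(alpha1, i) {
  check_level(alpha1, "alpha1")
  check_index(i, "i")
  alpha1 / i
}

#' Alpha-debt ceiling after t sequential tests
#'
#' The cumulative sum of the alpha-debt thresholds,
#' `sum(alpha1 / (1:t))` — `alpha1` times the t-th harmonic number. It is
#' the upper bound on the familywise error accumulated by the first `t`
#' tests: strictly increasing in `t`, with strictly decreasing increments.
#'
#' @param alpha1 first-test level, in (0, 1).
#' @param t number of sequential tests (vectorised over positive integers).
#' @return the debt ceiling(s).
#' @examples
#' debt_ceiling(0.05, 3) # 0.0916...
#' @export
debt_ceiling <- function(alpha1, t) {
  check_level(alpha1, "alpha1")
  check_index(t, "t")
  vapply(t, function(tt) sum(alpha1 / seq_len(tt)), numeric(1))
}

#' Initialise the state of a sequential policy
#'
#' The state is a ledger carried across sequential tests: the next test
#' index plus whatever wealth accounting the policy needs.
#'
#' @param policy a sequential [threshold_policy()].
#' @return an object of class `sequential_state`.
#' @export
sequential_state <- function(policy) {
  if (!inherits(policy, "threshold_policy") || !is_sequential_policy(policy)) {
    stop("'policy' must be a sequential threshold_policy", call. = FALSE)
  }
  p <- policy$parameters
  st <- switch(policy$name,
    uncorrected     = list(alpha = p$alpha),
    alpha_debt      = list(alpha1 = p$alpha1),
    alpha_spending  = list(alpha0 = p$alpha0, s = p$s,
                           remaining_wealth = p$alpha0, cumulative_spend = 0),
    alpha_investing = list(w0 = p$w0, omega = p$omega, s = p$s, wealth = p$w0)
  )
  st$policy <- policy$name
  st$test_index <- 1L
  structure(st, class = "sequential_state")
}

#' Next alpha-spending threshold
#'
#' Spends a fraction `s` of the remaining alpha-wealth: the threshold for
#' the current test is `s * remaining_wealth`, after which the remaining
#' wealth is reduced and the cumulative spend increased by that amount. For
#' any finite number of tests the total spend stays strictly below the
#' initial wealth `alpha0`.
#'
#' @param state a `sequential_state` for the `"alpha_spending"` policy.
#' @return a list with `threshold` and the advanced `state`.
#' @examples
#' st <- sequential_state(threshold_policy("alpha_spending", alpha0 = 0.05))
#' step <- alpha_spending_next(st) # threshold 0.025
#' alpha_spending_next(step$state) # threshold 0.0125
#' @export
alpha_spending_next <- function(state) {
  stopifnot(inherits(state, "sequential_state"),
            state$policy == "alpha_spending")
  if (state$remaining_wealth <= 0) {
    stop("alpha-wealth exhausted: remaining_wealth must be positive",
         call. = FALSE)
  }
  threshold <- state$s * state$remaining_wealth
  if (threshold < .Machine$double.xmin) threshold <- 0
  state$remaining_wealth <- state$remaining_wealth - threshold
  state$cumulative_spend <- state$cumulative_spend + threshold
  state$test_index <- state$test_index + 1L
  list(threshold = threshold, state = state)
}

#' One alpha-investing test
#'
#' Invests a fraction `s` of the current wealth `W` as the threshold
#' `alpha_i = s * W`. If the p-value falls below the threshold (rejection),
#' the wealth rises by the payout `omega`; otherwise it falls by
#' `alpha_i / (1 - alpha_i)`. With `0 < w0 < 1` and `s <= 0.5` the wealth
#' stays strictly positive after any retention, so the procedure can always
#' continue.
#'
#' @param state a `sequential_state` for the `"alpha_investing"` policy.
#' @param p_value the current test's p-value, in \[0, 1\].
#' @return a list with `decision` (a one-row decision data frame, see
#'   [run_sequential()]) and the advanced `state`.
#' @examples
#' st <- sequential_state(threshold_policy("alpha_investing"))
#' alpha_investing_step(st, 0.5)$state$wealth    # 0.05 - 0.025/0.975
#' alpha_investing_step(st, 0.001)$state$wealth  # 0.05 + 0.05
#' @export
alpha_investing_step <- function(state, p_value) {
  stopifnot(inherits(state, "sequential_state"),
            state$policy == "alpha_investing")
  check_pvalues(p_value)
  if (state$wealth <= 0) {
    stop("alpha-wealth exhausted: wealth must be positive", call. = FALSE)
  }
  threshold <- state$s * state$wealth
  if (threshold < .Machine$double.xmin) threshold <- 0
  rejected <- p_value < threshold
  state$wealth <- if (rejected) {
    state$wealth + state$omega
  } else {
    state$wealth - threshold / (1 - threshold)
  }
  decision <- decision_frame(state$test_index, threshold, p_value, rejected)
  state$test_index <- state$test_index + 1L
  list(decision = decision, state = state)
}

# shared input validation -----------------------------------------------

check_level <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    stop("'", name, "' must be a single number in (0, 1)", call. = FALSE)
  }
  invisible(x)
}

check_index <- function(i, name) {
  if (!is.numeric(i) || length(i) < 1L || any(!is.finite(i)) ||
      any(i < 1) || any(i != floor(i))) {
    stop("'", name, "' must be positive integer(s)", call. = FALSE)
  }
  invisible(i)
}

check_pvalues <- function(p) {
  if (length(p) && (!is.numeric(p) || any(!is.finite(p)) ||
                    any(p < 0) || any(p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

decision_frame <- function(index, threshold, p_value, rejected) {
  data.frame(index = as.integer(index), threshold = threshold,
             p_value = p_value, rejected = rejected)
}
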