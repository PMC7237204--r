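#' Configure the global-null simulation
#'
#' One dependent variable and `n_tests` independent variables are drawn
#' from a multivariate Gaussian with zero mean, unit variance and zero
#' covariance; each independent variable is tested against the dependent
#' variable with a two-tailed Pearson correlation. Repeating over
#' iterations estimates the familywise error rate of each sequential
#' procedure as the number of tests grows.
#'
#' @param n_obs observations per variable (>= 4 so the correlation test
#'   has at least 2 residual degrees of freedom).
#' @param n_tests number of independent variables / sequential tests.
#' @param n_iterations Monte-Carlo iterations.
#' @param alpha nominal level of the uncorrected test.
#' @param seed integer seed; every run with the same config reproduces the
#'   same results exactly.
#' @return an object of class `null_sim_config`.
#' @export
null_sim_config <- function(n_obs = 100, n_tests = 100, n_iterations = 1000,
                            alpha = 0.05, seed = 42L) {
  check_index(n_obs, "n_obs"); check_index(n_tests, "n_tests")
  check_index(n_iterations, "n_iterations")
  check_level(alpha, "alpha")
  if (n_obs < 4) stop("'n_obs' must be at least 4", call. = FALSE)
  structure(list(n_obs = as.integer(n_obs), n_tests = as.integer(n_tests),
                 n_iterations = as.integer(n_iterations), alpha = alpha,
                 seed = as.integer(seed), k_true = 0L, rho = 0, lam = 0),
            class = "null_sim_config")
}

#' Configure the ordered-effect simulation
#'
#' Extends the global-null design with `k_true` true-positive variables:
#' these and the dependent variable share a common pairwise covariance
#' `rho` (compound symmetry, positive semidefinite for `rho` in \[0, 1\]),
#' while the remaining variables stay independent of everything. The order
#' weight `lam` biases where in the test sequence the true positives land:
#' positive values place them earlier (odds `1 + lam : 1`), negative
#' values later.
#'
#' @inheritParams null_sim_config
#' @param k_true number of true-positive variables (1 to 10 in the study
#'   design; any value up to `n_tests` is accepted).
#' @param rho common covariance of the true-positive block, in \[0, 1\].
#' @param lam order weight in \[-1, 1\].
#' @return an object of classes `effect_sim_config` and `null_sim_config`.
#' @export
effect_sim_config <- function(n_obs = 100, n_tests = 100, n_iterations = 1000,
                              alpha = 0.05, seed = 42L,
                              k_true = 10, rho = 0.5, lam = 0) {
  cfg <- null_sim_config(n_obs, n_tests, n_iterations, alpha, seed)
  check_index(k_true, "k_true")
  if (k_true > cfg$n_tests) {
    stop("'k_true' cannot exceed 'n_tests'", call. = FALSE)
  }
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho > 1) {
    stop("'rho' must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(lam) || length(lam) != 1L || lam < -1 || lam > 1) {
    stop("'lam' must lie in [-1, 1]", call. = FALSE)
  }
  cfg$k_true <- as.integer(k_true); cfg$rho <- rho; cfg$lam <- lam
  class(cfg) <- c("effect_sim_config", class(cfg))
  cfg
}

#' Covariance matrix implied by a simulation configuration
#'
#' Unit variances everywhere; the dependent variable (column 1) and the
#' true-positive columns form a compound-symmetric block with off-diagonal
#' `rho`; all other covariances are zero. Eigenvalues of a
#' compound-symmetric block of size `b` are `1 + (b - 1) rho` and
#' `1 - rho`, so the matrix is positive semidefinite for `rho` in \[0, 1\].
#'
#' @param config a simulation config.
#' @param tp_columns 1-based column indices (within the independent
#'   variables, i.e. 1..n_tests) carrying the true-positive label;
#'   defaults to the first `k_true`.
#' @return a `(n_tests + 1) x (n_tests + 1)` covariance matrix whose first
#'   row/column is the dependent variable.
#' @export
implied_covariance <- function(config, tp_columns = seq_len(config$k_true)) {
  d <- config$n_tests + 1L
  sigma <- diag(d)
  if (config$k_true > 0L && config$rho > 0) {
    block <- c(1L, tp_columns + 1L)
    sigma[block, block] <- config$rho
    diag(sigma)[block] <- 1
  }
  sigma
}

#' Draw one dataset from a simulation configuration
#'
#' Samples `n_obs` rows from the multivariate Gaussian implied by the
#' config (see [implied_covariance()]). Column 1 is the dependent
#' variable; columns 2..(n_tests + 1) are the independent variables, with
#' the true positives in `tp_columns`. Sampling is by the Cholesky factor
#' of the compound-symmetric block, so only the (k_true + 1)-dimensional
#' block is ever factorised.
#'
#' @inheritParams implied_covariance
#' @return an `n_obs x (n_tests + 1)` numeric matrix.
#' @export
sample_dataset <- function(config, tp_columns = seq_len(config$k_true)) {
  n <- config$n_obs
  m <- config$n_tests
  k <- config$k_true
  z <- matrix(stats::rnorm(n * (m + 1L)), nrow = n)
  if (k == 0L || config$rho == 0) {
    return(z)
  }
  if (config$rho < 0 || config$rho > 1) {
    stop("implied covariance is not positive semidefinite", call. = FALSE)
  }
  b <- k + 1L
  sigma_block <- matrix(config$rho, b, b)
  diag(sigma_block) <- 1
  # chol() of a PSD compound-symmetric matrix; rho = 1 degenerates to a
  # rank-one block handled by the pivoted factorisation
  ch <- suppressWarnings(chol(sigma_block, pivot = TRUE))
  piv <- attr(ch, "pivot")
  rk <- attr(ch, "rank")
  correlated <- z[, seq_len(b), drop = FALSE][, seq_len(rk), drop = FALSE] %*%
    ch[seq_len(rk), order(piv), drop = FALSE]
  out <- z
  out[, 1L] <- correlated[, 1L]
  out[, tp_columns + 1L] <- correlated[, -1L, drop = FALSE]
  out
}

#' Two-tailed Pearson correlation p-value
#'
#' The textbook t-transform of the sample correlation:
#' `t = r * sqrt((n - 2) / (1 - r^2))` referred to a t-distribution with
#' `n - 2` degrees of freedom, two-tailed. Identical to
#' `stats::cor.test(x, y)$p.value`, which is used as the independent
#' cross-check in the test suite.
#'
#' @param x,y numeric vectors of equal length `n >= 4`, neither constant.
#' @return the two-tailed p-value.
#' @export
pearson_pvalue <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  drop(pearson_pvalues(x, matrix(y, ncol = 1)))
}

# Vectorised Pearson p-values of each column of `xs` against `dv`.
# r is clamped away from +/-1 only through the pmax on (1 - r^2).
pearson_pvalues <- function(dv, xs) {
  n <- length(dv)
  r <- drop(stats::cor(dv, xs))
  tsq <- r * r * (n - 2) / pmax(1 - r * r, .Machine$double.eps)
  2 * stats::pt(-sqrt(tsq), df = n - 2)
}

#' Assign true-positive positions in the test order
#'
#' Fills the sequence one position at a time. While both pools are
#' non-empty, the current position is a true positive with odds
#' `1 + lam : 1` when `lam >= 0` (probability `(1 + lam) / (2 + lam)`),
#' and with the mirrored odds `1 : 1 + |lam|` when `lam < 0`. Once a pool
#' empties, the rest of the other pool fills the tail.
#'
#' @param k_true number of true positives.
#' @param n_tests total sequence length.
#' @param lam order weight in \[-1, 1\].
#' @return a character vector of length `n_tests` over
#'   `c("true_positive", "true_negative")` containing exactly `k_true`
#'   true positives.
#' @export
assign_order <- function(k_true, n_tests, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || lam < -1 || lam > 1) {
    stop("'lam' must lie in [-1, 1]", call. = FALSE)
  }
  if (k_true < 0 || k_true > n_tests) {
    stop("'k_true' must lie in [0, n_tests]", call. = FALSE)
  }
  p_tp <- if (lam >= 0) (1 + lam) / (2 + lam) else 1 / (2 + abs(lam))
  labels <- character(n_tests)
  tp_left <- k_true
  tn_left <- n_tests - k_true
  for (i in seq_len(n_tests)) {
    if (tp_left == 0L) {
      labels[i] <- "true_negative"; tn_left <- tn_left - 1L
    } else if (tn_left == 0L) {
      labels[i] <- "true_positive"; tp_left <- tp_left - 1L
    } else if (stats::runif(1) < p_tp) {
      labels[i] <- "true_positive"; tp_left <- tp_left - 1L
    } else {
      labels[i] <- "true_negative"; tn_left <- tn_left - 1L
    }
  }
  labels
}

# Deterministic per-cell / per-stream seed derivation from a base seed.
# Keeps results of each grid cell independently reproducible.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %%
               2147483647)
}

#' Familywise error of sequential procedures under a global null
#'
#' For each iteration a null dataset is drawn, the `n_tests` ordered
#' Pearson p-values are computed once, and every policy thresholds the
#' same sequence. The familywise error at `m` is the fraction of
#' iterations with at least one rejection among the first `m` tests, so
#' each policy's curve is non-decreasing in `m`.
#'
#' @param config a [null_sim_config()].
#' @param policies a list of sequential [threshold_policy()] objects.
#' @return a long-format data frame with columns `policy`, `m`, `fwer`.
#' @export
run_null_experiment <- function(config,
                                policies = default_sequential_policies(
                                  config$alpha)) {
  stopifnot(inherits(config, "null_sim_config"))
  stopifnot(all(vapply(policies, is_sequential_policy, logical(1))))
  names(policies) <- vapply(policies, `[[`, character(1), "name")
  m <- config$n_tests
  # any_first_m[[policy]][iter, m]: cumulative any-rejection indicator
  any_rej <- lapply(policies, function(p)
    matrix(FALSE, config$n_iterations, m))
  set.seed(config$seed)
  for (iter in seq_len(config$n_iterations)) {
    dat <- sample_dataset(config)
    pvals <- pearson_pvalues(dat[, 1L], dat[, -1L, drop = FALSE])
    for (nm in names(policies)) {
      rej <- pvals < sequential_thresholds(policies[[nm]], pvals)
      any_rej[[nm]][iter, ] <- cumsum(rej) > 0
    }
  }
  out <- lapply(names(policies), function(nm)
    data.frame(policy = nm, m = seq_len(m),
               fwer = colMeans(any_rej[[nm]])))
  do.call(rbind, out)
}

#' The four sequential procedures at their default parameters
#'
#' @param alpha the level/wealth shared by all procedures (default 0.05).
#' @return a named list of [threshold_policy()] objects.
#' @export
default_sequential_policies <- function(alpha = 0.05) {
  list(
    uncorrected     = threshold_policy("uncorrected", alpha = alpha),
    alpha_debt      = threshold_policy("alpha_debt", alpha1 = alpha),
    alpha_spending  = threshold_policy("alpha_spending", alpha0 = alpha),
    alpha_investing = threshold_policy("alpha_investing", w0 = alpha,
                                       omega = alpha)
  )
}

#' Ordered-effect simulation over a (lambda, rho, k_true) grid
#'
#' For every grid cell, `n_iterations` datasets are drawn with the
#' configured true-positive block; each iteration assigns the
#' true-positive positions by the lambda-weighted rule ([assign_order()]),
#' computes the ordered Pearson p-values once, and thresholds them with
#' every sequential procedure in order plus the simultaneous Bonferroni
#' and Benjamini-Hochberg baselines over all tests at once. Counts of true
#' and false rejections are averaged into TPR, FPR and the
#' average-of-counts FDR (see [false_discovery_rate()]).
#'
#' @param lam_grid,rho_grid,k_grid grid values for the order weight, the
#'   true-positive covariance, and the number of true positives.
#' @param n_obs,n_iterations,alpha,seed shared simulation parameters (see
#'   [effect_sim_config()]); `n_tests` is fixed by `n_tests`.
#' @param n_tests number of independent variables.
#' @param policies sequential policies to evaluate.
#' @param include_simultaneous include the Bonferroni and BH baselines.
#' @return a long-format data frame with columns `policy`, `lambda`,
#'   `rho`, `k_true`, `metric` (`"tpr"`, `"fpr"`, `"fdr"`) and `value`.
#' @export
run_ordered_experiment <- function(lam_grid = seq(-1, 1, by = 0.25),
                                   rho_grid = seq(0, 1, by = 0.025),
                                   k_grid = 10,
                                   n_obs = 100, n_tests = 100,
                                   n_iterations = 1000, alpha = 0.05,
                                   seed = 42L,
                                   policies = default_sequential_policies(alpha),
                                   include_simultaneous = TRUE) {
  names(policies) <- vapply(policies, `[[`, character(1), "name")
  grid <- expand.grid(lambda = lam_grid, rho = rho_grid, k_true = k_grid,
                      KEEP.OUT.ATTRS = FALSE)
  sim_names <- if (include_simultaneous) c("bonferroni", "bh_fdr") else NULL
  all_names <- c(names(policies), sim_names)
  res <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- effect_sim_config(n_obs = n_obs, n_tests = n_tests,
                             n_iterations = n_iterations, alpha = alpha,
                             seed = derive_seed(seed, g),
                             k_true = grid$k_true[g], rho = grid$rho[g],
                             lam = grid$lambda[g])
    counts <- simulate_cell(cfg, policies, sim_names)
    avg_true <- colMeans(counts$true_rej)
    avg_false <- colMeans(counts$false_rej)
    res[[g]] <- data.frame(
      policy = rep(all_names, times = 3),
      lambda = grid$lambda[g], rho = grid$rho[g], k_true = grid$k_true[g],
      metric = rep(c("tpr", "fpr", "fdr"), each = length(all_names)),
      value = c(avg_true / cfg$k_true,
                avg_false / (cfg$n_tests - cfg$k_true),
                mapply(function(tr, fr) false_discovery_rate(tr, fr),
                       avg_true, avg_false)),
      row.names = NULL)
  }
  do.call(rbind, res)
}

# One grid cell: n_iterations draws, returning per-iteration true/false
# rejection counts for each procedure.
simulate_cell <- function(cfg, policies, sim_names) {
  all_names <- c(names(policies), sim_names)
  true_rej <- matrix(0L, cfg$n_iterations, length(all_names),
                     dimnames = list(NULL, all_names))
  false_rej <- true_rej
  set.seed(cfg$seed)
  for (iter in seq_len(cfg$n_iterations)) {
    labels <- assign_order(cfg$k_true, cfg$n_tests, cfg$lam)
    tp_cols <- which(labels == "true_positive")
    dat <- sample_dataset(cfg, tp_columns = tp_cols)
    pvals <- pearson_pvalues(dat[, 1L], dat[, -1L, drop = FALSE])
    is_tp <- labels == "true_positive"
    for (nm in names(policies)) {
      rej <- pvals < sequential_thresholds(policies[[nm]], pvals)
      true_rej[iter, nm] <- sum(rej & is_tp)
      false_rej[iter, nm] <- sum(rej & !is_tp)
    }
    if ("bonferroni" %in% all_names) {
      rej <- bonferroni_reject(pvals, cfg$alpha)$rejected
      true_rej[iter, "bonferroni"] <- sum(rej & is_tp)
      false_rej[iter, "bonferroni"] <- sum(rej & !is_tp)
    }
    if ("bh_fdr" %in% all_names) {
      rej <- bh_fdr_reject(pvals, cfg$alpha)$rejected
      true_rej[iter, "bh_fdr"] <- sum(rej & is_tp)
      false_rej[iter, "bh_fdr"] <- sum(rej & !is_tp)
    }
  }
  list(true_rej = true_rej, false_rej = false_rej)
}
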