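test_that("implied covariance is compound-symmetric over the true-positive block and PSD", {
  cfg <- effect_sim_config(k_true = 10, rho = 0.9, n_tests = 100)
  sigma <- implied_covariance(cfg)
  block <- sigma[1:11, 1:11]
  expect_equal(unname(diag(sigma)), rep(1, 101))
  expect_equal(unname(block[lower.tri(block)]), rep(0.9, 55))
  expect_equal(unname(sigma[1, 50]), 0)
  # eigen oracle of compound symmetry: 1 + (b - 1) rho and 1 - rho
  ev <- eigen(block, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(max(ev), 1 + 10 * 0.9)
  expect_equal(min(ev), 1 - 0.9)
  expect_gt(min(eigen(sigma, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
})

test_that("sampled datasets carry the configured covariance structure", {
  cfg <- effect_sim_config(n_obs = 20000, n_tests = 12, k_true = 4,
                           rho = 0.6, seed = 5)
  set.seed(cfg$seed)
  dat <- sample_dataset(cfg)
  emp <- cov(dat)
  # DV vs true positives around rho, vs true negatives around 0
  expect_equal(unname(emp[1, 2:5]), rep(0.6, 4), tolerance = 0.05)
  expect_equal(unname(emp[1, 6:13]), rep(0, 8), tolerance = 0.05)
  expect_equal(unname(diag(emp)), rep(1, 13), tolerance = 0.05)
  # agrees with the reference multivariate-normal sampler on moments
  ref <- MASS::mvrnorm(20000, mu = rep(0, 13),
                       Sigma = implied_covariance(cfg))
  expect_equal(mean(cov(ref)[1, 2:5]), mean(emp[1, 2:5]), tolerance = 0.05)
})

test_that("a null config and a zero-covariance effect config sample the same model", {
  cfg0 <- null_sim_config(n_obs = 500, n_tests = 5, seed = 9)
  cfg1 <- effect_sim_config(n_obs = 500, n_tests = 5, k_true = 3, rho = 0,
                            seed = 9)
  set.seed(9); a <- sample_dataset(cfg0)
  set.seed(9); b <- sample_dataset(cfg1)
  expect_identical(a, b)
})

test_that("degenerate rho = 1 still samples: the block collapses to one factor", {
  cfg <- effect_sim_config(n_obs = 200, n_tests = 6, k_true = 2, rho = 1,
                           seed = 2)
  set.seed(2)
  dat <- sample_dataset(cfg)
  expect_equal(cor(dat[, 1], dat[, 2]), 1, tolerance = 1e-10)
})

test_that("Pearson p-value reproduces cor.test and closed-form limits", {
  x <- rnorm(10, 0, 1)
  expect_lt(pearson_pvalue(x, x * 2 + 1), 1e-12)
  set.seed(3)
  for (rep in 1:25) {
    n <- sample(4:40, 1)
    a <- rnorm(n); b <- rnorm(n)
    expect_equal(pearson_pvalue(a, b), cor.test(a, b)$p.value)
  }
  # exactly zero correlation gives p = 1
  a <- c(-1, 0, 1, -1, 0, 1)
  b <- c(1, 0, 1, -1, 0, -1)   # cor = 0 by symmetry
  expect_equal(cor(a, b), 0)
  expect_equal(pearson_pvalue(a, b), 1)
  expect_error(pearson_pvalue(rep(1, 6), rnorm(6)), "constant")
  expect_error(pearson_pvalue(rnorm(5), rnorm(6)), "equal length")
})

test_that("the t-based p-value agrees with the exhaustive permutation null at n = 8", {
  set.seed(42)
  x <- rnorm(8)
  y <- 0.8 * x + rnorm(8)
  p_t <- pearson_pvalue(x, y)
  p_perm <- permutation_pvalue(x, y)
  expect_equal(p_t, p_perm, tolerance = 0.04)
})

test_that("lambda weights the odds of early true positives as 1 + lambda : 1", {
  set.seed(8)
  draws <- 4000
  first_label <- function(lam) {
    mean(replicate(draws,
                   assign_order(5, 100, lam)[1] == "true_positive"))
  }
  expect_equal(first_label(0), 0.5, tolerance = 0.03)
  expect_equal(first_label(1), 2 / 3, tolerance = 0.03)
  expect_equal(first_label(-1), 1 / 3, tolerance = 0.03)
  # exact pool bookkeeping regardless of lambda
  for (lam in c(-1, -0.3, 0, 0.7, 1)) {
    labels <- assign_order(7, 40, lam)
    expect_equal(sum(labels == "true_positive"), 7L)
    expect_equal(length(labels), 40L)
  }
  expect_error(assign_order(5, 100, 1.5), "\\[-1, 1\\]")
})

test_that("null-experiment FWER curves are monotone and match closed forms", {
  cfg <- null_sim_config(n_obs = 100, n_tests = 100, n_iterations = 300,
                         seed = 21)
  res <- run_null_experiment(cfg)
  for (pol in unique(res$policy)) {
    curve <- res$fwer[res$policy == pol]
    expect_true(all(diff(curve) >= 0))
  }
  # at m = 1 the FWER is the first threshold of each procedure
  # (three Monte-Carlo standard errors, absolute)
  at1 <- res[res$m == 1, ]
  se1 <- 3 * sqrt(0.05 * 0.95 / 300)
  expect_lt(abs(at1$fwer[at1$policy == "uncorrected"] - 0.05), se1)
  expect_lt(abs(at1$fwer[at1$policy == "alpha_debt"] - 0.05), se1)
  expect_lt(abs(at1$fwer[at1$policy == "alpha_spending"] - 0.025), se1)
  # identical config reproduces identical curves
  expect_identical(run_null_experiment(cfg), res)
})

test_that("ordered experiment: simultaneous baselines ignore lambda, sequential procedures do not", {
  res <- run_ordered_experiment(lam_grid = c(-1, 1), rho_grid = 0.6,
                                k_grid = 10, n_obs = 100,
                                n_iterations = 150, seed = 13)
  tpr <- res[res$metric == "tpr", ]
  pick <- function(pol, lam) tpr$value[tpr$policy == pol & tpr$lambda == lam]
  # Bonferroni and BH see all 100 p-values at once: lambda only relabels
  # positions, so their TPR moves only by Monte-Carlo noise
  expect_lt(abs(pick("bonferroni", -1) - pick("bonferroni", 1)), 0.08)
  expect_lt(abs(pick("bh_fdr", -1) - pick("bh_fdr", 1)), 0.08)
  # spending loses substantial power when true positives arrive later;
  # investing recoups wealth after its first hit, so for strong effects
  # its TPR is only required to be non-decreasing in lambda (within
  # Monte-Carlo error)
  expect_gt(pick("alpha_spending", 1), pick("alpha_spending", -1) + 0.1)
  for (pol in c("alpha_debt", "alpha_spending", "alpha_investing")) {
    expect_gte(pick(pol, 1), pick(pol, -1) - 0.05)
  }
  # uncorrected per-test FPR sits near the nominal level at any lambda
  fpr <- res[res$metric == "fpr" & res$policy == "uncorrected", ]
  expect_lt(max(abs(fpr$value - 0.05)), 0.015)
})

test_that("perfect correlation with early placement yields full power for every procedure", {
  res <- run_ordered_experiment(lam_grid = 1, rho_grid = 1, k_grid = 1,
                                n_obs = 100, n_iterations = 50, seed = 17)
  tpr <- res[res$metric == "tpr", ]
  expect_true(all(tpr$value > 0.95))
})
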