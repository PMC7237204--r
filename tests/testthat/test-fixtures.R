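test_that("fixture specs validate their inputs", {
  expect_error(fixture_spec(missing_rate = 0.7), "\\[0, 0.5\\)")
  expect_error(fixture_spec(n_subjects = 0), "positive integer")
  expect_error(fixture_spec(planted = data.frame(dependent = 200,
                                                 independent = 1,
                                                 beta = 1)),
               "out of range")
})

test_that("generation is deterministic and shaped as specified", {
  spec <- fixture_spec(n_subjects = 120, n_independent = 7,
                       n_dependent = 9, missing_rate = 0.1, seed = 14)
  a <- generate_study(spec)
  b <- generate_study(spec)
  expect_identical(a$table, b$table)
  expect_equal(dim(a$table), c(120L, 16L))
  expect_equal(a$manifest$dependent, paste0("dv_", 1:9))
  expect_equal(a$manifest$independent, paste0("iv_", 1:7))
  rate <- mean(is.na(as.matrix(a$table)))
  expect_equal(rate, 0.1, tolerance = 0.02)
})

test_that("a complete null table yields no pooled Bonferroni findings", {
  study <- make_toy_study(n_subjects = 400, n_independent = 10,
                          n_dependent = 20, seed = 99)
  models <- fit_all_models(study$table, study$manifest)
  expect_equal(nrow(baseline_simultaneous(models, "bonferroni", 0.05)), 0L)
})

test_that("a strongly planted effect is found by every procedure in every permutation", {
  study <- make_toy_study(n_subjects = 1000, n_independent = 10,
                          n_dependent = 20,
                          planted = data.frame(dependent = 4,
                                               independent = 2, beta = 1),
                          seed = 111)
  expect_equal(study$ground_truth$dependent, "dv_4")
  for (pol in c("alpha_debt", "alpha_spending", "alpha_investing")) {
    res <- run_pipeline(study$table, study$manifest,
                        threshold_policy(pol), n_permutations = 25,
                        seed = 4)
    expect_true(all(res$per_permutation$findings >= 1),
                info = pol)
    expect_true(all(res$per_permutation$positive_studies >= 1),
                info = pol)
  }
})

test_that("moderate planted effects are recovered by alpha-debt in nearly all permutations", {
  planted <- data.frame(dependent = c(3, 11), independent = c(1, 5),
                        beta = 0.5)
  study <- make_toy_study(n_subjects = 1000, n_independent = 12,
                          n_dependent = 15, planted = planted, seed = 123)
  res <- run_pipeline(study$table, study$manifest,
                      threshold_policy("alpha_debt"),
                      n_permutations = 40, seed = 5)
  expect_gte(mean(res$per_permutation$findings >= nrow(planted)), 0.95)
})

test_that("null tables keep the uncorrected sequential policy calibrated", {
  # per-test rejection frequency of p < 0.05 across many null models
  study <- make_toy_study(n_subjects = 200, n_independent = 8,
                          n_dependent = 40, seed = 321)
  models <- fit_all_models(study$table, study$manifest)
  pool <- unlist(lapply(models, `[[`, "p_values"))
  rate <- mean(pool < 0.05)
  se <- sqrt(0.05 * 0.95 / length(pool))
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("written studies round-trip through the pipeline readers", {
  study <- make_toy_study(n_subjects = 60, n_independent = 4,
                          n_dependent = 5, missing_rate = 0.1, seed = 222)
  dir <- withr::local_tempdir()
  paths <- write_study(study, dir)
  back <- read_study(paths$table, paths$manifest)
  expect_equal(back$table, study$table)
  expect_equal(back$manifest$dependent, study$manifest$dependent)
  expect_equal(back$manifest$independent, study$manifest$independent)
})
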