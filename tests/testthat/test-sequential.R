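test_that("run_sequential applies each policy's threshold schedule in order", {
  p <- c(0.001, 0.04)
  unc <- run_sequential(p, threshold_policy("uncorrected", alpha = 0.05))
  expect_equal(unc$rejected, c(TRUE, TRUE))

  debt <- run_sequential(p, threshold_policy("alpha_debt", alpha1 = 0.05))
  expect_equal(debt$threshold, c(0.05, 0.025))
  expect_equal(debt$rejected, c(TRUE, FALSE))

  empty <- run_sequential(numeric(0), threshold_policy("alpha_spending"))
  expect_equal(nrow(empty), 0L)

  expect_error(run_sequential(p, threshold_policy("bonferroni")),
               "not a sequential")
})

test_that("spending thresholds decay geometrically and sum below the wealth", {
  # 50 tests: long enough to show the geometric decay while the partial
  # sum 0.05 * (1 - 0.5^50) is still distinguishable from 0.05 in double
  # precision
  p <- rep(0.5, 50)
  d <- run_sequential(p, threshold_policy("alpha_spending", alpha0 = 0.05))
  expect_equal(d$threshold[1:2], c(0.025, 0.0125))
  expect_lt(sum(d$threshold), 0.05)
  expect_equal(sum(d$threshold), 0.05 * (1 - 0.5^50))
  # closed form vs an explicit state-machine walk
  st <- sequential_state(threshold_policy("alpha_spending"))
  walked <- numeric(10)
  for (i in 1:10) {
    step <- alpha_spending_next(st)
    walked[i] <- step$threshold
    st <- step$state
  }
  expect_equal(d$threshold[1:10], walked)
})

test_that("debt thresholds dominate spending thresholds at shared defaults", {
  i <- 1:500
  debt <- alpha_debt_threshold(0.05, i)
  spend <- run_sequential(rep(1, 500),
                          threshold_policy("alpha_spending"))$threshold
  expect_true(all(debt >= spend))
})

test_that("every Bonferroni rejection is also an alpha-debt rejection, in any order", {
  set.seed(11)
  for (rep in 1:20) {
    m <- sample(5:60, 1)
    p <- rbeta(m, 0.2, 2)
    bonf <- bonferroni_reject(p, 0.05)$rejected
    ord <- sample(m)
    debt <- run_sequential(p[ord], threshold_policy("alpha_debt"))$rejected
    debt_original_order <- debt[order(ord)]
    expect_true(all(debt_original_order[bonf]))
  }
})

test_that("investing thresholds respond to rejections and the sequence is deterministic", {
  p <- c(0.001, 0.5, 0.001, 0.9, 0.9)
  pol <- threshold_policy("alpha_investing")
  d <- run_sequential(p, pol)
  # first rejection pays out: next threshold is s * (w0 + omega)
  expect_equal(d$threshold[2], 0.5 * (0.05 + 0.05))
  # and the same run reproduces bit for bit
  expect_identical(run_sequential(p, pol), d)
  # matches the one-step API walked manually
  st <- sequential_state(pol)
  for (i in seq_along(p)) {
    step <- alpha_investing_step(st, p[i])
    expect_identical(step$decision$rejected, d$rejected[i])
    expect_equal(step$decision$threshold, d$threshold[i])
    st <- step$state
  }
})

test_that("underflowing thresholds clamp to zero and the run completes", {
  d <- run_sequential(rep(0.5, 5000), threshold_policy("alpha_spending"))
  expect_equal(nrow(d), 5000L)
  tail_thresholds <- d$threshold[4000:5000]
  expect_true(all(tail_thresholds == 0))
  expect_true(all(!d$rejected[4000:5000]))
})

test_that("threshold schedules expose cumulative debt and spend", {
  sched <- threshold_schedule(threshold_policy("alpha_debt"), 3)
  expect_equal(sched$threshold, c(0.05, 0.025, 0.05 / 3))
  expect_equal(sched$cumulative, debt_ceiling(0.05, 1:3))
  sched <- threshold_schedule(threshold_policy("alpha_spending"), 2)
  expect_equal(sched$threshold, c(0.025, 0.0125))
  # investing schedule with a planted rejection pattern
  sched <- threshold_schedule(threshold_policy("alpha_investing"), 2,
                              rejections = c(TRUE, FALSE))
  expect_equal(sched$threshold, c(0.025, 0.05))
})

test_that("decisions serialise to CSV and read back identically", {
  d <- run_sequential(c(0.03, 0.2, 0.004), threshold_policy("alpha_debt"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_decisions(d, path)
  back <- read.csv(path)
  expect_equal(back$rejected, d$rejected)
  expect_equal(back$threshold, d$threshold)
})
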