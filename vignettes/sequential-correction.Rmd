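---
title: "Sequential correction for reused datasets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential correction for reused datasets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqcorrect)
```

## The problem

A statistical family is the set of hypothesis tests over which a joint
error rate is controlled. Conventional corrections (Bonferroni,
Benjamini–Hochberg) assume the family is known when the analysis is run.
Dataset reuse breaks that assumption: each new analysis of a shared
dataset extends the family after earlier results are already published,
and no analyst is in a position to correct simultaneously over tests that
have not happened yet. `seqcorrect` implements threshold procedures that
act *sequentially* — each test i receives a level α_i that depends only on
the past — together with the simulation machinery needed to measure their
familywise error (FWER), true/false positive rates and false discovery
rate (FDR), and a mass-univariate pipeline applying them to tabular
studies.

## The procedures and their assumptions

All sequential procedures share two structural rules: a test rejects when
`p < α_i` (strict inequality, applied uniformly), and decisions are
immutable — a later test never revises an earlier one.

**Uncorrected.** α_i = α (default 0.05). The reference for what happens
when reuse is ignored: under a global null with independent tests the
FWER after m tests is 1 − (1 − α)^m.

**α-debt.** α_i = α₁ / i: the i-th test applies a Bonferroni correction
that counts the i tests performed so far. The FWER is not held below a
fixed level; it grows under the *debt ceiling* Σ_{j≤i} α₁/j (α₁ times a
harmonic number), which increases without bound but ever more slowly.
Because α₁/i ≥ α₁/m for every i ≤ m, any rejection made by a
simultaneous Bonferroni correction of the full family is also made by
α-debt in any order — α-debt's type II error is never worse than
Bonferroni's. This dominance is asserted as a property test.

**α-spending.** A wealth α₀ is fixed in advance; test i spends a fraction
s of the remaining wealth, so α_i = α₀ · s · (1 − s)^(i−1). The spent sum
is strictly below α₀ for any finite number of tests, which bounds the
FWER below α₀ by the union bound. With the default s = 0.5 the first two
tests use 75% of the wealth — thresholds decay geometrically, so late
tests are nearly powerless.

**α-investing.** Test i invests α_i = s · W_{i−1} of its current wealth.
On rejection the wealth *rises* by a payout ω; on retention it falls by
α_i / (1 − α_i). The procedure targets the marginal false discovery rate
rather than the FWER, and its thresholds adapt: early discoveries buy
power for later tests. Two conventions needed fixing where the procedure
is stated loosely in the literature:

* the rejection branch does **not** additionally deduct α_i before the
  payout (some variants deduct in both branches; the update here is
  exactly `W_i = W_{i−1} + ω`). Users comparing against other
  implementations should check this convention first;
* with 0 < W₀ < 1 and s ≤ 0.5 the retention update keeps the wealth
  strictly positive (it maps W to W(1 − s/(1 − sW)) > 0), so the
  procedure never hard-stops; this is covered by a property test.

**Simultaneous baselines.** Bonferroni rejects at α/m; Benjamini–Hochberg
is the standard step-up: sort the p-values, find the largest rank r with
p\_(r) ≤ q·r/m, reject everything at or below p\_(r). The step-up
comparison keeps its canonical `≤` (while sequential rejection is
strict), and tied p-values share the outcome of their highest qualifying
rank. Both are delegated to `stats::p.adjust`; the test suite checks the
step-up against an independent exhaustive-rank enumeration on families up
to length 10.

### Numerical choices

Thresholds that fall below the smallest positive double are clamped to 0:
such a test can never reject, but a 10,000-test sequence still runs to
completion rather than underflowing into denormals or errors. A level of
1 or more (possible for α-investing after a long run of payouts) is
capped just below 1 before being used as a within-model correction level.
Uncorrected, α-debt and α-spending threshold schedules are computed in
closed form; α-investing walks the sequence because each threshold
depends on earlier outcomes.

## The two simulation designs

**Global-null FWER.** Each iteration draws `n_obs` observations of one
dependent and `n_tests` independent variables, all standard Gaussian with
zero covariance, and tests each independent variable against the
dependent one with a two-tailed Pearson correlation (the textbook
t-transform on n − 2 degrees of freedom, cross-checked in the tests
against `cor.test` and an exhaustive permutation null). The FWER at m is
the fraction of iterations with at least one rejection among the first m
tests. All policies threshold the *same* p-value sequence within an
iteration, mirroring the comparative design the procedures are meant for.

**Ordered effects.** `k_true` of the independent variables become true
positives: they and the dependent variable receive a common pairwise
covariance ρ (compound symmetry — eigenvalues 1 + (b−1)ρ and 1 − ρ for a
block of size b, hence positive semidefinite exactly on ρ ∈ [0, 1]).
Sampling factorises only the (k+1)-dimensional block with a pivoted
Cholesky, so ρ = 1 (a rank-one block) degenerates gracefully. The order
weight λ ∈ [−1, 1] controls where true positives land in the test
sequence: while both label pools are non-empty, the next position is a
true positive with odds (1+λ):1 for λ ≥ 0, mirrored for λ < 0, and the
surviving pool fills the tail.

One consequence of this assignment rule deserves emphasis: the odds are
independent of pool sizes, so with k_true = 10 among 100 tests the
true-positive pool is usually exhausted within the first ~30 positions
*even at λ = −1* (each position still has probability 1/3). λ therefore
shifts power most visibly for procedures whose thresholds decay fast
(α-spending) and near the noise floor; α-investing, which replenishes
wealth at its first hit, is nearly insensitive to λ when effects are
strong. The property tests assert monotonicity in λ within Monte-Carlo
error rather than a fixed gap.

**Metrics.** TPR and FPR are averages of per-iteration counts scaled by
k_true and n_tests − k_true. FDR uses the averages-of-counts form,
average false rejections / average discoveries, with 0 when there are no
discoveries at all; this sidesteps per-iteration 0/0 and matches how the
quadrant summaries are consumed. Quadrants split the (λ, ρ) grid at λ = 0
and a covariance "noise floor" of ρ = 0.25 — Q1: λ < 0, ρ > 0.25; Q2:
λ > 0, ρ > 0.25; Q3/Q4 the low-covariance counterparts — with boundary
cells excluded (strict inequalities).

### Parameters and problem sizes

* `n_obs = 100` observations per variable. The number is a package
  choice: it puts the detection boundary of a two-tailed Pearson test
  near ρ ≈ 0.25, i.e. at the quadrant noise floor, which makes the
  quadrant summaries informative.
* `n_tests = 100`, `n_iterations = 1000` for the null design; the
  ordered design defaults to a λ grid of −1…1 in steps of 0.25 and the
  full ρ grid 0…1 in steps of 0.025. The test suite and acceptance
  script run a reduced ordered grid (λ ∈ {±0.5, ±1}, ρ ∈ 0.3…0.95 in
  steps of 0.05, 200 iterations per cell — 11,200 iterations) chosen to
  estimate the Q1/Q2 averages with per-quadrant standard errors well
  below the 0.05 landmark.
* Seeds: one base seed per experiment; each grid cell derives its own
  seed from the base seed and the cell index by a fixed linear
  congruential map, so any cell can be reproduced in isolation and
  results are bit-identical across runs.

As measured by the acceptance computations, Bonferroni, BH, α-debt and
α-spending keep the Q1/Q2 average FDR below 0.05, while α-investing sits
marginally *above* the 0.05 mark (≈ 0.05–0.06). That is expected
behaviour, not a defect: investing's guarantee is on the marginal FDR
E[V]/(E[R]+1), which the same runs do keep below 0.05; the ratio of
averages E[V]/E[R] reported here is slightly larger by construction.

## The mass-univariate pipeline

The empirical design is one OLS model per dependent variable with all
independent variables as joint regressors — so a study with 182 outcomes
and 68 predictors registers 182 × 68 = 12,376 coefficient tests. Columns
are standardised first (sample n−1 standard deviation on non-missing
entries, missing cells preserved), then rows with a missing value in any
variable of a given model are dropped for that model only. Models include
an intercept; with standardised variables it is ≈ 0 and harmless, and
dropping it would silently change the residual degrees of freedom.

The hybrid correction walks the models in a given order: the sequential
policy supplies the level α_i for the i-th model, and the model's
coefficient p-values are corrected *within the model* by BH (or
Bonferroni) at that level. One model is one sequential step — the
sequential family is "analyses", not individual coefficients. For
α-investing, the model counts as a rejection (earning the payout) when it
yields at least one within-model finding; the procedure is defined on a
single test per step, and "any finding in the study" is the natural
model-level analogue.

Orders are randomised `n_permutations = 100` times, either uniformly or
"informed": dependents that were significant under *either* pooled
simultaneous baseline form a positive pool, and each position is drawn
from the positive or negative pool with probability ½ until one pool
empties. Reported are the mean, standard deviation, minimum and maximum
of the number of findings and of positive studies (models with ≥ 1
finding) across permutations.

## What the synthetic fixtures do and do not emulate

`fixture_spec()`/`generate_study()` reproduce the *shape* of a large
shared study: a 1000 × (182 + 68) table, iid Gaussian predictors,
outcomes that are linear in a few planted predictors plus unit noise, and
completely-at-random missingness. They deliberately do not model
correlated predictors (real morphometric estimates are strongly
inter-correlated), correlated outcomes, non-Gaussian scales, or
informative missingness. Passing tests on these fixtures therefore
validate the *correction logic* — threshold bookkeeping, order
sensitivity, baseline dominance, planted-effect recovery — not the
field-specific behaviour of any real dataset; on real data with
correlated regressors, per-coefficient power and the informativeness of
the "informed" order will differ.

## Known limitations

* α-debt's FWER is unbounded by design; the debt ceiling is a budget
  statement, not a guarantee.
* The FDR reported from simulations is a ratio of averages, not the
  expectation of the per-iteration ratio; the two differ when discovery
  counts are small.
* α-investing here is the fixed-fraction variant only; generalised
  investing schedules and modern online-FDR procedures are out of scope.
* The pipeline treats the variable roles as given; preparing variables
  (e.g. preferring age-adjusted versions) belongs to manifest
  construction, upstream of the package.
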