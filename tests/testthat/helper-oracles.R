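# Independent oracles used across the suite. These deliberately use
# direct enumeration / naive arithmetic rather than the package's own
# code paths.

# Benjamini-Hochberg step-up by exhaustive rank enumeration: for every
# rank r check p_(r) <= q r / m, take the largest qualifying rank, and
# reject all tests with p <= p_(r).
bh_brute_force <- function(p, q) {
  m <- length(p)
  if (m == 0L) return(logical(0))
  ps <- sort(p)
  qualifying <- which(ps <= q * seq_len(m) / m)
  if (length(qualifying) == 0L) return(rep(FALSE, m))
  p <= ps[max(qualifying)]
}

# All permutations of seq_len(n), as an (n! x n) matrix, by inserting n
# at every position of every permutation of n - 1 elements.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- append(sub[r, ], n, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

# Exact two-sided permutation p-value for the Pearson correlation of x, y
# by full enumeration over permutations of y (feasible up to n = 8).
permutation_pvalue <- function(x, y) {
  perms <- all_permutations(length(y))
  robs <- abs(cor(x, y))
  rs <- abs(apply(perms, 1L, function(idx) cor(x, y[idx])))
  mean(rs >= robs - 1e-12)
}

# A small deterministic study fixture shared by pipeline tests.
make_toy_study <- function(n_subjects = 300, n_independent = 8,
                           n_dependent = 12, planted = NULL,
                           missing_rate = 0, seed = 1234L) {
  generate_study(fixture_spec(n_subjects = n_subjects,
                              n_independent = n_independent,
                              n_dependent = n_dependent,
                              planted = planted,
                              missing_rate = missing_rate, seed = seed))
}
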