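test_that("Friedman test matches the rank formula and the identical-column case", {
  ident <- matrix(rep(c(1, 2, 3, 4, 5, 6), 4), ncol = 4)
  f0 <- friedman_ranks(ident)
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p_value, 1)

  set.seed(61)
  for (rep in 1:6) {
    x <- matrix(stats::rnorm(6 * 4), 6, 4)
    f <- friedman_ranks(x)
    expect_equal(f$statistic, oracle_friedman_stat(x), tolerance = 1e-12)
  }
})

test_that("Friedman statistic agrees with the stats-package implementation", {
  set.seed(62)
  # tie-free continuous data: no tie correction, both formulations coincide
  x <- matrix(stats::rnorm(12 * 4), 12, 4)
  f <- friedman_ranks(x)
  ref <- stats::friedman.test(x)
  expect_equal(f$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(stats::pchisq(f$statistic, 3, lower.tail = FALSE),
               ref$p.value, tolerance = 1e-12)
})

test_that("exact Friedman null matches full enumeration at small n", {
  # brute force: enumerate all (4!)^3 within-block orderings for n = 3
  perms <- as.matrix(expand.grid(1:24, 1:24, 1:24))
  all_orders <- breastplanr:::permutations_of(1:4)
  set.seed(68)
  x <- matrix(stats::rnorm(3 * 4), 3, 4)
  f <- friedman_ranks(x, n_exact = 8)
  expect_identical(f$method, "exact")
  stat_of <- function(r) 12 * 3 / (4 * 5) * sum((colMeans(r) - 2.5)^2)
  t_obs <- stat_of(t(apply(x, 1, rank)))
  ge <- 0
  for (i in seq_len(nrow(perms))) {
    r <- all_orders[unlist(perms[i, ]), ]
    if (stat_of(r) >= t_obs - 1e-9) ge <- ge + 1
  }
  expect_equal(f$p_value, ge / nrow(perms), tolerance = 1e-12)
})

test_that("chi-square approximation tracks the exact null at n = 8", {
  set.seed(63)
  devs <- replicate(5, {
    x <- matrix(stats::rnorm(8 * 4), 8, 4)
    f <- friedman_ranks(x, n_exact = 8)
    stopifnot(f$method == "exact")
    abs(f$p_value - stats::pchisq(f$statistic, 3, lower.tail = FALSE))
  })
  # discreteness of the permutation null dominates mid-range p-values;
  # the approximation stays within a few percent everywhere
  expect_lt(max(devs), 0.05)
  expect_lt(mean(devs), 0.04)
})

test_that("Wilcoxon exact p equals full sign-flip enumeration", {
  set.seed(64)
  for (n in c(5, 7, 10)) {
    for (rep in 1:4) {
      x <- stats::rnorm(n); y <- stats::rnorm(n)
      w <- wilcoxon_signed_rank(x, y)
      expect_identical(w$method, "exact")
      expect_equal(w$p_value, oracle_wilcoxon_p(x, y), tolerance = 1e-12)
    }
  }
  # with ties in |differences| the mid-rank DP must match enumeration too
  x <- c(5, 4, 7, 1, 9, 8)
  y <- c(3, 6, 5, 2, 4, 8)   # diffs 2 -2 2 -1 5 0: zero dropped, tied |2|s
  w <- wilcoxon_signed_rank(x, y)
  expect_equal(w$n_used, 5L)
  expect_equal(w$p_value, oracle_wilcoxon_p(x, y), tolerance = 1e-12)
})

test_that("Wilcoxon agrees with the stats-package exact test when tie-free", {
  set.seed(65)
  x <- stats::rnorm(12); y <- stats::rnorm(12)
  w <- wilcoxon_signed_rank(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(w$statistic, unname(ref$statistic))
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("normal approximation is used beyond the exact cutoff", {
  set.seed(66)
  x <- stats::rnorm(40); y <- stats::rnorm(40)
  w <- wilcoxon_signed_rank(x, y)
  expect_identical(w$method, "normal")
  expect_gte(w$p_value, 0)
  expect_lte(w$p_value, 1)
})

test_that("Bonferroni adjustment is capped and never below raw p", {
  p <- c(0.001, 0.04, 0.2, 0.9)
  adj <- bonferroni(p, 6)
  expect_equal(adj, pmin(1, 6 * p))
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
})

test_that("the comparison chain gates post-hoc tests on the omnibus", {
  ident <- matrix(rep(stats::rnorm(8), 4), ncol = 4,
                  dimnames = list(NULL, c("CS_CP", "DLS_DLP", "CS_DLP", "PS_DLP")))
  r0 <- compare_setups(ident)
  expect_null(r0$posthoc)
  expect_equal(r0$friedman$statistic, 0)
  expect_equal(nrow(r0$shapiro), 6)

  set.seed(67)
  base <- stats::rnorm(20)
  x <- cbind(CS_CP = base, DLS_DLP = base - 2 + stats::rnorm(20, 0, 0.1),
             CS_DLP = base + stats::rnorm(20, 0, 0.1),
             PS_DLP = base + 1 + stats::rnorm(20, 0, 0.1))
  r <- compare_setups(x)
  expect_false(is.null(r$posthoc))
  expect_equal(nrow(r$posthoc), 6)
  expect_equal(r$posthoc$p_adj, pmin(1, 6 * r$posthoc$p_raw))
  expect_error(compare_setups(x[1:4, ]), "at least 5")
})
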