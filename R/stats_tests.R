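# Paired nonparametric comparison chain used for the four plan setups:
# Shapiro-Wilk normality gate on pairwise differences (descriptive),
# Friedman omnibus across the k setups, and -- only when the omnibus is
# significant -- all pairwise Wilcoxon signed-rank tests with Bonferroni
# correction over the pair family.

# mid-ranks of a vector
midranks <- function(x) rank(x, ties.method = "average")

#' Friedman rank test for k paired columns
#'
#' Statistic `12 n / (k (k+1)) * sum_j (Rbar_j - (k+1)/2)^2` over per-block
#' mid-ranks (no tie correction). The p-value uses the chi-square
#' approximation with `k - 1` degrees of freedom; for `n <= n_exact`
#' tie-free blocks the exact permutation null (all within-block orderings
#' equally likely) is computed by dynamic programming over column rank-sum
#' vectors.
#'
#' @param x numeric matrix or data.frame, rows = blocks (patients),
#'   columns = treatments (plan setups).
#' @param n_exact use the exact null when `nrow(x) <= n_exact` and no
#'   block has ties (default 8).
#' @return list `statistic`, `df`, `p_value`, `method` ("exact" or
#'   "chisq").
#' @export
friedman_ranks <- function(x, n_exact = 8) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need at least 2 blocks and 2 columns")
  if (anyNA(x)) stop("missing values in comparison matrix")
  r <- t(apply(x, 1L, midranks))
  rbar <- colMeans(r)
  stat <- 12 * n / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
  has_ties <- any(apply(x, 1L, function(row) anyDuplicated(row) > 0L))
  if (n <= n_exact && !has_ties) {
    p <- friedman_exact_p(colSums(r), n, k)
    list(statistic = stat, df = k - 1L, p_value = p, method = "exact")
  } else {
    list(statistic = stat, df = k - 1L,
         p_value = stats::pchisq(stat, k - 1L, lower.tail = FALSE),
         method = "chisq")
  }
}

# exact permutation p-value P(T >= T_obs): DP over blocks on sorted column
# rank-sum vectors (the statistic is symmetric in columns, so states can be
# canonicalised by sorting)
friedman_exact_p <- function(obs_sums, n, k) {
  perms <- permutations_of(seq_len(k))
  t_of <- function(s) 12 / (n * k * (k + 1)) * sum(s^2) - 3 * n * (k + 1)
  t_obs <- t_of(obs_sums)
  states <- new.env(parent = emptyenv())
  assign(paste(rep(0L, k), collapse = ","), 1, envir = states)
  for (b in seq_len(n)) {
    nxt <- new.env(parent = emptyenv())
    for (key in ls(states)) {
      s <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
      w <- get(key, envir = states)
      for (p in seq_len(nrow(perms))) {
        s2 <- sort(s + perms[p, ])
        k2 <- paste(s2, collapse = ",")
        prev <- if (exists(k2, envir = nxt, inherits = FALSE))
          get(k2, envir = nxt) else 0
        assign(k2, prev + w, envir = nxt)
      }
    }
    states <- nxt
  }
  total <- 0; ge <- 0
  for (key in ls(states)) {
    s <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
    w <- get(key, envir = states)
    total <- total + w
    if (t_of(s) >= t_obs - 1e-9) ge <- ge + w
  }
  ge / total
}

permutations_of <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], permutations_of(v[-i])))
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences of exactly zero are dropped; absolute differences are
#' mid-ranked; the statistic is the sum of ranks of the positive
#' differences. For `n <= n_exact` retained pairs the exact two-sided
#' p-value is computed from the full sign-flip null (a generating-function
#' convolution over doubled ranks, valid with ties); otherwise the normal
#' approximation with tie-corrected variance is used.
#'
#' @param x,y paired numeric vectors.
#' @param n_exact exact-null cutoff on retained pairs (default 25).
#' @return list `statistic` (V), `n_used`, `p_value`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, n_exact = 25) {
  if (length(x) != length(y)) stop("x and y differ in length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, n_used = 0L, p_value = 1, method = "degenerate"))
  r <- midranks(abs(d))
  v <- sum(r[d > 0])
  if (n <= n_exact) {
    p <- wilcoxon_exact_p(r, v)
    list(statistic = v, n_used = n, p_value = p, method = "exact")
  } else {
    mu <- n * (n + 1) / 4
    tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
    z <- (v - mu) / sqrt(sig2)
    list(statistic = v, n_used = n,
         p_value = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
  }
}

# exact two-sided p for statistic v given mid-ranks r: distribution of
# sum(2r) over all 2^n sign assignments via integer convolution
wilcoxon_exact_p <- function(r, v) {
  r2 <- as.integer(round(2 * r))
  s <- sum(r2)
  cnt <- numeric(s + 1L)  # counts for doubled statistic 0..s
  cnt[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), cnt[seq_len(s + 1L - ri)])
    cnt <- cnt + shifted
  }
  total <- sum(cnt)
  v2 <- round(2 * v)
  p_le <- sum(cnt[seq_len(v2 + 1L)]) / total
  p_ge <- sum(cnt[(v2 + 1L):(s + 1L)]) / total
  min(1, 2 * min(p_le, p_ge))
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)`; never below the raw p.
#'
#' @param p raw p-values.
#' @param m family size.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, m) pmin(1, m * p)

#' Paired comparison of the plan setups on one metric
#'
#' Runs the full testing chain on an `n x k` matrix of one evaluation
#' metric across the k setups: Shapiro-Wilk normality p-values on every
#' pairwise difference (reported descriptively -- the chain always
#' proceeds nonparametrically), the Friedman omnibus test, and, only when
#' the omnibus p is below `alpha`, all pairwise Wilcoxon signed-rank tests
#' with Bonferroni correction over the pair family.
#'
#' @param values numeric matrix/data.frame, rows = patients, named columns
#'   = setups.
#' @param alpha omnibus significance level (default 0.05).
#' @param bonferroni_m family size for the correction; defaults to the
#'   number of pairs.
#' @return list of class `setup_comparison`: `shapiro` (data.frame),
#'   `friedman`, `posthoc` (data.frame or NULL), `alpha`.
#' @export
compare_setups <- function(values, alpha = 0.05, bonferroni_m = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 5L) stop("need at least 5 patients")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("setup", seq_len(ncol(values)))
  k <- ncol(values)
  pairs <- utils::combn(k, 2)
  m <- if (is.null(bonferroni_m)) ncol(pairs) else bonferroni_m
  shapiro <- data.frame(
    pair = apply(pairs, 2, function(ij)
      paste(colnames(values)[ij], collapse = " vs ")),
    shapiro_p = apply(pairs, 2, function(ij) {
      d <- values[, ij[1]] - values[, ij[2]]
      if (length(unique(d)) < 3L) NA_real_ else stats::shapiro.test(d)$p.value
    }),
    stringsAsFactors = FALSE
  )
  fr <- friedman_ranks(values)
  posthoc <- NULL
  if (fr$p_value < alpha) {
    posthoc <- data.frame(
      pair = shapiro$pair,
      v = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
      stringsAsFactors = FALSE
    )
    for (j in seq_len(ncol(pairs))) {
      w <- wilcoxon_signed_rank(values[, pairs[1, j]], values[, pairs[2, j]])
      posthoc$v[j] <- w$statistic
      posthoc$p_raw[j] <- w$p_value
    }
    posthoc$p_adj <- bonferroni(posthoc$p_raw, m)
  }
  structure(list(shapiro = shapiro, friedman = fr, posthoc = posthoc,
                 alpha = alpha, n = nrow(values)),
            class = "setup_comparison")
}

#' @export
print.setup_comparison <- function(x, ...) {
  cat(sprintf("Friedman chi^2 = %.3f (df %d), p = %.4g [%s], n = %d\n",
              x$friedman$statistic, x$friedman$df, x$friedman$p_value,
              x$friedman$method, x$n))
  if (is.null(x$posthoc)) {
    cat("omnibus not significant at alpha =", x$alpha,
        "-- no post-hoc tests\n")
  } else {
    cat("post-hoc Wilcoxon signed-rank (Bonferroni-adjusted):\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}
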