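# Independent brute-force oracles and small fixture builders. Oracles are
# deliberately naive (loops, full enumeration, sorting) and share no code
# with the implementation paths they check.

rand_dose_grid <- function(shape, spacing = c(2, 2, 2), lo = 0, hi = 50) {
  dose_grid(array(stats::runif(prod(shape), lo, hi), dim = shape), spacing)
}

# random connected-ish blob: union of a few random balls, at least 1 voxel
rand_blob_mask <- function(shape, spacing = c(2, 2, 2), n_balls = 3,
                           name = "blob") {
  coords <- lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing[a])
  m <- array(FALSE, shape)
  for (b in seq_len(n_balls)) {
    c0 <- vapply(1:3, function(a) stats::runif(1, 0, max(coords[[a]])),
                 numeric(1))
    r <- stats::runif(1, min(spacing), 0.45 * min(shape * spacing))
    d2 <- outer(outer((coords[[1]] - c0[1])^2, (coords[[2]] - c0[2])^2, "+"),
                (coords[[3]] - c0[3])^2, "+")
    m <- m | (d2 <= r^2)
  }
  if (!any(m)) m[ceiling(shape[1] / 2), ceiling(shape[2] / 2),
                 ceiling(shape[3] / 2)] <- TRUE
  struct_mask(m, spacing, name = name)
}

# --- DVH oracles -------------------------------------------------------

# cumulative volume fraction at dose d by direct counting
oracle_cum_volume <- function(doses, d) sum(doses >= d) / length(doses)

# minimum dose of the hottest p% of voxels by sorting
oracle_d_percent <- function(doses, p) {
  s <- sort(doses, decreasing = TRUE)
  s[max(1L, ceiling(length(s) * p / 100))]
}

# --- surface / distance oracles ---------------------------------------

# exhaustive 6-neighbour scan with explicit loops
oracle_surface_idx <- function(a) {
  dm <- dim(a)
  out <- NULL
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (!a[i, j, k]) next
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    on_surface <- FALSE
    for (q in nb) {
      if (any(q < 1) || q[1] > dm[1] || q[2] > dm[2] || q[3] > dm[3] ||
          !a[q[1], q[2], q[3]]) {
        on_surface <- TRUE
        break
      }
    }
    if (on_surface) out <- rbind(out, c(i, j, k))
  }
  out
}

# O(n^2) nearest distances: one explicit loop over A, full scan of B
oracle_nn_distances <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i) {
    sqrt(min((A[i, 1] - B[, 1])^2 + (A[i, 2] - B[, 2])^2 +
               (A[i, 3] - B[, 3])^2))
  }, numeric(1))
}

oracle_seg_metrics <- function(a, b, tau = 3) {
  sa <- surface_points(a)
  sb <- surface_points(b)
  dab <- oracle_nn_distances(sa, sb)
  dba <- oracle_nn_distances(sb, sa)
  list(
    vdsc = 2 * sum(a$membership & b$membership) /
      (sum(a$membership) + sum(b$membership)),
    sdsc = (sum(dab <= tau + 1e-9) + sum(dba <= tau + 1e-9)) /
      (length(dab) + length(dba)),
    hd95 = max(stats::quantile(dab, 0.95, type = 7, names = FALSE),
               stats::quantile(dba, 0.95, type = 7, names = FALSE))
  )
}

# --- statistics oracles ------------------------------------------------

# Friedman statistic straight from the rank formula
oracle_friedman_stat <- function(x) {
  n <- nrow(x); k <- ncol(x)
  r <- t(apply(x, 1, rank))
  rbar <- colMeans(r)
  12 * n / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
}

# exact two-sided Wilcoxon signed-rank p by full 2^n sign-flip enumeration
oracle_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs + 1e-12)
  p_ge <- mean(v_all >= v_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

# small evaluation table for workflow tests
toy_evals <- function(goals_dls, goals_ps, n = length(goals_dls)) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(c("CS_CP", "DLS_DLP", "CS_DLP", "PS_DLP"),
      function(s) data.frame(
        patient_id = sprintf("P%03d", i), setup = s,
        ptv_dmean = 40.3, ptv_d98 = 38.1, ptv_d2 = 42.1,
        lungs_dmean = 2.3, heart_dmean = 1.1, breastcl_dmean = 0.3,
        goals_met = switch(s, DLS_DLP = goals_dls[i], PS_DLP = goals_ps[i], 6L),
        tcp = 0.96, aer_w = 0.7, aer_wo = 0.4, aemr_cardiac_w = 0.4,
        aemr_cardiac_wo = 0.1, aemr_lung_w = 2.3, aemr_lung_wo = 0.1,
        stringsAsFactors = FALSE)))
  }))
}

voxel_idx_to_mm <- function(idx, m)
  sweep(sweep(idx - 1, 2, m$spacing, "*"), 2, m$origin, "+")

add_routes_for_test <- function(ev) breastplanr:::add_routes(ev)

# content fingerprint of a text file (no external digest dependency)
digest_file_lines <- function(f) paste(readLines(f), collapse = "\n")
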