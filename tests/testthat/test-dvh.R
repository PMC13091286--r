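make_pair <- function(doses, spacing = c(2, 2, 2)) {
  shape <- c(length(doses), 1, 1)
  list(dose = dose_grid(array(doses, shape), spacing),
       mask = struct_mask(array(TRUE, shape), spacing))
}

test_that("cumulative DVH matches direct counting on simple cases", {
  u <- make_pair(rep(40, 8))
  cv <- compute_dvh(u$dose, u$mask, 0.01)
  expect_equal(cv$cum_volume[cv$bin_edges <= 40], rep(1, sum(cv$bin_edges <= 40)))
  expect_equal(cv$cum_volume[cv$bin_edges > 40], rep(0, sum(cv$bin_edges > 40)))

  two <- make_pair(c(20, 40))
  cv2 <- compute_dvh(two$dose, two$mask, 0.01)
  at30 <- which.min(abs(cv2$bin_edges - 30))
  expect_equal(cv2$cum_volume[at30], 0.5)
})

test_that("DVH curve equals the sorting oracle at every bin edge", {
  set.seed(101)
  for (rep in 1:10) {
    shape <- rep(sample(8:12, 1), 3)
    g <- rand_dose_grid(shape, lo = 30, hi = 48)
    m <- rand_blob_mask(shape)
    cv <- compute_dvh(g, m, 0.05)
    doses <- g$values[m$membership]
    oracle <- vapply(cv$bin_edges, function(d) oracle_cum_volume(doses, d),
                     numeric(1))
    expect_equal(cv$cum_volume, oracle, tolerance = 1e-12)
  }
})

test_that("mean dose is the exact voxel mean", {
  u <- make_pair(rep(2.5, 5))
  expect_equal(d_mean(u$dose, u$mask), 2.5)
  two <- make_pair(c(0, 4))
  expect_equal(d_mean(two$dose, two$mask), 2)
  set.seed(102)
  for (rep in 1:10) {
    g <- rand_dose_grid(c(9, 9, 9))
    m <- rand_blob_mask(c(9, 9, 9))
    expect_equal(d_mean(g, m), sum(g$values[m$membership]) /
                   sum(m$membership), tolerance = 1e-9)
  }
})

test_that("dose-at-volume interpolates the cumulative curve", {
  u <- make_pair(rep(40, 8))
  cv <- compute_dvh(u$dose, u$mask, 0.01)
  expect_equal(d_percent(cv, 98), 40, tolerance = 0.01)

  # linear step from 1 at 39 Gy to 0 at 41 Gy: D50 is the midpoint
  edges <- seq(0, 41, by = 0.5)
  vols <- pmin(1, pmax(0, (41 - edges) / 2))
  ramp <- dvh_curve("x", edges, vols)
  expect_equal(d_percent(ramp, 50), 40)

  set.seed(103)
  for (rep in 1:10) {
    shape <- rep(sample(8:16, 1), 3)
    g <- rand_dose_grid(shape, lo = 20, hi = 50)
    m <- rand_blob_mask(shape)
    cv <- compute_dvh(g, m, 0.02)
    doses <- g$values[m$membership]
    for (p in c(2, 50, 98)) {
      expect_lt(abs(d_percent(cv, p) - oracle_d_percent(doses, p)), 0.02 + 1e-9)
    }
  }
})

test_that("D98 <= Dmean <= D2 within one bin width", {
  set.seed(104)
  for (rep in 1:10) {
    g <- rand_dose_grid(c(10, 10, 10), lo = 25, hi = 50)
    m <- rand_blob_mask(c(10, 10, 10))
    cv <- compute_dvh(g, m, 0.05)
    dm <- d_mean(g, m)
    expect_lte(d_percent(cv, 98), dm + 0.05)
    expect_lte(dm, d_percent(cv, 2) + 0.05)
  }
})

test_that("halving the bin width moves quantile doses by at most one coarse bin", {
  set.seed(105)
  g <- rand_dose_grid(c(10, 10, 10), lo = 30, hi = 45)
  m <- rand_blob_mask(c(10, 10, 10))
  for (w in c(0.2, 0.1, 0.05)) {
    c1 <- compute_dvh(g, m, w)
    c2 <- compute_dvh(g, m, w / 2)
    for (p in c(2, 98))
      expect_lte(abs(d_percent(c1, p) - d_percent(c2, p)), w + 1e-12)
  }
})

test_that("clinical goals follow the protocol thresholds inclusively", {
  cs_cp <- list(ptv_dmean = 40.3, ptv_d98 = 38.1, ptv_d2 = 42.1,
                lungs_dmean = 2.3, heart_dmean = 1.1, breastcl_dmean = 0.3)
  ev <- evaluate_goals(cs_cp)
  expect_equal(ev$goals_met, 6)
  expect_true(all(ev$goal_flags))

  boundary <- cs_cp
  boundary$ptv_dmean <- 40.45
  expect_equal(evaluate_goals(boundary)$goals_met, 6)

  hot_heart <- cs_cp
  hot_heart$heart_dmean <- 3.01
  ev2 <- evaluate_goals(hot_heart)
  expect_equal(ev2$goals_met, 5)
  expect_false(ev2$goal_flags[["heart_dmean_max"]])

  expect_error(evaluate_goals(cs_cp[-4]), "lungs_dmean")
})

test_that("lowering an OAR mean dose never reduces the goal count", {
  set.seed(106)
  for (rep in 1:20) {
    m <- list(ptv_dmean = runif(1, 39, 41.5), ptv_d98 = runif(1, 37, 39),
              ptv_d2 = runif(1, 41, 44), lungs_dmean = runif(1, 0.5, 8),
              heart_dmean = runif(1, 0.2, 4), breastcl_dmean = runif(1, 0.05, 2))
    base <- evaluate_goals(m)$goals_met
    for (oar in c("lungs_dmean", "heart_dmean", "breastcl_dmean")) {
      m2 <- m
      m2[[oar]] <- m[[oar]] * runif(1, 0.1, 0.9)
      expect_gte(evaluate_goals(m2)$goals_met, base)
    }
  }
})

test_that("DVH computation rejects empty masks and misalignment", {
  g <- dose_grid(array(1, c(3, 3, 3)), c(1, 1, 1))
  empty <- struct_mask(array(FALSE, c(3, 3, 3)), c(1, 1, 1),
                       allow_empty = TRUE)
  expect_error(compute_dvh(g, empty), "empty")
  off <- struct_mask(array(TRUE, c(3, 3, 3)), c(1.5, 1, 1))
  expect_error(compute_dvh(g, off), "aligned")
  expect_error(d_mean(g, off), "aligned")
})
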