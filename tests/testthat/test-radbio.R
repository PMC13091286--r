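uniform_curve <- function(d, w = 0.01) {
  edges <- seq(0, d + 10 * w, by = w)
  dvh_curve("u", edges, as.numeric(edges <= d))
}

two_bin_curve <- function(v, d, w = 1e-4) {
  # fractions v at doses d (point masses), built as a cumulative curve
  # whose drops happen in w-wide bins just above each dose so that the
  # differential form places the mass at d + w/2
  edges <- sort(unique(c(0, d, d + w, max(d) + 2 * w)))
  cum <- vapply(edges, function(e) sum(v[d >= e - 1e-12]), numeric(1))
  dvh_curve("x", edges, cum)
}

test_that("LQ conversion to 2 Gy fractions has the right fixed points", {
  p <- tcp_params(n_fractions = 15, alpha_beta = 10)
  cv <- uniform_curve(45)
  e <- eqd2_curve(cv, p)
  # 30 Gy in 15 fractions is 2 Gy/fraction: fixed point of the map
  i30 <- which.min(abs(cv$bin_edges - 30))
  expect_equal(e$bin_edges[i30], cv$bin_edges[i30], tolerance = 1e-9)
  expect_equal(e$bin_edges[1], 0)
  expect_equal(e$cum_volume, cv$cum_volume)
  # hand-computed: 40.05 Gy in 15 fx -> 40.05 * (2.67 + 10) / 12
  i <- which.min(abs(cv$bin_edges - 40.05))
  expect_equal(e$bin_edges[i], cv$bin_edges[i] * (cv$bin_edges[i] / 15 + 10) / 12,
               tolerance = 1e-12)
  expect_equal(40.05 * (40.05 / 15 + 10) / 12, 42.286125, tolerance = 1e-9)
})

test_that("EUD reduces to the right power means", {
  for (a in c(-7.2, -1, 1, 4)) {
    cv <- uniform_curve(40, w = 1e-3)
    expect_equal(eud(cv, a), 40, tolerance = 1e-3)
  }
  cv <- two_bin_curve(c(0.5, 0.5), c(38, 42))
  expect_equal(eud(cv, 1), 40, tolerance = 1e-3)
  expect_equal(eud(cv, -7.2),
               (0.5 * 38^-7.2 + 0.5 * 42^-7.2)^(-1 / 7.2),
               tolerance = 1e-3)
  # limits: large |a| approach extreme bin doses
  cv3 <- two_bin_curve(c(0.2, 0.5, 0.3), c(35, 40, 44))
  expect_equal(eud(cv3, 80), 44, tolerance = 0.1)
  expect_equal(eud(cv3, -80), 35, tolerance = 0.1)
  for (a in c(-7.2, -2, 1, 3)) {
    expect_equal(eud(cv3, a),
                 sum(c(0.2, 0.5, 0.3) * c(35, 40, 44)^a)^(1 / a),
                 tolerance = 1e-3)
  }
  expect_error(eud(cv3, 0), "nonzero")
})

test_that("cold volumes drive EUD towards zero for negative exponents", {
  cold <- two_bin_curve(c(0.05, 0.95), c(1e-4, 40))
  expect_lt(eud(cold, -7.2), 5)
})

test_that("TCP has the logistic midpoint, limits and monotonicity", {
  p <- tcp_params(tcd50 = 28.3, gamma50 = 2)
  expect_equal(tcp(28.3, p), 0.5)
  expect_equal(tcp(1e6, p), 1, tolerance = 1e-4)
  expect_equal(tcp(0, p), 0)
  expect_equal(tcp(1.2 * 28.3, p), 1 / (1 + (1 / 1.2)^8), tolerance = 1e-12)
  euds <- seq(0, 80, by = 0.5)
  expect_true(all(diff(tcp(euds, p)) > 0))
})

test_that("raising any part of the DVH never lowers the TCP", {
  p <- default_tcp_params()
  set.seed(31)
  for (rep in 1:10) {
    v <- as.vector(stats::rmultinom(1, 100, rep(1, 4))) / 100
    d <- sort(stats::runif(4, 20, 45))
    base <- tcp_from_curve(two_bin_curve(v, d), p)
    j <- sample(4, 1)
    d2 <- d
    d2[j] <- d2[j] + stats::runif(1, 0.1, 3)
    expect_gte(tcp_from_curve(two_bin_curve(v, sort(d2)), p) + 1e-12, base)
  }
})

test_that("uniform-dose TCP equals the closed form through EQD2", {
  p <- default_tcp_params()
  d <- 40.05
  eqd2 <- d * (d / p$n_fractions + p$alpha_beta) / (2 + p$alpha_beta)
  closed <- 1 / (1 + (p$tcd50 / eqd2)^(4 * p$gamma50))
  expect_equal(tcp_from_curve(uniform_curve(d, w = 1e-3), p), closed,
               tolerance = 1e-3)
})

test_that("excess risk is linear, zero-anchored and stratum-ordered", {
  m <- risk_model("acute_coronary_events", "heart", 0.074, 10, 5)
  expect_equal(excess_risk(0, m, TRUE)$value, 0)
  expect_equal(excess_risk(1.1, m, TRUE)$value, 0.814)
  expect_equal(excess_risk(2.2, m, TRUE)$value, 2 * 0.814)
  expect_gte(excess_risk(1.1, m, TRUE)$value, excess_risk(1.1, m, FALSE)$value)
  expect_error(risk_model("acute_coronary_events", "heart", 0.074, 3, 5),
               ">=")
})

test_that("the risk panel composes six per-endpoint estimates", {
  reg <- default_risk_registry()
  zero <- risk_panel(0, 0, reg)
  expect_length(zero, 6)
  expect_true(all(vapply(zero, function(r) r$value, numeric(1)) == 0))

  pan <- risk_panel(1.1, 2.3, reg)
  for (ep in names(reg)) {
    dose <- if (reg[[ep]]$organ == "heart") 1.1 else 2.3
    expect_equal(pan[[paste0(ep, ".with")]]$value,
                 excess_risk(dose, reg[[ep]], TRUE)$value)
    expect_equal(pan[[paste0(ep, ".without")]]$value,
                 excess_risk(dose, reg[[ep]], FALSE)$value)
    expect_gte(pan[[paste0(ep, ".with")]]$value,
               pan[[paste0(ep, ".without")]]$value)
  }
  # linearity in dose: panel(k * D) = k * panel(D)
  k <- 2.7
  pank <- risk_panel(k * 1.1, k * 2.3, reg)
  expect_equal(vapply(pank, function(r) r$value, numeric(1)),
               k * vapply(pan, function(r) r$value, numeric(1)))
  expect_error(risk_panel(1, 1, reg[1:2]), "missing endpoint")
})
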