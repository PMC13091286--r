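# Phantom, dose painting and perturbation tests use a coarse geometry so
# the whole suite stays at desk scale; the statistical checks run on the
# fast DVH-level sampler.

coarse_spec <- function(spacing = 8) phantom_spec(spacing_mm = spacing)

test_that("phantom structures are present, non-empty and disjoint", {
  ph <- build_phantom(coarse_spec())
  st <- ph$structures
  expect_setequal(names(st), c("Body", "CTVp", "PTVp-Skin05", "Lungs",
                               "Heart", "BreastCL"))
  for (s in st) expect_gt(sum(s$membership), 0)
  organs <- c("PTVp-Skin05", "Lungs", "Heart", "BreastCL")
  for (i in seq_along(organs)) for (j in seq_along(organs)) {
    if (i < j)
      expect_equal(sum(st[[organs[i]]]$membership &
                         st[[organs[j]]]$membership), 0)
  }
  # PTV covers the CTV except the skin collar, and stays inside the body
  expect_true(all(!st[["PTVp-Skin05"]]$membership | st[["Body"]]$membership))
  expect_gt(sum(st[["CTVp"]]$membership & st[["PTVp-Skin05"]]$membership) /
              sum(st[["CTVp"]]$membership), 0.5)
})

test_that("zero margins collapse the PTV onto the CTV", {
  sp <- phantom_spec(spacing_mm = 8, ptv_margin_mm = 0, skin_clearance_mm = 0)
  ph <- build_phantom(sp)
  expect_identical(ph$structures[["PTVp-Skin05"]]$membership,
                   ph$structures[["CTVp"]]$membership)
})

test_that("every PTV surface point keeps the skin clearance", {
  set.seed(81)
  for (rep in 1:4) {
    sp <- scale_phantom_spec(phantom_spec(spacing_mm = 8),
                             stats::runif(1, 0.85, 1.15))
    ph <- build_phantom(sp)
    ptv_s <- surface_points(ph$structures[["PTVp-Skin05"]])
    body <- ph$structures[["Body"]]
    outside <- struct_mask(!body$membership, body$spacing, body$origin,
                           name = "outside")
    d <- oracle_nn_distances(ptv_s, surface_points(outside))
    expect_gte(min(d), sp$skin_clearance_mm)
  }
})

test_that("dose painting is exact in the degenerate and calibrated cases", {
  ph <- build_phantom(coarse_spec())
  step <- paint_dose(ph, list(plateau_gy = 40, heterogeneity = 0,
                              falloff_mm = 0), seed = 1)
  ptv <- ph$structures[["PTVp-Skin05"]]
  expect_equal(unique(step$values[ptv$membership]), 40)
  expect_equal(max(step$values[!ptv$membership]), 0)
  expect_equal(d_mean(step, ph$structures[["Lungs"]]), 0)

  q <- list(plateau_gy = 40.4, heterogeneity = 0.025, falloff_mm = 12,
            oar_targets = c(Lungs = 2.5, Heart = 1.2, BreastCL = 0.4))
  d <- paint_dose(ph, q, seed = 2)
  expect_equal(d_mean(d, ptv), 40.4, tolerance = 0.05)
  expect_equal(d_mean(d, ph$structures[["Lungs"]]), 2.5, tolerance = 0.05 * 2.5)
  expect_equal(d_mean(d, ph$structures[["Heart"]]), 1.2, tolerance = 0.05 * 1.2)
  expect_true(all(d$values >= 0))

  expect_error(paint_dose(ph, list(plateau_gy = 40,
                                   oar_targets = c(Heart = 45)), seed = 1),
               "exceeds the plateau")
  expect_error(paint_dose(ph, list(plateau_gy = 40, falloff_mm = 0,
                                   oar_targets = c(Heart = 1)), seed = 1),
               "unreachable")
})

test_that("cold spots depress D98 and TCP in the painted dose", {
  ph <- build_phantom(coarse_spec())
  q <- list(plateau_gy = 40.4, heterogeneity = 0.02, falloff_mm = 12,
            cold_spot = list(depth_gy = 20, frac_volume = 0.08))
  pm_cold <- plan_metrics(paint_dose(ph, q, seed = 5), ph$structures)
  q$cold_spot <- NULL
  pm_ok <- plan_metrics(paint_dose(ph, q, seed = 5), ph$structures)
  expect_lt(pm_cold$ptv_d98, pm_ok$ptv_d98 - 2)
  expect_lt(pm_cold$tcp, 0.95)
  expect_gt(pm_ok$tcp, 0.9)
})

test_that("mask perturbation hits VDSC targets and keeps identity at 1", {
  ph <- build_phantom(phantom_spec(spacing_mm = 6))
  ctv <- ph$structures[["CTVp"]]
  expect_identical(perturb_mask(ctv, 1, 0, seed = 1), ctv)
  sdf <- signed_distance(ctv)
  for (seed in 1:5) {
    p <- perturb_mask(ctv, 0.95, 6, seed = seed, sdf = sdf)
    expect_gte(vdsc(ctv, p), 0.93)
    expect_lte(vdsc(ctv, p), 0.97)
  }
  heart <- ph$structures[["Heart"]]
  sdf_h <- signed_distance(heart)
  hds <- vapply(1:5, function(seed) {
    p <- perturb_mask(heart, 0.95, 9, seed = seed, sdf = sdf_h)
    expect_gte(vdsc(heart, p), 0.93)
    expect_lte(vdsc(heart, p), 0.97)
    hd95(heart, p)
  }, numeric(1))
  expect_lte(abs(stats::median(hds) - 9), 4)
})

test_that("sampled DVH parameters recover the configured quartiles", {
  cfg <- cohort_config()
  set.seed(82)
  for (s in c("CS_CP", "DLS_DLP")) {
    par <- sample_dvh_params(s, cfg, 800)
    for (m in names(cfg$targets[[s]])) {
      tgt <- cfg$targets[[s]][[m]]
      got <- stats::quantile(par[[m]], c(0.25, 0.5, 0.75), names = FALSE)
      expect_lt(max(abs(got - tgt) / tgt), 0.1)
    }
    expect_true(all(par$ptv_d98 < par$ptv_dmean))
    expect_true(all(par$ptv_dmean < par$ptv_d2))
  }
})

test_that("degenerate latents collapse all setups to the medians", {
  cfg <- cohort_config()
  u <- matrix(0.5, 4, 6)
  for (s in names(cfg$targets)) {
    par <- sample_dvh_params(s, cfg, 4, u = u)
    meds <- vapply(names(cfg$targets[[s]]),
                   function(m) cfg$targets[[s]][[m]][2], numeric(1))
    expect_equal(unlist(par[1, ]), meds, ignore_attr = TRUE, tolerance = 1e-9)
    expect_true(all(vapply(par, function(col) length(unique(col)) == 1,
                           logical(1))))
  }
})

test_that("reconstructed PTV curves reproduce their summary parameters", {
  set.seed(83)
  for (rep in 1:10) {
    dmean <- stats::runif(1, 39.8, 40.6)
    d98 <- dmean - stats::runif(1, 1.5, 3)
    d2 <- dmean + stats::runif(1, 1.2, 2.5)
    cv <- ptv_curve_model(dmean, d98, d2, bin_width = 0.01)
    expect_equal(eud(cv, 1), dmean, tolerance = 0.02)
    expect_equal(d_percent(cv, 98), d98, tolerance = 0.02)
    expect_equal(d_percent(cv, 2), d2, tolerance = 0.02)
  }
  # cold spot pulls D98 to the cold band
  cv <- ptv_curve_model(40.4, 38.2, 42.2, cold_w = 0.05, cold_dose = 25)
  expect_lt(d_percent(cv, 98), 27)
})

test_that("cohort generation is deterministic and route-consistent", {
  cfg <- cohort_config(n_patients = 30, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$evals, b$evals)
  ev <- a$evals
  for (id in unique(ev$patient_id)) {
    dls <- ev$goals_met[ev$patient_id == id & ev$setup == "DLS_DLP"]
    ps <- ev$goals_met[ev$patient_id == id & ev$setup == "PS_DLP"]
    expect_identical(unique(ev$route[ev$patient_id == id]),
                     assign_route(dls, ps))
  }
  expect_true(all(ev$tcp >= 0 & ev$tcp <= 1))
  expect_true(all(ev$goals_met %in% 0:6))
})

test_that("voxel-level cohort runs the volumetric chain end to end", {
  cfg <- cohort_config(n_patients = 2, seed = 5,
                       phantom = phantom_spec(spacing_mm = 8))
  co <- generate_cohort(cfg, mode = "voxel")
  expect_equal(nrow(co$evals), 8)
  expect_true(all(co$evals$ptv_dmean > 39 & co$evals$ptv_dmean < 41.5))
  expect_length(co$volumes, 2)
  expect_s3_class(co$volumes[[1]]$phantom$structures[["Heart"]],
                  "struct_mask")
  # DL-emulated contours differ from the truth the configured way
  dls <- co$volumes[[1]]$dl_structures
  truth <- co$volumes[[1]]$phantom$structures
  v <- vdsc(truth[["Heart"]], dls[["Heart"]])
  expect_gte(v, 0.9)
  expect_lt(v, 1)
  expect_identical(dls[["BreastCL"]]$membership,
                   truth[["BreastCL"]]$membership)
})
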