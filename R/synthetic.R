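# Synthetic virtual-patient generator: voxel phantoms of left-breast
# anatomy, plan-like dose fields, contour perturbations emulating
# DL-vs-clinical segmentation differences, and a fast DVH-level sampler
# whose per-setup marginals are quantile-matched to configured
# median (Q1-Q3) triples.

# ---- quantile-kink ("split normal") sampling families -----------------

# quantile function that passes exactly through (Q1, median, Q3):
# m + sigma_lo * qnorm(u) below the median, m + sigma_hi * qnorm(u) above
split_normal_q <- function(u, triple) {
  q1 <- triple[1]; med <- triple[2]; q3 <- triple[3]
  z <- stats::qnorm(u)
  s_lo <- (med - q1) / stats::qnorm(0.75)
  s_hi <- (q3 - med) / stats::qnorm(0.75)
  med + ifelse(z < 0, s_lo, s_hi) * z
}

# positive, right-skew-capable family for OAR mean doses: split normal in
# log space (exact median and quartiles, strictly positive support)
split_lnorm_q <- function(u, triple) exp(split_normal_q(u, log(triple)))

split_normal_cdf <- function(x, m, s_lo, s_hi) {
  ifelse(x < m, stats::pnorm((x - m) / s_lo), stats::pnorm((x - m) / s_hi))
}

validate_triple <- function(tr, what) {
  if (length(tr) != 3L || any(!is.finite(tr)) || !(tr[1] < tr[2] && tr[2] < tr[3]))
    stop(sprintf("'%s' must be an increasing (Q1, median, Q3) triple", what))
  tr
}

# ---- configuration ----------------------------------------------------

#' Default per-setup DVH-parameter targets
#'
#' Named list `targets[[setup]][[metric]] = c(Q1, median, Q3)` in Gy for
#' the four plan setups and six goal metrics, reflecting a clinical
#' left-breast cohort (40.05 Gy in 15 fractions). Printed cohort tables
#' round to 0.1 Gy; where that rounding makes a quartile triple
#' degenerate, sub-rounding widths consistent with the printed values are
#' used (the PTV mean-dose triples of the deep-learning plans).
#'
#' @return nested list of triples.
#' @export
default_dvh_targets <- function() {
  list(
    CS_CP = list(
      ptv_dmean = c(40.22, 40.30, 40.36),
      ptv_d98 = c(38.09, 38.12, 38.30),
      ptv_d2 = c(41.90, 42.10, 42.36),
      lungs_dmean = c(1.9, 2.3, 2.7),
      heart_dmean = c(0.8, 1.1, 1.4),
      breastcl_dmean = c(0.2, 0.3, 0.4)),
    DLS_DLP = list(
      ptv_dmean = c(40.37, 40.40, 40.43),
      ptv_d98 = c(37.90, 38.20, 38.40),
      ptv_d2 = c(42.00, 42.20, 42.40),
      lungs_dmean = c(2.1, 2.5, 2.9),
      heart_dmean = c(0.9, 1.2, 1.7),
      breastcl_dmean = c(0.3, 0.4, 0.5)),
    CS_DLP = list(
      ptv_dmean = c(40.37, 40.40, 40.43),
      ptv_d98 = c(38.10, 38.30, 38.40),
      ptv_d2 = c(42.00, 42.20, 42.40),
      lungs_dmean = c(1.9, 2.3, 2.7),
      heart_dmean = c(0.9, 1.1, 1.6),
      breastcl_dmean = c(0.2, 0.3, 0.5)),
    PS_DLP = list(
      ptv_dmean = c(40.37, 40.40, 40.43),
      ptv_d98 = c(38.10, 38.30, 38.40),
      ptv_d2 = c(42.00, 42.20, 42.40),
      lungs_dmean = c(1.9, 2.3, 2.7),
      heart_dmean = c(0.8, 1.1, 1.6),
      breastcl_dmean = c(0.2, 0.3, 0.5))
  )
}

#' Default contour-perturbation targets
#'
#' Per-structure (VDSC, HD95 mm) medians characterising DL-vs-clinical
#' contour differences. A VDSC target of 1 means the DL contour is taken
#' as identical.
#'
#' @return data.frame `structure, vdsc, hd95_mm`.
#' @export
default_contour_targets <- function() {
  data.frame(
    structure = c("PTVp-Skin05", "Lungs", "Heart", "BreastCL"),
    vdsc = c(0.95, 0.98, 0.95, 1.0),
    hd95_mm = c(6.0, 1.2, 9.0, 0.0),
    stringsAsFactors = FALSE
  )
}

#' Cohort simulation configuration
#'
#' Every distributional assumption of the synthetic generator.
#'
#' @param n_patients cohort size (default 101).
#' @param seed RNG seed; all outputs are pure functions of (config, seed).
#' @param targets per-setup metric triples, see [default_dvh_targets()].
#' @param rho_setup correlation of the same metric between two setups of
#'   one patient (shared-anatomy latent, default 0.9).
#' @param rho_metric correlation between two different metrics of one
#'   plan (shared plan-quality latent, default 0.4).
#' @param defect_fraction fraction of patients whose DL target
#'   segmentation defect is clinically relevant (cold spot in the fully
#'   automated plan only; default 0.23).
#' @param defect_depth_gy range (min, max) of the cold-spot dose deficit
#'   below the plateau, Gy.
#' @param defect_volume range (min, max) of the cold fractional volume.
#' @param contour_targets per-structure (VDSC, HD95) targets, see
#'   [default_contour_targets()].
#' @param bin_width dose grid (Gy) for reconstructed DVH curves.
#' @param tcp_params,risk_registry,goals radiobiology and goal settings
#'   used when evaluating generated plans.
#' @param phantom [phantom_spec()] used in voxel-level mode.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 101, seed = 1,
                          targets = default_dvh_targets(),
                          rho_setup = 0.9, rho_metric = 0.4,
                          defect_fraction = 0.23,
                          defect_depth_gy = c(14, 28),
                          defect_volume = c(0.03, 0.18),
                          contour_targets = default_contour_targets(),
                          bin_width = 0.02,
                          tcp_params = default_tcp_params(),
                          risk_registry = default_risk_registry(),
                          goals = default_goals(),
                          phantom = phantom_spec()) {
  if (rho_setup < 0 || rho_setup > 1 || rho_metric < 0 || rho_metric > 1)
    stop("correlations must lie in [0, 1]")
  if (defect_fraction < 0 || defect_fraction > 1)
    stop("defect_fraction must lie in [0, 1]")
  for (s in names(targets))
    for (m in names(targets[[s]]))
      validate_triple(targets[[s]][[m]], paste(s, m))
  structure(list(n_patients = n_patients, seed = seed, targets = targets,
                 rho_setup = rho_setup, rho_metric = rho_metric,
                 defect_fraction = defect_fraction,
                 defect_depth_gy = defect_depth_gy,
                 defect_volume = defect_volume,
                 contour_targets = contour_targets,
                 bin_width = bin_width, tcp_params = tcp_params,
                 risk_registry = risk_registry, goals = goals,
                 phantom = phantom),
            class = "cohort_config")
}

# ---- correlated latent uniforms --------------------------------------

# Gaussian-copula uniforms for n patients x setups x metrics with
# corr(same metric, two setups) = rho_s, corr(two metrics, one setup) =
# rho_m, corr(two metrics, two setups) = rho_s * rho_m
latent_uniforms <- function(n, setups, metrics, rho_s, rho_m) {
  ns <- length(setups); nm <- length(metrics)
  g_p <- stats::rnorm(n)
  g_pm <- matrix(stats::rnorm(n * nm), n, nm)
  g_ps <- matrix(stats::rnorm(n * ns), n, ns)
  eps <- array(stats::rnorm(n * ns * nm), c(n, ns, nm))
  a <- sqrt(rho_s * (1 - rho_m))
  b <- sqrt(rho_m * (1 - rho_s))
  g <- sqrt(rho_s * rho_m)
  d <- sqrt((1 - rho_s) * (1 - rho_m))
  z <- array(0, c(n, ns, nm), dimnames = list(NULL, setups, metrics))
  for (s in seq_len(ns)) for (m in seq_len(nm))
    z[, s, m] <- g * g_p + a * g_pm[, m] + b * g_ps[, s] + d * eps[, s, m]
  stats::pnorm(z)
}

# ---- DVH-level sampler ------------------------------------------------

#' Sample per-plan DVH parameters for one setup
#'
#' Draws `n` six-metric vectors from the configured quantile-matched
#' marginals. PTV metrics use the split-normal family, OAR mean doses its
#' log-space version. The PTV ordering D98 <= Dmean <= D2 holds by
#' construction of the reconstructed dose distribution downstream; raw
#' draws violating it (possible only under extreme configs) are clamped.
#'
#' @param setup one of `"CS_CP", "DLS_DLP", "CS_DLP", "PS_DLP"`.
#' @param config a [cohort_config()].
#' @param n number of plans to draw.
#' @param u optional n x 6 matrix of latent uniforms (columns in metric
#'   order) for externally supplied correlation structure.
#' @return data.frame of the six metrics.
#' @export
sample_dvh_params <- function(setup, config, n, u = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  tg <- config$targets[[setup]]
  if (is.null(tg)) stop(sprintf("no targets configured for setup '%s'", setup))
  metrics <- c("ptv_dmean", "ptv_d98", "ptv_d2",
               "lungs_dmean", "heart_dmean", "breastcl_dmean")
  if (is.null(u)) u <- matrix(stats::runif(n * 6), n, 6)
  out <- data.frame(matrix(NA_real_, n, 6))
  names(out) <- metrics
  for (j in seq_along(metrics)) {
    m <- metrics[j]
    out[[m]] <- if (grepl("^ptv", m)) split_normal_q(u[, j], tg[[m]])
                else split_lnorm_q(u[, j], tg[[m]])
  }
  # guard the PTV ordering (gaps are ~2 Gy against ~0.2 Gy spreads, so
  # violations require a pathological config)
  out$ptv_d98 <- pmin(out$ptv_d98, out$ptv_dmean - 0.05)
  out$ptv_d2 <- pmax(out$ptv_d2, out$ptv_dmean + 0.05)
  out
}

#' Reconstruct a PTV DVH curve from its summary parameters
#'
#' Builds the cumulative DVH of a voxel-dose distribution chosen to
#' reproduce the plan's (D_mean, D_98, D_2) exactly: a split-normal bulk
#' (mode solved so the mean matches, tail widths from the D98/D2 gaps),
#' optionally mixed with a cold-spot component (uniform over a 2 Gy band
#' around `cold_dose` with volume fraction `cold_w`) emulating a
#' clinically relevant target-coverage defect.
#'
#' @param dmean,d98,d2 target DVH parameters, Gy (d98 < dmean < d2).
#' @param cold_w cold-spot volume fraction (0 = none).
#' @param cold_dose centre dose of the cold spot, Gy.
#' @param bin_width curve resolution, Gy.
#' @return a [dvh_curve()] named `"PTVp-Skin05"`.
#' @export
ptv_curve_model <- function(dmean, d98, d2, cold_w = 0, cold_dose = NA,
                            bin_width = 0.05) {
  if (!(d98 < dmean && dmean < d2)) stop("need d98 < dmean < d2")
  z98 <- stats::qnorm(0.98)
  cc <- 1 / (z98 * sqrt(2 * pi))
  m <- (dmean - cc * (d2 + d98)) / (1 - 2 * cc)
  s_lo <- (m - d98) / z98
  s_hi <- (d2 - m) / z98
  if (s_lo <= 0 || s_hi <= 0) stop("degenerate DVH parameter combination")
  half <- 1
  top <- max(d2 + 4 * s_hi, m)
  edges <- seq(0, (floor(top / bin_width) + 1) * bin_width, by = bin_width)
  cdf <- split_normal_cdf(edges, m, s_lo, s_hi)
  if (cold_w > 0) {
    if (!is.finite(cold_dose)) stop("cold_dose required when cold_w > 0")
    lo <- max(cold_dose - half, 0)
    cold_cdf <- pmin(pmax((edges - lo) / (cold_dose + half - lo), 0), 1)
    cdf <- (1 - cold_w) * cdf + cold_w * cold_cdf
  }
  dvh_curve("PTVp-Skin05", edges, 1 - cdf)
}

# evaluate one sampled plan (dvh-level): curve-derived PTV metrics keep
# every reported number consistent with the curve the TCP sees
evaluate_sampled_plan <- function(p, config, cold_w = 0, cold_dose = NA) {
  curve <- ptv_curve_model(p$ptv_dmean, p$ptv_d98, p$ptv_d2,
                           cold_w = cold_w, cold_dose = cold_dose,
                           bin_width = config$bin_width)
  m <- list(
    ptv_dmean = eud(curve, 1),
    ptv_d98 = d_percent(curve, 98),
    ptv_d2 = d_percent(curve, 2),
    lungs_dmean = p$lungs_dmean,
    heart_dmean = p$heart_dmean,
    breastcl_dmean = p$breastcl_dmean
  )
  ev <- evaluate_goals(m, config$goals)
  risks <- risk_panel(m$heart_dmean, m$lungs_dmean, config$risk_registry)
  c(m, ev, list(tcp = tcp_from_curve(curve, config$tcp_params),
                risks = risks))
}

risk_row <- function(risks) {
  c(aer_w = risks$acute_coronary_events.with$value,
    aer_wo = risks$acute_coronary_events.without$value,
    aemr_cardiac_w = risks$cardiac_disease_mortality.with$value,
    aemr_cardiac_wo = risks$cardiac_disease_mortality.without$value,
    aemr_lung_w = risks$secondary_lung_cancer_mortality.with$value,
    aemr_lung_wo = risks$secondary_lung_cancer_mortality.without$value)
}

#' Generate a synthetic evaluated cohort
#'
#' DVH-level mode samples per-setup DVH parameters with the configured
#' correlation structure, reconstructs PTV DVH curves (with cold-spot
#' defects in the fully automated DLS-DLP plans of the defect
#' subpopulation, removed again in PS-DLP), evaluates goals, TCP and the
#' risk panel, and assigns workflow routes. Voxel-level mode additionally
#' builds a per-patient phantom, paints the four dose fields and runs the
#' volumetric evaluation chain ([plan_metrics()]); it is intended for
#' small `n`.
#'
#' @param config a [cohort_config()].
#' @param mode `"dvh"` (fast, default) or `"voxel"`.
#' @return list of class `synthetic_cohort`: `evals` (cohort evaluation
#'   data.frame, one row per patient x setup), `config`, and in
#'   voxel-level mode `volumes` (per-patient dose grids and masks).
#' @export
generate_cohort <- function(config, mode = c("dvh", "voxel")) {
  stopifnot(inherits(config, "cohort_config"))
  mode <- match.arg(mode)
  set.seed(config$seed)
  if (mode == "dvh") cohort_dvh_level(config) else cohort_voxel_level(config)
}

cohort_dvh_level <- function(config) {
  n <- config$n_patients
  setups <- c("CS_CP", "DLS_DLP", "CS_DLP", "PS_DLP")
  metrics <- c("ptv_dmean", "ptv_d98", "ptv_d2",
               "lungs_dmean", "heart_dmean", "breastcl_dmean")
  u <- latent_uniforms(n, setups, metrics, config$rho_setup, config$rho_metric)
  defect <- stats::runif(n) < config$defect_fraction
  depth <- stats::runif(n, config$defect_depth_gy[1], config$defect_depth_gy[2])
  coldw <- stats::runif(n, config$defect_volume[1], config$defect_volume[2])
  rows <- vector("list", n * length(setups))
  ri <- 0L
  for (s in setups) {
    par <- sample_dvh_params(s, config, n, u = u[, s, ])
    for (i in seq_len(n)) {
      is_def <- s == "DLS_DLP" && defect[i]
      ev <- evaluate_sampled_plan(
        par[i, ], config,
        cold_w = if (is_def) coldw[i] else 0,
        cold_dose = if (is_def) par$ptv_dmean[i] - depth[i] else NA)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        patient_id = sprintf("P%03d", i), setup = s,
        ptv_dmean = ev$ptv_dmean, ptv_d98 = ev$ptv_d98, ptv_d2 = ev$ptv_d2,
        lungs_dmean = ev$lungs_dmean, heart_dmean = ev$heart_dmean,
        breastcl_dmean = ev$breastcl_dmean,
        goals_met = ev$goals_met, tcp = ev$tcp,
        t(risk_row(ev$risks)),
        stringsAsFactors = FALSE)
    }
  }
  evals <- do.call(rbind, rows)
  evals <- add_routes(evals)
  structure(list(evals = evals, config = config, mode = "dvh"),
            class = "synthetic_cohort")
}

add_routes <- function(evals) {
  ids <- unique(evals$patient_id)
  route <- vapply(ids, function(id) assign_route(
    evals$goals_met[evals$patient_id == id & evals$setup == "DLS_DLP"],
    evals$goals_met[evals$patient_id == id & evals$setup == "PS_DLP"]),
    character(1))
  evals$route <- route[match(evals$patient_id, ids)]
  evals
}

cohort_voxel_level <- function(config) {
  n <- config$n_patients
  setups <- c("CS_CP", "DLS_DLP", "CS_DLP", "PS_DLP")
  metrics <- c("ptv_dmean", "ptv_d98", "ptv_d2",
               "lungs_dmean", "heart_dmean", "breastcl_dmean")
  u <- latent_uniforms(n, setups, metrics, config$rho_setup, config$rho_metric)
  defect <- stats::runif(n) < config$defect_fraction
  depth <- stats::runif(n, config$defect_depth_gy[1], config$defect_depth_gy[2])
  size <- exp(stats::rnorm(n, 0, 0.05))  # per-patient anatomical scale
  rows <- list(); volumes <- vector("list", n)
  for (i in seq_len(n)) {
    spec_i <- scale_phantom_spec(config$phantom, size[i])
    ph <- build_phantom(spec_i)
    dls <- perturb_structures(ph, config$contour_targets,
                              seed = config$seed + 7919L * i)
    pm <- list()
    for (s in setups) {
      par <- sample_dvh_params(s, config, 1L,
                               u = matrix(u[i, s, ], 1L))
      q <- plan_quality_from_params(par, spec_i)
      if (s == "DLS_DLP" && defect[i]) {
        q$cold_spot <- list(depth_gy = depth[i],
                            frac_volume = stats::runif(1, config$defect_volume[1],
                                                       config$defect_volume[2]))
      }
      dose <- paint_dose(ph, q, seed = config$seed + 104729L * i + match(s, setups))
      pm[[s]] <- plan_metrics(dose, ph$structures, config$goals,
                              config$tcp_params, config$risk_registry)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = sprintf("P%03d", i), setup = s,
        ptv_dmean = pm[[s]]$ptv_dmean, ptv_d98 = pm[[s]]$ptv_d98,
        ptv_d2 = pm[[s]]$ptv_d2, lungs_dmean = pm[[s]]$lungs_dmean,
        heart_dmean = pm[[s]]$heart_dmean,
        breastcl_dmean = pm[[s]]$breastcl_dmean,
        goals_met = pm[[s]]$goals_met, tcp = pm[[s]]$tcp,
        t(risk_row(pm[[s]]$risks)), stringsAsFactors = FALSE)
    }
    volumes[[i]] <- list(phantom = ph, dl_structures = dls)
  }
  evals <- add_routes(do.call(rbind, rows))
  structure(list(evals = evals, config = config, mode = "voxel",
                 volumes = volumes),
            class = "synthetic_cohort")
}

# translate sampled DVH parameters into dose-painting quality knobs
plan_quality_from_params <- function(par, spec) {
  list(plateau_gy = par$ptv_dmean,
       heterogeneity = (par$ptv_d2 - par$ptv_d98) / (2 * stats::qnorm(0.98)) /
         par$ptv_dmean,
       falloff_mm = 12,
       oar_targets = c(Lungs = par$lungs_dmean, Heart = par$heart_dmean,
                       BreastCL = par$breastcl_dmean),
       cold_spot = NULL)
}
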