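#' Cumulative dose-volume histogram
#'
#' Builds the cumulative DVH of a structure on uniform dose bin edges
#' `0, w, 2w, ...` extending one bin beyond the maximum member-voxel dose.
#' `cum_volume[i]` is the fraction of the structure volume receiving at
#' least `bin_edges[i]` Gy, so the curve starts at 1 and ends at 0.
#'
#' @param dose a [dose_grid()].
#' @param mask an aligned, non-empty [struct_mask()].
#' @param bin_width bin width in Gy (default 0.01, i.e. 1 cGy).
#' @return An object of class `dvh_curve` with fields `structure`,
#'   `bin_edges` (Gy), `cum_volume` (fractions in `[0, 1]`).
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.01) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "struct_mask"))
  if (bin_width <= 0) stop("bin_width must be positive")
  stop_if_misaligned(dose, mask, "dose and mask")
  if (mask$empty || !any(mask$membership))
    stop(sprintf("cannot compute DVH of empty mask '%s'", mask$name))
  d <- dose$values[mask$membership]
  edges <- seq(0, (floor(max(d) / bin_width) + 1) * bin_width, by = bin_width)
  # fraction of voxels with dose >= edge; findInterval on sorted doses
  ds <- sort(d)
  n <- length(ds)
  below <- findInterval(edges - 1e-12, ds)  # voxels strictly below edge
  dvh_curve(mask$name, edges, (n - below) / n)
}

#' Construct a DVH curve object
#'
#' @param structure structure label.
#' @param bin_edges ascending, uniformly spaced dose bin edges in Gy.
#' @param cum_volume non-increasing fractions in `[0, 1]`, starting at 1.
#' @return `dvh_curve` object.
#' @export
dvh_curve <- function(structure, bin_edges, cum_volume) {
  bin_edges <- as.numeric(bin_edges)
  cum_volume <- as.numeric(cum_volume)
  if (length(bin_edges) != length(cum_volume))
    stop("bin_edges and cum_volume differ in length")
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  if (any(cum_volume < -1e-9 | cum_volume > 1 + 1e-9))
    stop("cum_volume outside [0, 1]")
  if (any(diff(cum_volume) > 1e-9)) stop("cum_volume must be non-increasing")
  structure(list(structure = structure, bin_edges = bin_edges,
                 cum_volume = pmin(pmax(cum_volume, 0), 1)),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve '%s', %d bins, 0-%.2f Gy>\n",
              x$structure, length(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' Mean structure dose
#'
#' Arithmetic mean of member-voxel doses, computed on the raw voxels (never
#' from the binned curve).
#'
#' @inheritParams compute_dvh
#' @return D_mean in Gy.
#' @export
d_mean <- function(dose, mask) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "struct_mask"))
  stop_if_misaligned(dose, mask, "dose and mask")
  if (mask$empty || !any(mask$membership))
    stop(sprintf("cannot compute D_mean of empty mask '%s'", mask$name))
  mean(dose$values[mask$membership])
}

#' Dose to the hottest p% of the volume
#'
#' `d_percent(curve, p)` is the dose D_p such that the fraction `p/100` of
#' the structure volume receives at least D_p, obtained by linear
#' interpolation between the bracketing bin edges of the cumulative curve
#' (D_98 and D_2 of the clinical goals are `p = 98` and `p = 2`).
#'
#' @param curve a `dvh_curve`.
#' @param p percent of volume, in (0, 100).
#' @return dose in Gy.
#' @export
d_percent <- function(curve, p) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (p <= 0 || p >= 100) stop("p must be in (0, 100)")
  v <- curve$cum_volume
  e <- curve$bin_edges
  if (length(e) == 1L) {
    warning("degenerate single-bin DVH; returning its dose")
    return(e)
  }
  f <- p / 100
  # first index where the curve has dropped below f
  i <- which(v < f)[1]
  if (is.na(i)) return(e[length(e)])
  if (i == 1L) return(e[1])
  # interpolate within [e[i-1], e[i]] where v falls from v[i-1] >= f to v[i] < f
  v0 <- v[i - 1L]; v1 <- v[i]
  if (v0 == v1) return(e[i - 1L])
  e[i - 1L] + (v0 - f) / (v0 - v1) * (e[i] - e[i - 1L])
}

#' The six clinical goals of the left-breast protocol
#'
#' Default goal set: PTV D_mean within 39.65-40.45 Gy (99-101% of 40.05 Gy),
#' PTV D_98 >= 38.05 Gy (95%), PTV D_2 <= 42.85 Gy (107%), mean lung dose
#' <= 6 Gy, mean heart dose <= 3 Gy, mean contralateral-breast dose <= 1 Gy.
#' All comparisons are inclusive at the thresholds.
#'
#' @return data.frame with columns `goal`, `structure`, `metric`,
#'   `comparator` (`"range"`, `"ge"`, `"le"`), `lower`, `upper` (Gy).
#' @export
default_goals <- function() {
  data.frame(
    goal = c("ptv_dmean_range", "ptv_d98_min", "ptv_d2_max",
             "lungs_dmean_max", "heart_dmean_max", "breastcl_dmean_max"),
    structure = c("PTVp-Skin05", "PTVp-Skin05", "PTVp-Skin05",
                  "Lungs", "Heart", "BreastCL"),
    metric = c("ptv_dmean", "ptv_d98", "ptv_d2",
               "lungs_dmean", "heart_dmean", "breastcl_dmean"),
    comparator = c("range", "ge", "le", "le", "le", "le"),
    lower = c(39.65, 38.05, NA, NA, NA, NA),
    upper = c(40.45, NA, 42.85, 6, 3, 1),
    stringsAsFactors = FALSE
  )
}

validate_goals <- function(goals) {
  need <- c("goal", "metric", "comparator", "lower", "upper")
  if (!all(need %in% names(goals))) stop("goal set missing required columns")
  thr <- c(goals$lower, goals$upper)
  if (any(thr[!is.na(thr)] <= 0)) stop("goal thresholds must be positive")
  goals
}

#' Evaluate the clinical goals on a set of DVH parameters
#'
#' @param metrics named list or vector with entries `ptv_dmean`, `ptv_d98`,
#'   `ptv_d2`, `lungs_dmean`, `heart_dmean`, `breastcl_dmean` (Gy).
#' @param goals a goal table as returned by [default_goals()].
#' @return list with `goal_flags` (named logical) and `goals_met` (0-6).
#'   Boundary values count as met.
#' @export
evaluate_goals <- function(metrics, goals = default_goals()) {
  goals <- validate_goals(goals)
  metrics <- as.list(metrics)
  flags <- logical(nrow(goals))
  names(flags) <- goals$goal
  for (r in seq_len(nrow(goals))) {
    m <- metrics[[goals$metric[r]]]
    if (is.null(m) || !is.finite(m))
      stop(sprintf("missing or non-finite parameter '%s' for goal '%s'",
                   goals$metric[r], goals$goal[r]))
    flags[r] <- switch(goals$comparator[r],
      range = m >= goals$lower[r] && m <= goals$upper[r],
      ge = m >= goals$lower[r],
      le = m <= goals$upper[r],
      stop(sprintf("unknown comparator '%s'", goals$comparator[r]))
    )
  }
  list(goal_flags = flags, goals_met = sum(flags))
}

#' Full per-plan metric panel from dose and structures
#'
#' Computes the six DVH goal parameters on the reference structures, the
#' goal flags, TCP from the PTV DVH, and the six-entry excess-risk panel.
#'
#' @param dose a [dose_grid()].
#' @param structures named list of aligned `struct_mask`s containing at
#'   least `PTVp-Skin05`, `Lungs`, `Heart`, `BreastCL`.
#' @param goals goal table (default [default_goals()]).
#' @param tcp_params [tcp_params()] used for the EUD/TCP chain.
#' @param risk_registry list of three [risk_model()]s (default
#'   [default_risk_registry()]).
#' @param bin_width DVH bin width in Gy.
#' @return list of class `plan_metrics`.
#' @export
plan_metrics <- function(dose, structures, goals = default_goals(),
                         tcp_params = default_tcp_params(),
                         risk_registry = default_risk_registry(),
                         bin_width = 0.01) {
  need <- c("PTVp-Skin05", "Lungs", "Heart", "BreastCL")
  miss <- setdiff(need, names(structures))
  if (length(miss)) stop("missing structures: ", paste(miss, collapse = ", "))
  ptv <- structures[["PTVp-Skin05"]]
  curve <- compute_dvh(dose, ptv, bin_width)
  m <- list(
    ptv_dmean = d_mean(dose, ptv),
    ptv_d98 = d_percent(curve, 98),
    ptv_d2 = d_percent(curve, 2),
    lungs_dmean = d_mean(dose, structures[["Lungs"]]),
    heart_dmean = d_mean(dose, structures[["Heart"]]),
    breastcl_dmean = d_mean(dose, structures[["BreastCL"]])
  )
  ev <- evaluate_goals(m, goals)
  tc <- tcp_from_curve(curve, tcp_params)
  risks <- risk_panel(m$heart_dmean, m$lungs_dmean, risk_registry)
  structure(c(m, ev, list(tcp = tc, risks = risks)), class = "plan_metrics")
}
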