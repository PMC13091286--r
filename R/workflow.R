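#' Workflow route times
#'
#' Hands-on (`t_active`, minutes) and between-steps (`t_inter`, working
#' hours) times per plan for the current workflow and the four candidate
#' routes of the automated workflow. Defaults: current 85 min / 37 h,
#' A 20 / 16, B 25 / 24, C 75 / 36, D 70 / 36.
#'
#' @param t_active named numeric, minutes, names
#'   `current, A, B, C, D`.
#' @param t_inter named numeric, hours, same names.
#' @return list of class `route_times`.
#' @export
route_times <- function(
    t_active = c(current = 85, A = 20, B = 25, C = 75, D = 70),
    t_inter = c(current = 37, A = 16, B = 24, C = 36, D = 36)) {
  need <- c("current", "A", "B", "C", "D")
  if (!all(need %in% names(t_active)) || !all(need %in% names(t_inter)))
    stop("route times must name current, A, B, C, D")
  if (any(t_active < 0) || any(t_inter < 0)) stop("times must be >= 0")
  if (t_active[["A"]] > t_active[["current"]])
    stop("route A active time cannot exceed the current workflow's")
  structure(list(t_active = t_active[need], t_inter = t_inter[need]),
            class = "route_times")
}

#' Assign the workflow route for one patient
#'
#' Decision rules: route A if the fully automated plan (DLS-DLP) meets all
#' six clinical goals; otherwise route B if the target-corrected plan
#' (PS-DLP) meets all six; otherwise route C (standing in for the C/D
#' worst case -- D is never auto-assigned). TCP and NTCP play no part in
#' routing.
#'
#' @param dls_goals_met goals met (0-6) by the DLS-DLP setup.
#' @param ps_goals_met goals met (0-6) by the PS-DLP setup.
#' @return `"A"`, `"B"` or `"C"`.
#' @export
assign_route <- function(dls_goals_met, ps_goals_met) {
  for (g in c(dls_goals_met, ps_goals_met)) {
    if (is.na(g) || g < 0 || g > 6 || g != round(g))
      stop("goals_met must be an integer in 0..6")
  }
  if (dls_goals_met == 6) "A" else if (ps_goals_met == 6) "B" else "C"
}

#' Average workflow time saving per patient
#'
#' Difference between the current workflow's times and the count-weighted
#' mean over the assigned routes: `delta = t(current) - sum(n_r t_r) /
#' sum(n_r)`. Patients routed C/D use route-C times (worst case).
#'
#' @param route_counts named counts over routes `current`, `A`, `B`, `C`,
#'   `D` (unnamed vectors are taken as `A`, `B`, `C`).
#' @param times a [route_times()].
#' @return list `dt_active_min`, `dt_inter_h`, `n`.
#' @export
time_saving <- function(route_counts, times = route_times()) {
  stopifnot(inherits(times, "route_times"))
  if (is.null(names(route_counts)))
    names(route_counts) <- c("A", "B", "C")[seq_along(route_counts)]
  bad <- setdiff(names(route_counts), c("current", "A", "B", "C", "D"))
  if (length(bad)) stop("unknown route(s): ", paste(bad, collapse = ", "))
  counts <- unlist(route_counts)
  if (any(counts < 0)) stop("route counts must be >= 0")
  n <- sum(counts)
  if (n == 0) stop("no patients routed")
  rs <- names(counts)
  list(
    dt_active_min = times$t_active[["current"]] -
      sum(counts * times$t_active[rs]) / n,
    dt_inter_h = times$t_inter[["current"]] -
      sum(counts * times$t_inter[rs]) / n,
    n = n
  )
}

#' Summarize an evaluated cohort
#'
#' From the per-patient, per-setup evaluation table: median (Q1-Q3) of
#' every metric per setup (linear-interpolation quartiles, type 7),
#' percentage of patients meeting at least k of the six goals for
#' k = 3..6 (rounded to integers), route counts, and the average time
#' saving.
#'
#' @param evals data.frame in the cohort evaluation layout (one row per
#'   patient x setup) as produced by [generate_cohort()] or
#'   [read_cohort_csv()].
#' @param times a [route_times()].
#' @return list of class `cohort_summary`.
#' @export
summarize_cohort <- function(evals, times = route_times()) {
  setups <- c("CS_CP", "DLS_DLP", "CS_DLP", "PS_DLP")
  metrics <- c("ptv_dmean", "ptv_d98", "ptv_d2", "lungs_dmean",
               "heart_dmean", "breastcl_dmean", "tcp",
               "aer_w", "aer_wo", "aemr_cardiac_w", "aemr_cardiac_wo",
               "aemr_lung_w", "aemr_lung_wo")
  metrics <- intersect(metrics, names(evals))
  present <- intersect(setups, unique(evals$setup))
  quart <- do.call(rbind, lapply(present, function(s) {
    sub <- evals[evals$setup == s, , drop = FALSE]
    do.call(rbind, lapply(metrics, function(m) {
      q <- stats::quantile(sub[[m]], c(0.25, 0.5, 0.75), type = 7,
                           names = FALSE, na.rm = TRUE)
      data.frame(setup = s, metric = m, q1 = q[1], median = q[2], q3 = q[3],
                 stringsAsFactors = FALSE)
    }))
  }))
  goal_pct <- do.call(rbind, lapply(present, function(s) {
    gm <- evals$goals_met[evals$setup == s]
    data.frame(setup = s,
               k = 3:6,
               pct = sapply(3:6, function(k) round(100 * mean(gm >= k))),
               stringsAsFactors = FALSE)
  }))
  # routing needs both decision setups
  routes <- NULL; counts <- NULL; saving <- NULL
  if (all(c("DLS_DLP", "PS_DLP") %in% present)) {
    ids <- unique(evals$patient_id)
    routes <- vapply(ids, function(id) {
      assign_route(
        evals$goals_met[evals$patient_id == id & evals$setup == "DLS_DLP"],
        evals$goals_met[evals$patient_id == id & evals$setup == "PS_DLP"])
    }, character(1))
    counts <- c(A = sum(routes == "A"), B = sum(routes == "B"),
                C = sum(routes == "C"))
    saving <- time_saving(counts, times)
  }
  structure(list(quartiles = quart, goal_pct = goal_pct,
                 route_counts = counts, routes = routes,
                 time_saving = saving,
                 n = length(unique(evals$patient_id))),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary, %d patients>\n", x$n))
  if (!is.null(x$route_counts)) {
    cat("routes:", paste(names(x$route_counts), x$route_counts,
                         sep = "=", collapse = ", "), "\n")
    cat(sprintf("time saving: %.1f min active, %.1f h inter\n",
                x$time_saving$dt_active_min, x$time_saving$dt_inter_h))
  }
  invisible(x)
}
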