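# Orchestration and reporting: cohort evaluation CSV, DVH CSV dialect,
# YAML run configuration, summary tables in the clinical layout
# (median (Q1-Q3) per setup), statistics report, provenance echo.

cohort_csv_cols <- c("patient_id", "setup", "ptv_dmean", "ptv_d98", "ptv_d2",
                     "lungs_dmean", "heart_dmean", "breastcl_dmean",
                     "goals_met", "tcp", "aer_w", "aer_wo",
                     "aemr_cardiac_w", "aemr_cardiac_wo",
                     "aemr_lung_w", "aemr_lung_wo", "route")

#' Write / read the cohort evaluation CSV
#'
#' Fixed column order
#' `patient_id,setup,...,goals_met,tcp,aer_w,...,route`; full precision
#' (15 significant digits), so a written table re-reads bit-identically
#' for reporting purposes.
#'
#' @param evals cohort evaluation data.frame.
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_cohort_csv <- function(evals, path) {
  miss <- setdiff(cohort_csv_cols, names(evals))
  if (length(miss)) stop("evaluation table missing columns: ",
                         paste(miss, collapse = ", "))
  df <- evals[, cohort_csv_cols]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(cohort_csv_cols, names(df))
  if (length(miss)) stop("cohort CSV missing columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' Write / read DVH curves in the DVH CSV dialect
#'
#' Header `dose_gy,<structure1>,<structure2>,...`, one row per ascending
#' bin edge, volume fractions with 6 decimals. Curves are padded with
#' zeros beyond their own maximum dose so all share the longest edge
#' grid; the reader tolerates comment lines starting with `#`.
#'
#' @param curves named list of [dvh_curve()]s on a common bin width.
#' @param path file path.
#' @return `path` (write) or a named list of curves (read).
#' @export
write_dvh_csv <- function(curves, path) {
  if (!length(curves)) stop("no curves to write")
  widths <- vapply(curves, function(cv) stats::median(diff(cv$bin_edges)),
                   numeric(1))
  if (max(widths) - min(widths) > 1e-9)
    stop("curves must share one bin width")
  edges <- curves[[which.max(vapply(curves, function(cv)
    length(cv$bin_edges), integer(1)))]]$bin_edges
  tab <- data.frame(dose_gy = sprintf("%.6f", edges))
  for (nm in names(curves)) {
    v <- curves[[nm]]$cum_volume
    tab[[nm]] <- sprintf("%.6f", c(v, rep(0, length(edges) - length(v))))
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dvh_csv
#' @export
read_dvh_csv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        stringsAsFactors = FALSE)
  if (names(df)[1] != "dose_gy") stop("DVH CSV must start with dose_gy column")
  lapply(stats::setNames(nm = names(df)[-1]), function(nm)
    dvh_curve(nm, df$dose_gy, df[[nm]]))
}

#' Run configuration
#'
#' Bundles every setting of a pipeline run; fully serializable to YAML so
#' the report can echo an exact copy.
#'
#' @param cohort a [cohort_config()] (carries the seed).
#' @param times a [route_times()].
#' @param alpha significance level for the statistics chain.
#' @param out_dir output directory for the report bundle.
#' @param mode `"dvh"` or `"voxel"` simulation fidelity.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), times = route_times(),
                       alpha = 0.05, out_dir = "results", mode = "dvh") {
  structure(list(cohort = cohort, times = times, alpha = alpha,
                 out_dir = out_dir, mode = mode),
            class = "run_config")
}

#' Run the full evaluation pipeline
#'
#' Simulates (or accepts) an evaluated cohort, writes the per-patient
#' evaluation CSV, the cohort summary tables (median (Q1-Q3) per setup,
#' goals-met percentages), route counts and time savings, the
#' statistical comparison report and a provenance echo of the full
#' configuration. All DVH metrics of the deep-learning plans are
#' evaluated against the reference (simulated-truth) structures. Any
#' stage error removes the partial bundle.
#'
#' @param config a [run_config()].
#' @param evals optional pre-computed cohort evaluation table (skips
#'   simulation).
#' @return list of class `report_bundle` with `evals`, `summary`,
#'   `tables`, `stats`, `files`.
#' @export
run_pipeline <- function(config = run_config(), evals = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e, stage) {
    unlink(written)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) on_fail(e, name))
  }
  if (is.null(evals)) {
    evals <- stage("simulate", {
      co <- generate_cohort(config$cohort, mode = config$mode)
      message(sprintf("stage simulate: %d patients in = %d patients out",
                      config$cohort$n_patients,
                      length(unique(co$evals$patient_id))))
      co$evals
    })
  }
  out <- function(f) file.path(config$out_dir, f)
  stage("evaluation-csv", {
    write_cohort_csv(evals, out("cohort_evaluation.csv"))
    written <- c(written, out("cohort_evaluation.csv"))
    message(sprintf("stage evaluation-csv: %d rows", nrow(evals)))
  })
  summary <- stage("summarize", {
    s <- summarize_cohort(evals, config$times)
    message(sprintf("stage summarize: %d patients in = %d patients out",
                    length(unique(evals$patient_id)), s$n))
    s
  })
  tables <- stage("render", render_summary(summary))
  stage("write-tables", {
    utils::write.csv(tables$dvh, out("table_dvh_parameters.csv"),
                     row.names = FALSE)
    utils::write.csv(tables$risk, out("table_risk_panel.csv"),
                     row.names = FALSE)
    utils::write.csv(tables$goals, out("table_goals_met.csv"),
                     row.names = FALSE)
    written <- c(written, out(c("table_dvh_parameters.csv",
                                 "table_risk_panel.csv",
                                 "table_goals_met.csv")))
  })
  stats_rep <- stage("statistics", {
    r <- cohort_statistics(evals, alpha = config$alpha)
    message(sprintf("stage statistics: %d metrics in = %d reports out",
                    length(r), length(r)))
    r
  })
  stage("statistics-csv", {
    utils::write.csv(stats_report_table(stats_rep), out("statistics.csv"),
                     row.names = FALSE)
    written <- c(written, out("statistics.csv"))
  })
  stage("routing", {
    rt <- data.frame(route = names(summary$route_counts),
                     n = as.integer(summary$route_counts))
    rt$percent <- round(100 * rt$n / sum(rt$n))
    utils::write.csv(rt, out("route_counts.csv"), row.names = FALSE)
    ts <- summary$time_saving
    utils::write.csv(
      data.frame(dt_active_min = ts$dt_active_min, dt_inter_h = ts$dt_inter_h),
      out("time_saving.csv"), row.names = FALSE)
    written <- c(written, out(c("route_counts.csv", "time_saving.csv")))
    message(sprintf("stage routing: %d patients in = %d patients out",
                    summary$n, sum(rt$n)))
  })
  stage("provenance", {
    jsonlite::write_json(serialize_config(config), out("provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, out("provenance.json"))
  })
  structure(list(evals = evals, summary = summary, tables = tables,
                 stats = stats_rep,
                 files = written),
            class = "report_bundle")
}

serialize_config <- function(config) {
  co <- config$cohort
  list(
    n_patients = co$n_patients, seed = co$seed, mode = config$mode,
    alpha = config$alpha,
    rho_setup = co$rho_setup, rho_metric = co$rho_metric,
    defect_fraction = co$defect_fraction,
    defect_depth_gy = co$defect_depth_gy,
    defect_volume = co$defect_volume,
    bin_width = co$bin_width,
    targets = co$targets,
    contour_targets = co$contour_targets,
    tcp = unclass(co$tcp_params),
    risk_models = lapply(co$risk_registry, unclass),
    goals = co$goals,
    route_times = list(t_active = as.list(config$times$t_active),
                       t_inter = as.list(config$times$t_inter))
  )
}

# per-metric paired statistics across the four setups
cohort_statistics <- function(evals, alpha = 0.05) {
  setups <- c("CS_CP", "DLS_DLP", "CS_DLP", "PS_DLP")
  metrics <- c("ptv_dmean", "ptv_d98", "ptv_d2", "lungs_dmean",
               "heart_dmean", "breastcl_dmean", "tcp")
  ids <- unique(evals$patient_id)
  out <- list()
  for (m in metrics) {
    wide <- sapply(setups, function(s)
      evals[[m]][match(paste(ids, s),
                       paste(evals$patient_id, evals$setup))])
    out[[m]] <- compare_setups(wide, alpha = alpha)
  }
  out
}

stats_report_table <- function(stats_rep) {
  do.call(rbind, lapply(names(stats_rep), function(m) {
    r <- stats_rep[[m]]
    base <- data.frame(metric = m, friedman_chisq = r$friedman$statistic,
                       friedman_p = r$friedman$p_value,
                       stringsAsFactors = FALSE)
    if (is.null(r$posthoc)) {
      base$pair <- NA_character_; base$wilcoxon_p_adj <- NA_real_
      base
    } else {
      cbind(base[rep(1, nrow(r$posthoc)), c("metric", "friedman_chisq",
                                            "friedman_p")],
            data.frame(pair = r$posthoc$pair,
                       wilcoxon_p_adj = r$posthoc$p_adj))
    }
  }))
}

fmt_cell <- function(median, q1, q3, digits = 1) {
  if (any(!is.finite(c(median, q1, q3)))) return("—")
  sprintf("%.*f (%.*f–%.*f)", digits, median, digits, q1, digits, q3)
}

#' Render a cohort summary as clinical-layout tables
#'
#' One row per evaluation metric, one column per plan setup, cells
#' `median (Q1-Q3)`: doses with 1 decimal in Gy, TCP and excess risks in
#' percent with 1 decimal. A separate goals-met table gives the integer
#' percentage of patients meeting at least k of the six goals.
#'
#' @param summary a [summarize_cohort()] result.
#' @return list of data.frames `dvh`, `risk`, `goals`.
#' @export
render_summary <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"))
  q <- summary$quartiles
  setups <- unique(q$setup)
  dose_metrics <- c(ptv_dmean = "PTVp-Skin05 - D_mean [Gy]",
                    ptv_d98 = "PTVp-Skin05 - D_98 [Gy]",
                    ptv_d2 = "PTVp-Skin05 - D_2 [Gy]",
                    lungs_dmean = "Lungs - D_mean [Gy]",
                    heart_dmean = "Heart - D_mean [Gy]",
                    breastcl_dmean = "Breast CL - D_mean [Gy]")
  risk_metrics <- c(tcp = "TCP [%]",
                    aer_w = "AER acute coronary events, with RF [%]",
                    aer_wo = "AER acute coronary events, without RF [%]",
                    aemr_cardiac_w = "AEMR cardiac disease, with RF [%]",
                    aemr_cardiac_wo = "AEMR cardiac disease, without RF [%]",
                    aemr_lung_w = "AEMR secondary lung cancer, with RF [%]",
                    aemr_lung_wo = "AEMR secondary lung cancer, without RF [%]")
  one_table <- function(metric_labels, scale = 1) {
    rows <- lapply(names(metric_labels), function(m) {
      cells <- vapply(setups, function(s) {
        row <- q[q$setup == s & q$metric == m, ]
        if (!nrow(row)) {
          warning(sprintf("no data for metric '%s' in setup %s", m, s))
          return("—")
        }
        fmt_cell(row$median * scale, row$q1 * scale, row$q3 * scale)
      }, character(1))
      c(metric = metric_labels[[m]], cells)
    })
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- c("metric", setups)
    df
  }
  dvh_tab <- one_table(dose_metrics)
  risk_tab <- one_table(risk_metrics[names(risk_metrics) %in% q$metric])
  # TCP is stored as a probability; report in percent
  if ("tcp" %in% q$metric) {
    tcp_row <- vapply(setups, function(s) {
      row <- q[q$setup == s & q$metric == "tcp", ]
      fmt_cell(row$median * 100, row$q1 * 100, row$q3 * 100)
    }, character(1))
    risk_tab[risk_tab$metric == "TCP [%]", setups] <- tcp_row
  }
  gp <- summary$goal_pct
  goals_tab <- data.frame(goals = sprintf("≥%d/6 goals", 6:3))
  for (s in setups)
    goals_tab[[s]] <- vapply(6:3, function(k)
      gp$pct[gp$setup == s & gp$k == k], numeric(1))
  list(dvh = dvh_tab, risk = risk_tab, goals = goals_tab)
}

#' Read / write a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` (write); a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(serialize_config(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  targets <- lapply(y$targets, function(s) lapply(s, as.numeric))
  goals <- if (is.null(y$goals)) default_goals() else
    as.data.frame(y$goals, stringsAsFactors = FALSE)
  tcp_p <- if (is.null(y$tcp)) default_tcp_params() else
    do.call(tcp_params, y$tcp[c("a", "tcd50", "gamma50", "eqd2_enabled",
                                "alpha_beta", "n_fractions",
                                "dose_per_fraction_ref")])
  reg <- if (is.null(y$risk_models)) default_risk_registry() else
    lapply(y$risk_models, function(m)
      risk_model(m$endpoint, m$organ, m$err_per_gy,
                 m$baseline_with_rf, m$baseline_without_rf))
  ct <- if (is.null(y$contour_targets)) default_contour_targets() else
    as.data.frame(y$contour_targets, stringsAsFactors = FALSE)
  co <- cohort_config(
    n_patients = y$n_patients, seed = y$seed,
    targets = if (length(targets)) targets else default_dvh_targets(),
    rho_setup = y$rho_setup, rho_metric = y$rho_metric,
    defect_fraction = y$defect_fraction,
    defect_depth_gy = as.numeric(y$defect_depth_gy),
    defect_volume = as.numeric(y$defect_volume),
    contour_targets = ct,
    bin_width = y$bin_width, tcp_params = tcp_p, risk_registry = reg,
    goals = goals)
  times <- route_times(unlist(y$route_times$t_active),
                       unlist(y$route_times$t_inter))
  run_config(cohort = co, times = times, alpha = y$alpha,
             mode = if (is.null(y$mode)) "dvh" else y$mode)
}
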