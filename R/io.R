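# Cohort readers/writers (CSV interchange, JSON/YAML sidecars) and the
# end-to-end pipeline: simulate -> indices -> anova -> predict -> roc ->
# report. Times are stored as hours since admission, states as the
# uppercase enum tokens, so no date or locale parsing is involved.

config_to_list <- function(config) {
  # matrices stored explicitly as lists of rows so that YAML and JSON
  # agree on orientation
  mat_rows <- function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
  dyn_to_list <- function(d) {
    list(ps_pre = mat_rows(d$ps_pre), ps_post = mat_rows(d$ps_post),
         pr_pre = mat_rows(d$pr_pre), pr_post = mat_rows(d$pr_post),
         ps_init = d$ps_init, pr_init = d$pr_init)
  }
  l <- unclass(config)
  l$favorable_dynamics <- dyn_to_list(config$favorable_dynamics)
  l$unfavorable_dynamics <- dyn_to_list(config$unfavorable_dynamics)
  l
}

config_from_list <- function(l) {
  as_mat <- function(x, n) if (is.matrix(x)) x else matrix(unlist(x), n, n, byrow = TRUE)
  fd <- l$favorable_dynamics
  ud <- l$unfavorable_dynamics
  cohort_config(
    n_favorable = l$n_favorable, n_unfavorable = l$n_unfavorable,
    stay_mean_days = l$stay_mean_days, stay_sd_days = l$stay_sd_days,
    sedation_mean_days = l$sedation_mean_days,
    sedation_sd_days = l$sedation_sd_days,
    interval_hours = l$interval_hours,
    favorable_dynamics = group_dynamics(
      as_mat(fd$ps_pre, 5), as_mat(fd$ps_post, 5),
      as_mat(fd$pr_pre, 4), as_mat(fd$pr_post, 4),
      unlist(fd$ps_init), unlist(fd$pr_init)),
    unfavorable_dynamics = group_dynamics(
      as_mat(ud$ps_pre, 5), as_mat(ud$ps_post, 5),
      as_mat(ud$pr_pre, 4), as_mat(ud$pr_post, 4),
      unlist(ud$ps_init), unlist(ud$pr_init)),
    missingness = l$missingness,
    seed = l$seed
  )
}

#' Write a cohort to a directory
#'
#' Writes `patients.csv` (patient_id, sedation_stop_h, discharge_h,
#' gose_6m, outcome) and `observations.csv` (patient_id, time_h,
#' ps_state, pr_state), states as uppercase enum tokens, plus a
#' `cohort_config.json` sidecar recording the full simulation config and
#' seed when one is attached to the cohort (or passed explicitly).
#'
#' @param cohort A [pupil_cohort()].
#' @param dir Output directory (created if absent).
#' @param config Optional [cohort_config()]; defaults to
#'   `attr(cohort, "config")`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = attr(cohort, "config")) {
  stopifnot(inherits(cohort, "pupil_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$patients, file.path(dir, "patients.csv"))
  readr::write_csv(cohort$observations, file.path(dir, "observations.csv"))
  if (!is.null(config)) {
    jsonlite::write_json(config_to_list(config),
                         file.path(dir, "cohort_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read and validate a cohort directory
#'
#' Reads `patients.csv` and `observations.csv` as written by
#' [write_cohort()] and runs full [pupil_cohort()] validation: unknown
#' state tokens, non-monotone times, orphan observations and
#' outcome/GOSE inconsistencies are rejected with the offending rows
#' named. A `cohort_config.json` sidecar, if present, is re-validated
#' (row-stochasticity within 1e-9) and re-attached.
#'
#' @param dir Directory containing the two CSV files.
#' @return A [pupil_cohort()].
#' @export
read_cohort <- function(dir) {
  pf <- file.path(dir, "patients.csv")
  of <- file.path(dir, "observations.csv")
  if (!file.exists(pf) || !file.exists(of)) {
    stop_validation("cohort directory must contain patients.csv and ",
                    "observations.csv: ", dir)
  }
  patients <- readr::read_csv(pf, show_col_types = FALSE)
  observations <- readr::read_csv(of, show_col_types = FALSE)
  cohort <- pupil_cohort(patients, observations)
  cf <- file.path(dir, "cohort_config.json")
  if (file.exists(cf)) {
    attr(cohort, "config") <- config_from_list(
      jsonlite::read_json(cf, simplifyVector = TRUE))
  }
  cohort
}

#' Pipeline configuration
#'
#' Bundles every option of the end-to-end run. Round-trips losslessly
#' through YAML via [write_pipeline_config()] / [read_pipeline_config()]
#' (numbers written with 12 significant digits; the shipped defaults are
#' exact 2-decimal values).
#'
#' @param cohort A [cohort_config()] describing the simulated cohort.
#' @param nd_range Days for the prognosis sweep (default 0:10).
#' @param denominator Jump-rate denominator convention.
#' @param roc_predictor Index for the ROC analysis.
#' @param roc_mode `"insample"` or `"loocv"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            nd_range = 0:10,
                            denominator = c("measurements", "transitions"),
                            roc_predictor = "ps_isochoria_pct",
                            roc_mode = c("insample", "loocv")) {
  structure(list(
    cohort = cohort,
    nd_range = as.integer(nd_range),
    denominator = match.arg(denominator),
    roc_predictor = match.arg(roc_predictor, index_names()),
    roc_mode = match.arg(roc_mode)
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  l <- unclass(config)
  l$cohort <- config_to_list(config$cohort)
  yaml::write_yaml(l, path, precision = 12)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  l <- yaml::read_yaml(path)
  pipeline_config(
    cohort = config_from_list(l$cohort),
    nd_range = l$nd_range,
    denominator = l$denominator,
    roc_predictor = l$roc_predictor,
    roc_mode = l$roc_mode
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_validation("pipeline stage '", stage, "' failed: ",
                    conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' simulate -> indices (per-day, cumulative, pre/post) -> mixed ANOVA per
#' index -> model-selection sweep -> ROC sweep -> human-readable summary.
#' Deterministic given the seed inside the cohort config: running the
#' same config twice produces byte-identical outputs. Any stage failure
#' aborts with the stage name and cause.
#'
#' @param config A [pipeline_config()] or path to its YAML file.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the computed tables; files written:
#'   `patients.csv`, `observations.csv`, `cohort_config.json`,
#'   `indices_perday.csv`, `indices_cumulative.csv`,
#'   `indices_prepost.csv`, `anova.json`, `scores.csv`,
#'   `best_models.csv`, `roc.json`, `summary.txt`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- run_stage("simulate", generate_cohort(config$cohort))
  write_cohort(cohort, out_dir)

  perday <- run_stage("indices",
    index_timecourse(cohort, "per_day", denominator = config$denominator))
  cumul <- run_stage("indices",
    index_timecourse(cohort, "cumulative_days", nd_max = max(config$nd_range),
                     denominator = config$denominator))
  prepost <- run_stage("indices",
    pre_post_indices(cohort, denominator = config$denominator))
  readr::write_csv(perday, file.path(out_dir, "indices_perday.csv"))
  readr::write_csv(cumul, file.path(out_dir, "indices_cumulative.csv"))
  readr::write_csv(prepost, file.path(out_dir, "indices_prepost.csv"))

  anova_res <- run_stage("anova", {
    lapply(stats::setNames(index_names(), index_names()), function(ix) {
      d <- data.frame(patient_id = prepost$patient_id,
                      group = prepost$outcome,
                      period = prepost$period,
                      value = prepost[[ix]])
      a <- mixed_anova(d)
      ph <- posthoc_six(d)
      list(anova = as.data.frame(a), posthoc = as.data.frame(ph),
           n_patients = attr(a, "n_patients"))
    })
  })
  jsonlite::write_json(anova_res, file.path(out_dir, "anova.json"),
                       auto_unbox = TRUE, digits = NA)

  sweep <- run_stage("predict",
    model_selection_sweep(cohort, nd_range = config$nd_range,
                          denominator = config$denominator))
  best <- best_models(sweep)
  readr::write_csv(sweep, file.path(out_dir, "scores.csv"))
  readr::write_csv(best, file.path(out_dir, "best_models.csv"))

  rocs <- run_stage("roc",
    roc_sweep(cohort, predictor = config$roc_predictor,
              nd_range = config$nd_range, mode = config$roc_mode,
              denominator = config$denominator))
  roc_out <- list(
    predictor = config$roc_predictor, mode = config$roc_mode,
    auc_by_nd = as.data.frame(rocs),
    curves = lapply(attr(rocs, "curves"), function(r) {
      list(auc = r$auc, thresholds = r$thresholds,
           sensitivity = r$sensitivity, specificity = r$specificity)
    })
  )
  jsonlite::write_json(roc_out, file.path(out_dir, "roc.json"),
                       auto_unbox = TRUE, digits = NA)

  run_stage("report", {
    con <- file(file.path(out_dir, "summary.txt"), "w")
    on.exit(close(con))
    w <- function(...) writeLines(paste0(...), con)
    np <- nrow(cohort$patients)
    w("pupildyn pipeline summary")
    w("=========================")
    w("cohort: ", np, " patients (",
      sum(cohort$patients$outcome == "FAVORABLE"), " favorable / ",
      sum(cohort$patients$outcome == "UNFAVORABLE"), " unfavorable), ",
      nrow(cohort$observations), " observations, seed ",
      config$cohort$seed)
    w("")
    w("mixed ANOVA (outcome x period), per index:")
    for (ix in index_names()) {
      a <- anova_res[[ix]]$anova
      w(sprintf("  %-18s between F=%.3f p=%.4g | period F=%.3f p=%.4g | interaction F=%.3f p=%.4g",
                ix, a$F[1], a$p[1], a$F[2], a$p[2], a$F[3], a$p[3]))
    }
    w("")
    w("best model per day (BIC criterion):")
    bb <- best[best$criterion == "bic", ]
    for (i in seq_len(nrow(bb))) {
      w(sprintf("  ND %2d: %-60s BIC=%.2f", bb$nd[i], bb$subset[i], bb$value[i]))
    }
    w("")
    w("AUC of ", config$roc_predictor, " by day:")
    for (i in seq_len(nrow(rocs))) {
      w(sprintf("  ND %2d: AUC=%.3f (n=%d)", rocs$nd[i], rocs$auc[i], rocs$n[i]))
    }
    w("")
    w("per-patient whole-stay indices:")
    whole <- indices_for_window(
      cohort, time_window(0, max(cohort$observations$time_h) + 1, "stay"),
      denominator = config$denominator)
    for (i in seq_len(nrow(whole))) {
      w(sprintf("  %s %-12s ps_jump=%.3f iso=%.3f pr_jump=%.3f pres=%.3f (n=%d)",
                whole$patient_id[i], whole$outcome[i], whole$ps_jump_rate[i],
                whole$ps_isochoria_pct[i], whole$pr_jump_rate[i],
                whole$pr_presence_pct[i], whole$n_obs[i]))
    }
  })

  invisible(list(cohort = cohort, perday = perday, cumulative = cumul,
                 prepost = prepost, anova = anova_res, sweep = sweep,
                 best = best, roc = rocs))
}
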