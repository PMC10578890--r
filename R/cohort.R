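#' Assemble and validate a pupillary-observation cohort
#'
#' A cohort bundles two tables. `patients` holds one row per patient:
#' `patient_id`, `sedation_stop_h` (hours since ICU admission at which
#' analgosedation ended), `discharge_h` (hours at ICU discharge),
#' `gose_6m` (Glasgow Outcome Scale Extended at 6 months, 1--8) and
#' `outcome` (`"FAVORABLE"` iff `gose_6m > 4`, else `"UNFAVORABLE"`).
#' `observations` holds one row per bedside reading: `patient_id`,
#' `time_h` (hours since admission, nominally on a 2-hour grid),
#' `ps_state` and `pr_state` (tokens from [ps_states()] / [pr_states()]).
#'
#' Validation enforces: known state tokens (offending rows are listed),
#' strictly increasing non-negative times within each patient, at least two
#' observations per patient, all observation times at or before discharge,
#' `0 < sedation_stop_h <= discharge_h`, the outcome/GOSE dichotomy, and no
#' orphan observations (every observation row must match a patient row).
#'
#' @param patients Data frame of per-patient metadata (columns above).
#' @param observations Data frame of bedside readings (columns above).
#' @return An object of class `pupil_cohort`: a list with tibbles
#'   `patients` and `observations`.
#' @seealso [generate_cohort()], [read_cohort()], [write_cohort()]
#' @export
pupil_cohort <- function(patients, observations) {
  patients <- tibble::as_tibble(patients)
  observations <- tibble::as_tibble(observations)

  need_p <- c("patient_id", "sedation_stop_h", "discharge_h", "gose_6m", "outcome")
  need_o <- c("patient_id", "time_h", "ps_state", "pr_state")
  miss_p <- setdiff(need_p, names(patients))
  miss_o <- setdiff(need_o, names(observations))
  if (length(miss_p)) {
    stop_validation("patients table lacks column(s): ", paste(miss_p, collapse = ", "))
  }
  if (length(miss_o)) {
    stop_validation("observations table lacks column(s): ", paste(miss_o, collapse = ", "))
  }
  patients$patient_id <- as.character(patients$patient_id)
  observations$patient_id <- as.character(observations$patient_id)

  if (anyDuplicated(patients$patient_id)) {
    stop_validation("duplicate patient_id in patients table: ",
                    patients$patient_id[duplicated(patients$patient_id)][1])
  }

  bad_ps <- which(!observations$ps_state %in% ps_states())
  if (length(bad_ps)) {
    stop_validation("unknown ps_state token(s) in observations row(s) ",
                    paste(utils::head(bad_ps, 5), collapse = ", "), ": ",
                    paste(unique(observations$ps_state[utils::head(bad_ps, 5)]),
                          collapse = ", "))
  }
  bad_pr <- which(!observations$pr_state %in% pr_states())
  if (length(bad_pr)) {
    stop_validation("unknown pr_state token(s) in observations row(s) ",
                    paste(utils::head(bad_pr, 5), collapse = ", "), ": ",
                    paste(unique(observations$pr_state[utils::head(bad_pr, 5)]),
                          collapse = ", "))
  }

  orphan <- which(!observations$patient_id %in% patients$patient_id)
  if (length(orphan)) {
    stop_validation("observation row(s) ",
                    paste(utils::head(orphan, 5), collapse = ", "),
                    " reference unknown patient_id ",
                    paste(unique(observations$patient_id[utils::head(orphan, 5)]),
                          collapse = ", "))
  }

  if (any(patients$gose_6m != round(patients$gose_6m)) ||
      any(patients$gose_6m < 1) || any(patients$gose_6m > 8)) {
    stop_validation("gose_6m must be an integer in 1..8")
  }
  if (!all(patients$outcome %in% c("FAVORABLE", "UNFAVORABLE"))) {
    stop_validation("outcome must be FAVORABLE or UNFAVORABLE")
  }
  mism <- which((patients$outcome == "FAVORABLE") != (patients$gose_6m > 4))
  if (length(mism)) {
    stop_validation("outcome/GOSE dichotomy violated for patient ",
                    patients$patient_id[mism[1]], ": gose_6m = ",
                    patients$gose_6m[mism[1]], " but outcome = ",
                    patients$outcome[mism[1]],
                    " (FAVORABLE iff GOSE > 4)")
  }
  if (any(patients$sedation_stop_h <= 0)) {
    stop_validation("sedation_stop_h must be > 0")
  }
  if (any(patients$discharge_h < patients$sedation_stop_h)) {
    stop_validation("discharge_h must be >= sedation_stop_h")
  }

  # Per-patient time checks.
  sp <- split(seq_len(nrow(observations)), observations$patient_id)
  discharge <- stats::setNames(patients$discharge_h, patients$patient_id)
  for (pid in patients$patient_id) {
    idx <- sp[[pid]]
    if (is.null(idx) || length(idx) < 2L) {
      stop_validation("patient ", pid, " has fewer than 2 observations")
    }
    tt <- observations$time_h[idx]
    if (any(tt < 0)) stop_validation("patient ", pid, " has negative observation times")
    if (any(diff(tt) <= 0)) {
      stop_validation("observation times not strictly increasing for patient ",
                      pid, " near row ", idx[which(diff(tt) <= 0)[1] + 1L])
    }
    if (any(tt > discharge[[pid]])) {
      stop_validation("patient ", pid, " has observations after discharge_h")
    }
  }

  structure(list(patients = patients, observations = observations),
            class = "pupil_cohort")
}

#' @export
print.pupil_cohort <- function(x, ...) {
  np <- nrow(x$patients)
  nf <- sum(x$patients$outcome == "FAVORABLE")
  cat("<pupil_cohort> ", np, " patients (", nf, " favorable / ", np - nf,
      " unfavorable), ", nrow(x$observations), " observations\n", sep = "")
  obs_per <- table(x$observations$patient_id)
  cat("  observations per patient: median ", stats::median(obs_per),
      " [", min(obs_per), "-", max(obs_per), "]\n", sep = "")
  invisible(x)
}

# 0/1 outcome coding used throughout prognosis: FAVORABLE = 1, UNFAVORABLE = 0.
outcome_binary <- function(outcome) as.integer(outcome == "FAVORABLE")
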