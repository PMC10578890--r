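#' Jump rate of a categorical state series
#'
#' The jump rate is the number of changes of state between consecutive
#' observed readings divided by the number of measurements N (default),
#' so it lies in \[0, (N-1)/N\]. The `"transitions"` option divides by
#' N - 1 instead, for users who prefer the per-transition rate. A change
#' across a gap in the grid (a missed reading between two observed ones)
#' counts as at most one change, because only observed consecutive pairs
#' are compared.
#'
#' @param states Ordered vector (character or factor) of observed states.
#' @param denominator `"measurements"` (N, the default) or
#'   `"transitions"` (N - 1).
#' @return The jump rate, or `NA_real_` when fewer than two observations
#'   make the index undefined (propagated as missing, never as zero).
#' @examples
#' jump_rate(c("ISOCHORIC", "ANISO_LEFT", "ANISO_LEFT", "ISOCHORIC"))  # 0.5
#' @export
jump_rate <- function(states, denominator = c("measurements", "transitions")) {
  denominator <- match.arg(denominator)
  states <- as.character(states)
  n <- length(states)
  if (n < 2L) return(NA_real_)
  changes <- sum(states[-1] != states[-n])
  changes / if (denominator == "measurements") n else (n - 1L)
}

#' Occupancy percentage of a state
#'
#' Fraction of observed time points spent in `normal_state`. Summed over
#' every state in the alphabet this partitions to 1 for any non-empty
#' series.
#'
#' @param states Ordered vector of observed states.
#' @param normal_state The state whose occupancy is measured.
#' @return Fraction in \[0, 1\], or `NA_real_` for an empty series.
#' @examples
#' occupancy_pct(c("ISOCHORIC", "ISOCHORIC", "ANISO_LEFT", "ISOCHORIC"),
#'               "ISOCHORIC")  # 0.75
#' @export
occupancy_pct <- function(states, normal_state) {
  states <- as.character(states)
  if (length(states) == 0L) return(NA_real_)
  mean(states == normal_state)
}

#' Define a half-open evaluation window
#'
#' Observations with `start <= time_h < end` belong to the window; a
#' reading exactly at a boundary belongs to the later window.
#'
#' @param start,end Window bounds in hours since admission (`start < end`).
#' @param label Optional label; defaults to `"[start,end)"`.
#' @return A `time_window` list.
#' @export
time_window <- function(start, end, label = NULL) {
  assert_scalar_number(start, "start", lower = 0)
  assert_scalar_number(end, "end")
  if (start >= end) stop_validation("window start must be < end")
  if (is.null(label)) label <- sprintf("[%g,%g)", start, end)
  structure(list(start = start, end = end, label = label),
            class = "time_window")
}

# The four indices on one patient's in-window states.
.index_row <- function(ps, pr, denominator) {
  n <- length(ps)
  tibble::tibble(
    n_obs = n,
    ps_jump_rate = jump_rate(ps, denominator),
    ps_isochoria_pct = occupancy_pct(ps, ps_normal_state()),
    pr_jump_rate = jump_rate(pr, denominator),
    pr_presence_pct = occupancy_pct(pr, pr_normal_state())
  )
}

#' Evaluate the four indices on a time window
#'
#' Computes, per patient, the pupil-size jump rate, isochoria percentage,
#' photo-reactivity jump rate and presence percentage over the
#' observations falling in the half-open window. Patients with no
#' in-window observation get `n_obs = 0` and missing indices; jump rates
#' additionally require at least two in-window observations.
#'
#' @param cohort A [pupil_cohort()].
#' @param window A [time_window()].
#' @param denominator Passed to [jump_rate()].
#' @return Tibble with one row per patient: `patient_id`, `outcome`,
#'   `window_label`, `n_obs` and the four indices.
#' @export
indices_for_window <- function(cohort, window,
                               denominator = c("measurements", "transitions")) {
  stopifnot(inherits(cohort, "pupil_cohort"), inherits(window, "time_window"))
  denominator <- match.arg(denominator)
  obs <- cohort$observations
  inw <- obs[obs$time_h >= window$start & obs$time_h < window$end, ]
  sp <- split(inw, inw$patient_id)
  rows <- lapply(cohort$patients$patient_id, function(pid) {
    o <- sp[[pid]]
    r <- if (is.null(o)) .index_row(character(0), character(0), denominator)
         else .index_row(o$ps_state, o$pr_state, denominator)
    dplyr::bind_cols(tibble::tibble(patient_id = pid), r)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::left_join(out,
                          cohort$patients[, c("patient_id", "outcome")],
                          by = "patient_id")
  dplyr::bind_cols(
    out[, "patient_id"], out[, "outcome"],
    tibble::tibble(window_label = window$label),
    out[, c("n_obs", index_names())]
  )
}

#' Per-day or cumulative index time courses
#'
#' `"per_day"` evaluates the indices on each calendar day
#' `[24k, 24(k+1))` of a patient's stay (the per-patient trajectories one
#' would plot for the entire length of stay). `"cumulative_days"`
#' evaluates them on expanding windows `[0, 24(ND+1))` for
#' ND = 0..min(`nd_max`, last full day): ND = 0 is the first day's data,
#' ND = 5 the first six days, and so on -- the windows the day-by-day
#' prognosis sweep consumes.
#'
#' @param cohort A [pupil_cohort()].
#' @param resolution `"per_day"` or `"cumulative_days"`.
#' @param nd_max Largest ND for the cumulative mode (default 10).
#' @param denominator Passed to [jump_rate()].
#' @return Long tibble: `patient_id`, `outcome`, `day` (or `nd`),
#'   `window_label`, `n_obs`, four index columns.
#' @export
index_timecourse <- function(cohort,
                             resolution = c("per_day", "cumulative_days"),
                             nd_max = 10L,
                             denominator = c("measurements", "transitions")) {
  stopifnot(inherits(cohort, "pupil_cohort"))
  resolution <- match.arg(resolution)
  denominator <- match.arg(denominator)
  out <- lapply(seq_len(nrow(cohort$patients)), function(i) {
    pid <- cohort$patients$patient_id[i]
    obs <- cohort$observations[cohort$observations$patient_id == pid, ]
    t_last <- max(obs$time_h)
    one <- pupil_cohort(cohort$patients[i, ], obs)
    if (resolution == "per_day") {
      days <- 0:floor(t_last / 24)
      dplyr::bind_rows(lapply(days, function(k) {
        w <- time_window(24 * k, 24 * (k + 1), sprintf("day%02d", k))
        dplyr::bind_cols(tibble::tibble(day = k),
                         indices_for_window(one, w, denominator))
      }))
    } else {
      nds <- 0:min(nd_max, floor(t_last / 24))
      dplyr::bind_rows(lapply(nds, function(k) {
        w <- time_window(0, 24 * (k + 1), sprintf("nd%02d", k))
        dplyr::bind_cols(tibble::tibble(nd = k),
                         indices_for_window(one, w, denominator))
      }))
    }
  })
  out <- dplyr::bind_rows(out)
  dplyr::relocate(out, "patient_id", "outcome")
}

#' Pre- and post-sedation indices
#'
#' Splits each patient's series at the sedation stop (PRE: observations
#' with `time_h < sedation_stop_h`; POST: the rest, through discharge)
#' and evaluates the four indices on each side. Patients with no
#' post-sedation observations get a POST row with `n_obs = 0` and missing
#' indices; pre/post analyses then exclude them listwise.
#'
#' @param cohort A [pupil_cohort()].
#' @param denominator Passed to [jump_rate()].
#' @return Long tibble: `patient_id`, `outcome`, `period` ("PRE"/"POST"),
#'   `n_obs`, four index columns.
#' @export
pre_post_indices <- function(cohort,
                             denominator = c("measurements", "transitions")) {
  stopifnot(inherits(cohort, "pupil_cohort"))
  denominator <- match.arg(denominator)
  out <- lapply(seq_len(nrow(cohort$patients)), function(i) {
    p <- cohort$patients[i, ]
    obs <- cohort$observations[cohort$observations$patient_id == p$patient_id, ]
    pre <- obs[obs$time_h < p$sedation_stop_h, ]
    post <- obs[obs$time_h >= p$sedation_stop_h, ]
    dplyr::bind_rows(
      dplyr::bind_cols(tibble::tibble(patient_id = p$patient_id,
                                      outcome = p$outcome, period = "PRE"),
                       .index_row(pre$ps_state, pre$pr_state, denominator)),
      dplyr::bind_cols(tibble::tibble(patient_id = p$patient_id,
                                      outcome = p$outcome, period = "POST"),
                       .index_row(post$ps_state, post$pr_state, denominator))
    )
  })
  dplyr::bind_rows(out)
}
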