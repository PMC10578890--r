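#' Markov dynamics of one outcome group
#'
#' The categorical pupil-size (5 states) and photo-reactivity (4 states)
#' series of a patient are modelled as independent first-order Markov
#' chains on the 2-hour observation grid, with a hard regime switch at the
#' end of sedation: transitions into times before `sedation_stop` use the
#' `*_pre` matrices, transitions into later times the `*_post` matrices.
#'
#' @param ps_pre,ps_post 5x5 row-stochastic transition matrices for the
#'   pupil-size chain (state order as [ps_states()]), pre-/post-sedation.
#' @param pr_pre,pr_post 4x4 row-stochastic matrices for the
#'   photo-reactivity chain (order as [pr_states()]).
#' @param ps_init,pr_init Initial state distributions at admission.
#' @return An object of class `group_dynamics`.
#' @export
group_dynamics <- function(ps_pre, ps_post, pr_pre, pr_post, ps_init, pr_init) {
  assert_stochastic(ps_pre,  "ps_pre",  5L)
  assert_stochastic(ps_post, "ps_post", 5L)
  assert_stochastic(pr_pre,  "pr_pre",  4L)
  assert_stochastic(pr_post, "pr_post", 4L)
  assert_distribution(ps_init, "ps_init", 5L)
  assert_distribution(pr_init, "pr_init", 4L)
  structure(list(ps_pre = unname(ps_pre), ps_post = unname(ps_post),
                 pr_pre = unname(pr_pre), pr_post = unname(pr_post),
                 ps_init = unname(ps_init), pr_init = unname(pr_init)),
            class = "group_dynamics")
}

# Row builder: self-transition `self` on state `i`, probability `to_normal`
# of returning to state 1, remainder spread evenly over the other states.
.row_to <- function(n, i, self, to_normal, spread) {
  r <- rep(spread, n)
  r[1] <- to_normal
  r[i] <- self
  r
}

#' Shipped default group dynamics
#'
#' Defaults encode the qualitative time-course pattern the indices are
#' designed to capture. Favorable patients hold stable isochoric,
#' photo-reactive pupils throughout (isochoric self-transition 0.96 during
#' sedation, 0.99 after; abnormal excursions are brief). Unfavorable
#' patients switch states frequently while sedated (isochoric
#' self-transition 0.70) and after sedation ends stabilize toward
#' pathological size states (abnormal self-transition 0.92, return to
#' isochoria 0.02). Photo-reactivity separates the groups only mildly
#' (stationary presence roughly 0.92 favorable vs 0.87 unfavorable during
#' sedation, drifting toward 0.78 afterwards in the unfavorable group),
#' so pupil size carries most of the prognostic signal, as in the
#' clinical pattern the indices are designed to expose.
#'
#' @param outcome `"FAVORABLE"` or `"UNFAVORABLE"`.
#' @return A [group_dynamics()] object.
#' @export
default_group_dynamics <- function(outcome = c("FAVORABLE", "UNFAVORABLE")) {
  outcome <- match.arg(outcome)
  if (outcome == "FAVORABLE") {
    ps_pre  <- rbind(c(0.96, 0.01, 0.01, 0.01, 0.01),
                     t(vapply(2:5, function(i) .row_to(5, i, 0.34, 0.60, 0.02),
                              numeric(5))))
    ps_post <- rbind(c(0.99, 0.0025, 0.0025, 0.0025, 0.0025),
                     t(vapply(2:5, function(i) .row_to(5, i, 0.17, 0.80, 0.01),
                              numeric(5))))
    pr_pre  <- rbind(c(0.95, 0.02, 0.015, 0.015),
                     t(vapply(2:4, function(i) .row_to(4, i, 0.39, 0.55, 0.03),
                              numeric(4))))
    pr_post <- rbind(c(0.99, 0.004, 0.003, 0.003),
                     t(vapply(2:4, function(i) .row_to(4, i, 0.21, 0.75, 0.02),
                              numeric(4))))
    ps_init <- c(0.90, 0.04, 0.04, 0.01, 0.01)
    pr_init <- c(0.90, 0.04, 0.03, 0.03)
  } else {
    ps_pre  <- rbind(c(0.70, 0.075, 0.075, 0.075, 0.075),
                     t(vapply(2:5, function(i) .row_to(5, i, 0.45, 0.25, 0.10),
                              numeric(5))))
    ps_post <- rbind(c(0.80, 0.05, 0.05, 0.05, 0.05),
                     t(vapply(2:5, function(i) .row_to(5, i, 0.92, 0.02, 0.02),
                              numeric(5))))
    pr_pre  <- rbind(c(0.92, 0.04, 0.02, 0.02),
                     t(vapply(2:4, function(i) .row_to(4, i, 0.35, 0.55, 0.05),
                              numeric(4))))
    pr_post <- rbind(c(0.93, 0.04, 0.015, 0.015),
                     t(vapply(2:4, function(i) .row_to(4, i, 0.69, 0.25, 0.03),
                              numeric(4))))
    ps_init <- c(0.40, 0.20, 0.20, 0.10, 0.10)
    pr_init <- c(0.80, 0.10, 0.05, 0.05)
  }
  group_dynamics(ps_pre, ps_post, pr_pre, pr_post, ps_init, pr_init)
}

#' Cohort simulation configuration
#'
#' Defaults mirror the scale of the kind of neuro-ICU cohort the analysis
#' is designed for: 14 favorable + 6 unfavorable patients, ICU stay
#' 17 +/- 9 days, sedation 9 +/- 6 days (both truncated below at 1 day;
#' sedation clipped to the stay), readings every 2 hours with 5% of grid
#' points missed, giving around 195 observations per patient.
#'
#' @param n_favorable,n_unfavorable Group sizes (>= 1).
#' @param stay_mean_days,stay_sd_days Mean/SD of ICU-stay length in days.
#' @param sedation_mean_days,sedation_sd_days Mean/SD of sedation length.
#' @param interval_hours Observation grid spacing (hours, default 2).
#' @param favorable_dynamics,unfavorable_dynamics [group_dynamics()]
#'   objects per outcome group.
#' @param missingness Probability in \[0, 1) that any grid point is missed.
#' @param seed Integer seed; `generate_cohort()` is reproducible given it.
#' @return An object of class `cohort_config` (a named list).
#' @export
cohort_config <- function(n_favorable = 14L, n_unfavorable = 6L,
                          stay_mean_days = 17, stay_sd_days = 9,
                          sedation_mean_days = 9, sedation_sd_days = 6,
                          interval_hours = 2,
                          favorable_dynamics = default_group_dynamics("FAVORABLE"),
                          unfavorable_dynamics = default_group_dynamics("UNFAVORABLE"),
                          missingness = 0.05,
                          seed = 1L) {
  n_favorable <- assert_count(n_favorable, "n_favorable", min = 1L)
  n_unfavorable <- assert_count(n_unfavorable, "n_unfavorable", min = 1L)
  assert_scalar_number(stay_mean_days, "stay_mean_days", lower = 0)
  assert_scalar_number(stay_sd_days, "stay_sd_days", lower = 0)
  assert_scalar_number(sedation_mean_days, "sedation_mean_days", lower = 0)
  assert_scalar_number(sedation_sd_days, "sedation_sd_days", lower = 0)
  assert_scalar_number(interval_hours, "interval_hours")
  if (interval_hours <= 0) stop_validation("interval_hours must be > 0")
  assert_scalar_number(missingness, "missingness", lower = 0)
  if (missingness >= 1) stop_validation("missingness must be < 1")
  stopifnot(inherits(favorable_dynamics, "group_dynamics"),
            inherits(unfavorable_dynamics, "group_dynamics"))
  structure(list(n_favorable = n_favorable, n_unfavorable = n_unfavorable,
                 stay_mean_days = stay_mean_days, stay_sd_days = stay_sd_days,
                 sedation_mean_days = sedation_mean_days,
                 sedation_sd_days = sedation_sd_days,
                 interval_hours = interval_hours,
                 favorable_dynamics = favorable_dynamics,
                 unfavorable_dynamics = unfavorable_dynamics,
                 missingness = missingness,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Truncated-normal draw by inverse CDF (one uniform per draw, keeping the
# RNG stream length independent of rejection behaviour).
rtnorm_low <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(max(mean, lower), n))
  plo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (1 - plo), mean, sd)
}

# Sample a regime-switching chain over `times`. The transition INTO time
# times[i] uses the pre matrix when times[i] < sedation_stop, else post.
sample_chain <- function(times, sedation_stop, pre, post, init) {
  n <- length(times)
  cum_pre <- t(apply(pre, 1, cumsum))
  cum_post <- t(apply(post, 1, cumsum))
  s <- integer(n)
  s[1] <- findInterval(stats::runif(1), cumsum(init)) + 1L
  if (n >= 2) {
    u <- stats::runif(n - 1)
    for (i in 2:n) {
      cum <- if (times[i] < sedation_stop) cum_pre else cum_post
      s[i] <- findInterval(u[i - 1], cum[s[i - 1], ]) + 1L
    }
  }
  s
}

#' Simulate one patient's observation series
#'
#' @param group_params A [group_dynamics()] object.
#' @param stay_hours Length of ICU stay in hours (>= `interval`).
#' @param sedation_stop Hours at which sedation ends (<= `stay_hours`).
#' @param interval Grid spacing in hours.
#' @param outcome `"FAVORABLE"` or `"UNFAVORABLE"`; GOSE at 6 months is
#'   drawn uniformly from 5..8 or 1..4 accordingly.
#' @param patient_id Identifier string.
#' @param missingness Per-grid-point drop probability in \[0, 1).
#' @return A one-patient [pupil_cohort()].
#' @details Observations are placed at t = 0, interval, 2*interval, ...
#'   up to `stay_hours` inclusive; a 16-day stay on the 2-hour grid gives
#'   193 readings. Dropped grid points are simply absent (no imputation);
#'   if dropping would leave fewer than two readings the first two grid
#'   points are retained. Uses the current RNG state; seed outside.
#' @export
generate_patient <- function(group_params, stay_hours, sedation_stop,
                             interval = 2, outcome = "FAVORABLE",
                             patient_id = "P01", missingness = 0) {
  if (!inherits(group_params, "group_dynamics")) {
    stop_validation("group_params must be a group_dynamics object")
  }
  assert_scalar_number(stay_hours, "stay_hours", lower = interval)
  assert_scalar_number(sedation_stop, "sedation_stop", lower = 0)
  if (sedation_stop > stay_hours) {
    stop_validation("sedation_stop must be <= stay_hours")
  }
  outcome <- match.arg(outcome, c("FAVORABLE", "UNFAVORABLE"))

  times <- seq(0, stay_hours, by = interval)
  ps <- sample_chain(times, sedation_stop,
                     group_params$ps_pre, group_params$ps_post,
                     group_params$ps_init)
  pr <- sample_chain(times, sedation_stop,
                     group_params$pr_pre, group_params$pr_post,
                     group_params$pr_init)
  keep <- rep(TRUE, length(times))
  if (missingness > 0) {
    keep <- stats::runif(length(times)) >= missingness
    if (sum(keep) < 2L) keep[1:2] <- TRUE
  }
  gose <- if (outcome == "FAVORABLE") sample(5:8, 1L) else sample(1:4, 1L)

  patients <- tibble::tibble(
    patient_id = patient_id,
    sedation_stop_h = sedation_stop,
    discharge_h = stay_hours,
    gose_6m = gose,
    outcome = outcome
  )
  observations <- tibble::tibble(
    patient_id = patient_id,
    time_h = times[keep],
    ps_state = ps_states()[ps[keep]],
    pr_state = pr_states()[pr[keep]]
  )
  pupil_cohort(patients, observations)
}

#' Simulate a full cohort
#'
#' Stay and sedation lengths are drawn per patient from truncated normal
#' distributions (truncated below at 1 day), rounded to the observation
#' grid, with sedation clipped to end no later than discharge. Patients
#' whose drawn sedation reaches discharge have no post-sedation
#' observations; downstream pre/post analyses exclude them listwise.
#'
#' @param config A [cohort_config()].
#' @return A [pupil_cohort()] with the config attached as attribute
#'   `"config"`. Reproducible: equal configs (including seed) give
#'   identical cohorts.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    stop_validation("config must be a cohort_config object")
  }
  set.seed(config$seed)
  n <- config$n_favorable + config$n_unfavorable
  outcome <- rep(c("FAVORABLE", "UNFAVORABLE"),
                 c(config$n_favorable, config$n_unfavorable))
  ids <- sprintf("P%02d", seq_len(n))
  iv <- config$interval_hours

  stay_h <- 24 * rtnorm_low(n, config$stay_mean_days, config$stay_sd_days, 1)
  sed_h <- 24 * rtnorm_low(n, config$sedation_mean_days, config$sedation_sd_days, 1)
  stay_h <- pmax(iv, round(stay_h / iv) * iv)
  sed_h <- pmax(iv, round(sed_h / iv) * iv)
  sed_h <- pmin(sed_h, stay_h)

  parts <- lapply(seq_len(n), function(i) {
    dyn <- if (outcome[i] == "FAVORABLE") config$favorable_dynamics
           else config$unfavorable_dynamics
    generate_patient(dyn, stay_h[i], sed_h[i], interval = iv,
                     outcome = outcome[i], patient_id = ids[i],
                     missingness = config$missingness)
  })
  cohort <- pupil_cohort(
    patients = dplyr::bind_rows(lapply(parts, `[[`, "patients")),
    observations = dplyr::bind_rows(lapply(parts, `[[`, "observations"))
  )
  attr(cohort, "config") <- config
  cohort
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized
#' to sum to 1. Used to reason about long-run state occupancy of the
#' simulated chains.
#'
#' @param m Row-stochastic square matrix.
#' @return Numeric stationary probability vector.
#' @export
stationary_distribution <- function(m) {
  assert_stochastic(m, "m", nrow(m))
  e <- eigen(t(m))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}
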