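# Independent oracles, coded deliberately apart from the package routines
# they check: explicit loops, closed forms and exhaustive enumeration.

# Brute-force loop versions of the two index primitives.
oracle_jump_rate <- function(states, per_transition = FALSE) {
  n <- length(states)
  changes <- 0L
  for (i in 2:n) if (states[i] != states[i - 1]) changes <- changes + 1L
  changes / if (per_transition) (n - 1) else n
}

oracle_occupancy <- function(states, normal) {
  hits <- 0L
  for (s in states) if (s == normal) hits <- hits + 1L
  hits / length(states)
}

# Cell-means sums-of-squares decomposition for the 2 (group, between) x
# 2 (period, within) mixed design. pre/post/group are per-patient vectors.
# Within-stratum effects computed through the difference variable
# d = post - pre; the between stratum through subject means.
oracle_mixed_anova <- function(pre, post, group) {
  group <- as.character(group)
  g <- sort(unique(group))
  stopifnot(length(g) == 2L)
  N <- length(pre)
  m_i <- (pre + post) / 2
  grand <- mean(c(pre, post))
  n_g <- sapply(g, function(gg) sum(group == gg))
  mg <- sapply(g, function(gg) mean(m_i[group == gg]))
  ss_group <- 2 * sum(n_g * (mg - grand)^2)
  ss_subj <- 2 * sum(sapply(g, function(gg) {
    sum((m_i[group == gg] - mg[gg])^2)
  }))
  d <- post - pre
  dbar <- mean(d)
  dg <- sapply(g, function(gg) mean(d[group == gg]))
  ss_period <- N * dbar^2 / 2
  ss_inter <- sum(n_g * (dg - dbar)^2) / 2
  ss_err_w <- sum(sapply(g, function(gg) sum((d[group == gg] - dg[gg])^2))) / 2
  list(
    F_group = (ss_group / 1) / (ss_subj / (N - 2)),
    F_period = (ss_period / 1) / (ss_err_w / (N - 2)),
    F_inter = (ss_inter / 1) / (ss_err_w / (N - 2)),
    df2 = N - 2
  )
}

# Exhaustive pairwise Mann-Whitney AUC: P(case score > control score),
# ties counting one half.
oracle_auc_pairwise <- function(score, y) {
  cases <- score[y == 1]
  controls <- score[y == 0]
  tot <- 0
  for (a in cases) {
    for (b in controls) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(cases) * length(controls))
}

# Limiting distribution by brute matrix powering (independent of the
# eigen-decomposition route in the package).
oracle_limit_distribution <- function(P, steps = 2000L) {
  M <- P
  for (i in seq_len(steps)) M <- M %*% P
  M[1, ]
}

# Hand-built cohort from explicit state sequences on the 2-h grid.
make_cohort <- function(ps, pr, sedation_stop, outcome = "FAVORABLE",
                        gose = if (outcome == "FAVORABLE") 6L else 3L,
                        id = "P01", interval = 2) {
  stopifnot(length(ps) == length(pr))
  times <- (seq_along(ps) - 1) * interval
  pupil_cohort(
    patients = tibble::tibble(patient_id = id,
                              sedation_stop_h = sedation_stop,
                              discharge_h = max(times),
                              gose_6m = gose, outcome = outcome),
    observations = tibble::tibble(patient_id = id, time_h = times,
                                  ps_state = ps, pr_state = pr)
  )
}

# Combine single-patient cohorts into one.
bind_cohorts <- function(...) {
  parts <- list(...)
  pupil_cohort(
    patients = dplyr::bind_rows(lapply(parts, `[[`, "patients")),
    observations = dplyr::bind_rows(lapply(parts, `[[`, "observations"))
  )
}

random_ps_series <- function(n) sample(ps_states(), n, replace = TRUE)
random_pr_series <- function(n) sample(pr_states(), n, replace = TRUE)

# Small, fast cohort config for structural tests.
fast_config <- function(seed = 1L, ...) {
  cohort_config(n_favorable = 5L, n_unfavorable = 4L,
                stay_mean_days = 6, stay_sd_days = 2,
                sedation_mean_days = 3, sedation_sd_days = 1,
                seed = seed, ...)
}
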