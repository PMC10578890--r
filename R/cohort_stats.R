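# Group-level inference: 2 (outcome, between) x 2 (period, within) mixed
# repeated-measures ANOVA, the six Bonferroni-corrected post-hoc contrasts,
# and clinical-covariate tests computable from printed group summaries.

# Listwise-complete long data: patients with both PRE and POST values.
.complete_prepost <- function(data) {
  need <- c("patient_id", "group", "period", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop_validation("data lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(data$period %in% c("PRE", "POST"))) {
    stop_validation("period must be PRE or POST")
  }
  ok <- stats::aggregate(value ~ patient_id, data = data,
                         FUN = function(v) sum(!is.na(v)))
  keep <- ok$patient_id[ok$value == 2L]
  d <- data[data$patient_id %in% keep & !is.na(data$value), ]
  per_group <- table(unique(d[, c("patient_id", "group")])$group)
  if (length(per_group) < 2L || any(per_group < 2L)) {
    stop_validation("insufficient data: need >= 2 patients with complete ",
                    "PRE/POST values in each group (have ",
                    paste(names(per_group), per_group, sep = "=", collapse = ", "),
                    ")")
  }
  d$patient_id <- factor(d$patient_id)
  d$group <- factor(d$group)
  d$period <- factor(d$period, levels = c("PRE", "POST"))
  d
}

#' Mixed repeated-measures ANOVA (outcome x period)
#'
#' Two-way mixed ANOVA with outcome group as the between-subjects factor
#' and period (PRE = during sedation, POST = after sedation end) as the
#' within-subjects factor, fitted on one pupillary index at a time.
#' Patients missing either period are excluded listwise. Sums of squares
#' are Type II; with the two-level within factor entered first this
#' coincides with the classical univariate mixed-model decomposition.
#' With zero error variance (e.g. all values identical) the F ratios are
#' undefined and returned as `NaN` with a warning.
#'
#' @param data Long data frame with columns `patient_id`, `group`
#'   (outcome label), `period` (`"PRE"`/`"POST"`) and `value`.
#' @return A tibble of class `pupil_anova` with one row per effect
#'   (`group`, `period`, `group:period`): `df1`, `df2`, `F`, `p`, plus
#'   attribute `n_patients`.
#' @export
mixed_anova <- function(data) {
  d <- .complete_prepost(data)
  ss_total <- sum((d$value - mean(d$value))^2)
  if (ss_total <= 1e-20 * max(1, mean(d$value)^2)) {
    warning("zero error variance: F ratios undefined (NaN)")
    out <- tibble::tibble(effect = c("group", "period", "group:period"),
                          df1 = 1, df2 = nlevels(d$patient_id) - 2,
                          F = NaN, p = NaN)
    attr(out, "n_patients") <- nlevels(d$patient_id)
    class(out) <- c("pupil_anova", class(out))
    return(out)
  }
  fit <- stats::aov(value ~ group * period + Error(patient_id), data = d)
  s <- summary(fit)
  grab <- function(stratum, term) {
    tab <- s[[stratum]][[1]]
    i <- match(term, trimws(rownames(tab)))
    r <- match("Residuals", trimws(rownames(tab)))
    F <- tab[i, "Sum Sq"] / tab[i, "Df"] / (tab[r, "Sum Sq"] / tab[r, "Df"])
    p <- stats::pf(F, tab[i, "Df"], tab[r, "Df"], lower.tail = FALSE)
    tibble::tibble(effect = term, df1 = tab[i, "Df"], df2 = tab[r, "Df"],
                   F = F, p = p)
  }
  out <- dplyr::bind_rows(
    grab("Error: patient_id", "group"),
    grab("Error: Within", "period"),
    grab("Error: Within", "group:period")
  )
  if (any(is.nan(out$F))) {
    warning("zero error variance: F ratios undefined (NaN)")
  }
  attr(out, "n_patients") <- nlevels(d$patient_id)
  class(out) <- c("pupil_anova", class(out))
  out
}

#' The six post-hoc comparisons, Bonferroni corrected
#'
#' Exactly six contrasts per index: between-group at PRE and at POST
#' (pooled-variance independent t), PRE vs POST within each outcome group
#' (paired t), and the two marginal contrasts (between-group on
#' per-patient means; PRE vs POST paired over all patients). Raw p-values
#' are Bonferroni corrected by the factor 6, capped at 1.
#'
#' @inheritParams mixed_anova
#' @return Tibble with columns `comparison`, `t`, `df`, `p_raw`,
#'   `p_bonferroni`.
#' @export
posthoc_six <- function(data) {
  d <- .complete_prepost(data)
  g <- levels(d$group)
  wide <- tidyr::pivot_wider(d, id_cols = c("patient_id", "group"),
                             names_from = "period", values_from = "value")
  ind_t <- function(x, y) stats::t.test(x, y, var.equal = TRUE)
  pair_t <- function(x, y) stats::t.test(x, y, paired = TRUE)
  rows <- list(
    list(sprintf("%s vs %s at PRE", g[1], g[2]),
         ind_t(wide$PRE[wide$group == g[1]], wide$PRE[wide$group == g[2]])),
    list(sprintf("%s vs %s at POST", g[1], g[2]),
         ind_t(wide$POST[wide$group == g[1]], wide$POST[wide$group == g[2]])),
    list(sprintf("PRE vs POST in %s", g[1]),
         pair_t(wide$PRE[wide$group == g[1]], wide$POST[wide$group == g[1]])),
    list(sprintf("PRE vs POST in %s", g[2]),
         pair_t(wide$PRE[wide$group == g[2]], wide$POST[wide$group == g[2]])),
    list(sprintf("%s vs %s (marginal)", g[1], g[2]),
         ind_t((wide$PRE + wide$POST)[wide$group == g[1]] / 2,
               (wide$PRE + wide$POST)[wide$group == g[2]] / 2)),
    list("PRE vs POST (marginal)", pair_t(wide$PRE, wide$POST))
  )
  out <- dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(comparison = r[[1]],
                   t = unname(r[[2]]$statistic),
                   df = unname(r[[2]]$parameter),
                   p_raw = r[[2]]$p.value)
  }))
  out$p_bonferroni <- pmin(1, 6 * out$p_raw)
  out
}

#' Pooled-variance two-sample t-test from printed summaries
#'
#' Student t-test computed from group means, SDs and sizes only, with
#' pooled variance and `n1 + n2 - 2` degrees of freedom -- the form that
#' reproduces group-comparison statistics printed in clinical summary
#' tables. With zero pooled variance, equal means give t = 0 (p = 1) and
#' unequal means an infinite t (flagged with a warning, p = 0).
#'
#' @param mean1,sd1,n1 Summary of group 1 (`n1 >= 2`, `sd1 >= 0`).
#' @param mean2,sd2,n2 Summary of group 2.
#' @return List with `t`, `df`, `p` (two-sided).
#' @examples
#' pooled_t_from_summary(43.06, 16.15, 15, 46, 23.12, 6)  # |t| = 0.333
#' @export
pooled_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  n1 <- assert_count(n1, "n1", min = 2L)
  n2 <- assert_count(n2, "n2", min = 2L)
  assert_scalar_number(sd1, "sd1", lower = 0)
  assert_scalar_number(sd2, "sd2", lower = 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = df, p = 1))
    warning("zero pooled variance with unequal means: t is infinite")
    return(list(t = sign(mean1 - mean2) * Inf, df = df, p = 0))
  }
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Yates continuity-corrected chi-square for a 2x2 table
#'
#' Continuity-corrected statistic
#' `n * (max(0, |ad - bc| - n/2))^2 / ((a+b)(c+d)(a+c)(b+d))`, with p from
#' the chi-square distribution on 1 df. The correction floors at zero:
#' tables with `|ad - bc| <= n/2` give a statistic of exactly 0.
#'
#' @param a,b Group-1 counts (e.g. finding present / absent).
#' @param c,d Group-2 counts.
#' @return List with `chi2`, `df` (= 1), `p`.
#' @examples
#' chi2_2x2_yates(12, 3, 0, 6)  # chi2 = 8.17
#' @export
chi2_2x2_yates <- function(a, b, c, d) {
  for (v in list(a = a, b = b, c = c, d = d)) assert_count(v, "count")
  tab <- matrix(c(a, c, b, d), nrow = 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_validation("chi-square undefined: a row or column marginal is zero")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter), p = ct$p.value)
}

#' Pearson chi-square for an r x c contingency table
#'
#' Plain Pearson statistic `sum((O - E)^2 / E)` without continuity
#' correction, `df = (r-1)(c-1)`.
#'
#' @param table Matrix of non-negative counts.
#' @return List with `chi2`, `df`, `p`.
#' @examples
#' chi2_rxc(rbind(c(10, 2, 1, 2), c(1, 3, 2, 0)))  # chi2 = 7.40, df = 3
#' @export
chi2_rxc <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop_validation("table must contain non-negative integer counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_validation("chi-square undefined: a row or column marginal is zero")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter), p = ct$p.value)
}

#' Clinical-covariate tests from a tidy summary table
#'
#' Applies, per variable, the test appropriate to its type: a
#' pooled-variance t-test for quantitative variables summarized as
#' n/mean/SD per group, a Yates-corrected 2x2 chi-square for two-level
#' categorical counts, and a plain Pearson r x c chi-square for
#' categorical variables with more levels.
#'
#' @param summary_df Long data frame with columns `variable`, `type`
#'   (`"quantitative"`/`"categorical"`), `group`, `level` (categorical
#'   only), `n`, `mean`, `sd` (quantitative only), `count` (categorical
#'   only). See `system.file("extdata", "clinical_summary.csv",
#'   package = "pupildyn")` for the shipped example.
#' @return Tibble: `variable`, `test`, `statistic`, `df`, `p`.
#' @export
clinical_summary_tests <- function(summary_df) {
  summary_df <- tibble::as_tibble(summary_df)
  out <- lapply(split(summary_df, summary_df$variable), function(v) {
    type <- v$type[1]
    if (type == "quantitative") {
      g <- split(v, v$group)
      if (length(g) != 2L) stop_validation("quantitative variable ", v$variable[1],
                                           " needs exactly 2 groups")
      r <- pooled_t_from_summary(g[[1]]$mean, g[[1]]$sd, g[[1]]$n,
                                 g[[2]]$mean, g[[2]]$sd, g[[2]]$n)
      tibble::tibble(variable = v$variable[1], test = "pooled_t",
                     statistic = r$t, df = r$df, p = r$p)
    } else {
      tab <- tidyr::pivot_wider(v[, c("group", "level", "count")],
                                names_from = "level", values_from = "count")
      m <- as.matrix(tab[, -1])
      if (ncol(m) == 2L) {
        r <- chi2_2x2_yates(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
        tibble::tibble(variable = v$variable[1], test = "chi2_yates",
                       statistic = r$chi2, df = r$df, p = r$p)
      } else {
        r <- chi2_rxc(m)
        tibble::tibble(variable = v$variable[1], test = "chi2_pearson",
                       statistic = r$chi2, df = r$df, p = r$p)
      }
    }
  })
  dplyr::bind_rows(out)
}
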