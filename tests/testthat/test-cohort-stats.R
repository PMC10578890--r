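# Random long-format pre/post dataset builder.
rand_prepost <- function(n_per_group = c(3L, 3L), seed = NULL, integers = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  n <- sum(n_per_group)
  group <- rep(c("A", "B"), n_per_group)
  pre <- if (integers) sample(1:9, n, replace = TRUE) else rnorm(n)
  post <- if (integers) sample(1:9, n, replace = TRUE) else rnorm(n)
  list(
    long = data.frame(
      patient_id = rep(sprintf("P%02d", 1:n), each = 2),
      group = rep(group, each = 2),
      period = rep(c("PRE", "POST"), n),
      value = as.vector(rbind(pre, post))
    ),
    pre = pre, post = post, group = group
  )
}

test_that("mixed ANOVA matches the independent sums-of-squares oracle", {
  # balanced toy set with integer values, then random balanced/unbalanced sets
  cases <- list(rand_prepost(c(3L, 3L), seed = 1, integers = TRUE),
                rand_prepost(c(4L, 4L), seed = 2),
                rand_prepost(c(14L, 6L), seed = 3),
                rand_prepost(c(5L, 9L), seed = 4))
  for (cs in cases) {
    got <- mixed_anova(cs$long)
    want <- oracle_mixed_anova(cs$pre, cs$post, cs$group)
    expect_equal(got$F[got$effect == "group"], want$F_group, tolerance = 1e-10)
    expect_equal(got$F[got$effect == "period"], want$F_period, tolerance = 1e-10)
    expect_equal(got$F[got$effect == "group:period"], want$F_inter,
                 tolerance = 1e-10)
    expect_equal(got$df2, rep(want$df2, 3))
  }
})

test_that("mixed ANOVA is invariant to patient order and constant shifts", {
  cs <- rand_prepost(c(6L, 4L), seed = 10)
  base <- mixed_anova(cs$long)
  shuffled <- cs$long[sample(nrow(cs$long)), ]
  shifted <- cs$long; shifted$value <- shifted$value + 1000
  expect_equal(mixed_anova(shuffled)$F, base$F)
  expect_equal(mixed_anova(shifted)$F, base$F, tolerance = 1e-6)
})

test_that("between-group F equals the squared t on per-patient means", {
  for (s in 1:5) {
    cs <- rand_prepost(c(7L, 5L), seed = 100 + s)
    a <- mixed_anova(cs$long)
    m <- (cs$pre + cs$post) / 2
    t <- stats::t.test(m[cs$group == "A"], m[cs$group == "B"],
                       var.equal = TRUE)$statistic
    expect_equal(a$F[a$effect == "group"], unname(t^2), tolerance = 1e-10)
  }
})

test_that("degenerate inputs are handled explicitly", {
  const <- rand_prepost(c(3L, 3L), seed = 6)$long
  const$value <- 1
  expect_warning(res <- mixed_anova(const), "zero error variance")
  expect_true(all(is.nan(res$F)))
  few <- rand_prepost(c(1L, 3L), seed = 7)$long
  err <- expect_error(mixed_anova(few), class = "pupildyn_validation_error")
  expect_match(conditionMessage(err), "insufficient")
})

test_that("post-hoc set has exactly six Bonferroni-corrected comparisons", {
  cs <- rand_prepost(c(6L, 6L), seed = 20)
  ph <- posthoc_six(cs$long)
  expect_equal(nrow(ph), 6L)
  expect_equal(ph$p_bonferroni, pmin(1, 6 * ph$p_raw))
  expect_true(all(ph$p_bonferroni >= ph$p_raw))
})

test_that("identical groups yield uniformly corrected p-values of one", {
  pre <- c(1, 4); post <- c(2, 3)  # same pairs in both groups
  long <- data.frame(
    patient_id = rep(sprintf("P%02d", 1:4), each = 2),
    group = rep(c("A", "B"), each = 4),
    period = rep(c("PRE", "POST"), 4),
    value = rep(as.vector(rbind(pre, post)), 2)
  )
  ph <- posthoc_six(long)
  expect_true(all(ph$p_bonferroni == 1))
})

test_that("paired post-hoc t matches the textbook closed form", {
  pre <- c(3, 5, 8, 4); post <- c(4, 4, 9, 7)
  long <- data.frame(
    patient_id = rep(sprintf("P%02d", 1:8), each = 2),
    group = rep(c("A", "B"), each = 8),
    period = rep(c("PRE", "POST"), 8),
    value = c(as.vector(rbind(pre, post)), as.vector(rbind(post + 1, pre)))
  )
  ph <- posthoc_six(long)
  d <- pre - post
  t_hand <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  expect_equal(ph$t[ph$comparison == "PRE vs POST in A"], t_hand,
               tolerance = 1e-12)
})

test_that("pooled-variance t reproduces the printed age comparison", {
  # inputs are themselves printed (rounded) summaries, so agreement is to
  # the printed precision, not to exact 3-decimal re-rounding
  r <- pooled_t_from_summary(43.06, 16.15, 15, 46, 23.12, 6)
  expect_equal(abs(r$t), 0.333, tolerance = 0.005)
  expect_equal(r$p, 0.743, tolerance = 0.005)
  expect_equal(r$df, 19)
})

test_that("pooled-variance t handles degenerate summaries", {
  expect_equal(pooled_t_from_summary(5, 2, 10, 5, 3, 8)$t,
               0, tolerance = 1e-12)
  eq <- pooled_t_from_summary(5, 0, 4, 5, 0, 4)
  expect_equal(eq$t, 0); expect_equal(eq$p, 1)
  expect_warning(inf <- pooled_t_from_summary(6, 0, 4, 5, 0, 4),
                 "infinite")
  expect_true(is.infinite(inf$t))
  # closed form on arbitrary summaries
  r <- pooled_t_from_summary(10, 6, 15, 8, 7, 6)
  sp2 <- (14 * 36 + 5 * 49) / 19
  expect_equal(r$t, 2 / sqrt(sp2 * (1 / 15 + 1 / 6)), tolerance = 1e-12)
})

test_that("Yates chi-squares reproduce the printed CT-finding comparisons", {
  expect_equal(round(chi2_2x2_yates(12, 3, 0, 6)$chi2, 2), 8.17)  # tSAH
  expect_equal(round(chi2_2x2_yates(12, 3, 0, 6)$p, 3), 0.004)
  expect_equal(round(chi2_2x2_yates(5, 10, 0, 6)$chi2, 2), 1.11)  # EDH
  expect_equal(round(chi2_2x2_yates(0, 15, 1, 5)$chi2, 2), 0.24)  # IVH
  expect_equal(round(chi2_2x2_yates(3, 12, 3, 3)$chi2, 2), 0.71)  # neurosurgery
  expect_equal(round(chi2_2x2_yates(10, 5, 5, 1)$chi2, 2), 0.05)  # inv. monitoring
})

test_that("continuity correction floors at zero and never exceeds plain Pearson", {
  r <- chi2_2x2_yates(5, 5, 6, 5)  # |ad - bc| = 5 <= n/2
  expect_equal(r$chi2, 0); expect_equal(r$p, 1)
  set.seed(42)
  for (i in 1:20) {
    tab <- matrix(sample(1:12, 4, replace = TRUE), 2)
    yates <- chi2_2x2_yates(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])$chi2
    plain <- chi2_rxc(tab)$chi2
    expect_lte(yates, plain + 1e-12)
  }
})

test_that("Pearson r x c reproduces the printed Marshall comparison and identities", {
  m <- rbind(c(10, 2, 1, 2), c(1, 3, 2, 0))
  r <- chi2_rxc(m)
  expect_equal(round(r$chi2, 2), 7.40)
  expect_equal(r$df, 3)
  expect_equal(round(r$p, 2), 0.06)
  # independence: table proportional to its marginals
  ind <- outer(c(10, 20), c(1, 2, 3)) / 10
  expect_equal(chi2_rxc(ind * 10)$chi2, 0, tolerance = 1e-12)
  # 2x2 algebraic identity without correction
  set.seed(9)
  for (i in 1:10) {
    a <- sample(1:9, 4, replace = TRUE)
    tab <- matrix(a, 2)
    n <- sum(a)
    hand <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
      (prod(rowSums(tab)) * prod(colSums(tab)))
    expect_equal(chi2_rxc(tab)$chi2, hand, tolerance = 1e-10)
  }
  expect_error(chi2_rxc(rbind(c(0, 0), c(1, 2))),
               class = "pupildyn_validation_error")
})

test_that("the shipped clinical summary reproduces every printed statistic it can", {
  path <- system.file("extdata", "clinical_summary.csv", package = "pupildyn")
  df <- readr::read_csv(path, show_col_types = FALSE)
  res <- clinical_summary_tests(df)
  get <- function(v, col) res[[col]][res$variable == v]
  expect_equal(abs(get("age", "statistic")), 0.333, tolerance = 0.005)
  expect_equal(round(get("tsah", "statistic"), 2), 8.17)
  expect_equal(round(get("edh", "statistic"), 2), 1.11)
  expect_equal(round(get("ivh", "statistic"), 2), 0.24)
  expect_equal(round(get("neurosurgery", "statistic"), 2), 0.71)
  expect_equal(round(get("inm", "statistic"), 2), 0.05)
  expect_equal(round(get("marshall", "statistic"), 2), 7.40)
  expect_equal(get("marshall", "df"), 3)
})
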