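test_that("point-biserial matches the two-group closed form and conventions", {
  # perfectly group-ordered values with two distinct levels
  y <- c(rep(1, 6), rep(0, 4))
  x <- c(rep(2, 6), rep(1, 4))
  r <- point_biserial(x, y)$r
  n <- length(y); n1 <- 6; n0 <- 4
  closed <- (mean(x[y == 1]) - mean(x[y == 0])) / stats::sd(x) *
    sqrt(n1 * n0 / (n * (n - 1)))
  expect_equal(abs(r), abs(closed), tolerance = 1e-12)
  # outcome-independent values: r = 0
  expect_equal(point_biserial(c(1, 2, 3, 1, 2, 3), c(0, 0, 0, 1, 1, 1))$r, 0)
  # sign convention: higher occupancy in the favorable (=1) group gives r > 0
  set.seed(2)
  iso <- c(rnorm(10, 0.9, 0.03), rnorm(5, 0.5, 0.05))
  out <- c(rep(1, 10), rep(0, 5))
  expect_gt(point_biserial(iso, out)$r, 0)
  expect_lt(point_biserial(-iso, out)$r, 0)  # jump-rate-like reversal
})

test_that("point-biserial is invariant to positive affine transforms", {
  set.seed(7)
  x <- rnorm(20); y <- rbinom(20, 1, 0.6)
  base <- point_biserial(x, y)
  expect_equal(point_biserial(3 * x + 5, y)$r, base$r, tolerance = 1e-12)
  expect_equal(point_biserial(-2 * x, y)$r, -base$r, tolerance = 1e-12)
  expect_error(point_biserial(rep(1, 10), rbinom(10, 1, 0.5)),
               class = "pupildyn_validation_error")
})

test_that("intercept-only log-likelihood matches the closed form", {
  y <- c(rep(1, 14), rep(0, 6))
  fit <- fit_logistic(matrix(numeric(0), 20, 0), y)
  expect_equal(fit$logLik, 14 * log(0.7) + 6 * log(0.3), tolerance = 1e-8)
  expect_false(fit$separation)
})

test_that("perfect separation is flagged and Firth prediction still classifies", {
  y <- c(rep(1, 10), rep(0, 10))
  fit <- fit_logistic(matrix(y, ncol = 1), y)
  expect_true(fit$separation)
  expect_false(is.null(fit$firth))
  sc <- score_model(matrix(y, ncol = 1), y, "self")
  expect_true(sc$separation_flag)
  expect_equal(sc$loocv_accuracy, 1.0)
})

test_that("logistic coefficients recover generating betas within three SE", {
  set.seed(123)
  n <- 50
  x <- rnorm(n)
  beta <- c(-0.5, 1.5)
  y <- rbinom(n, 1, stats::plogis(beta[1] + beta[2] * x))
  fit <- fit_logistic(matrix(x, ncol = 1), y)
  # observed-information SEs at the MLE
  Xd <- cbind(1, x)
  mu <- stats::plogis(drop(Xd %*% fit$coefficients))
  se <- sqrt(diag(solve(crossprod(Xd, Xd * (mu * (1 - mu))))))
  expect_true(all(abs(fit$coefficients - beta) < 3 * se))
})

test_that("intercept-only BIC and LOOCV accuracy take their forced values", {
  y <- c(rep(1, 14), rep(0, 6))
  sc <- score_model(matrix(numeric(0), 20, 0), y, "intercept")
  expect_equal(sc$bic, log(20) - 2 * (14 * log(0.7) + 6 * log(0.3)),
               tolerance = 1e-8)
  expect_equal(sc$loocv_accuracy, 0.70)
  expect_true(is.na(sc$lr_pvalue))
})

test_that("the LR test keeps roughly nominal size on a useless predictor", {
  set.seed(314)
  rejections <- vapply(1:400, function(i) {
    y <- c(rep(1, 14), rep(0, 6))
    x <- rnorm(20)
    fit <- fit_logistic(matrix(x, ncol = 1), y)
    lr <- max(0, fit$null_deviance - fit$deviance)
    stats::pchisq(lr, 1, lower.tail = FALSE) < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.12)
})

test_that("the sweep covers all fifteen subsets per day and nests deviances", {
  co <- generate_cohort(fast_config(seed = 21))
  sweep <- suppressMessages(model_selection_sweep(co, nd_range = 0:3))
  nd_kept <- setdiff(0:3, attr(sweep, "skipped"))
  expect_equal(nrow(sweep), 15L * length(nd_kept))
  expect_equal(sort(unique(sweep$subset)), sort(names(pupildyn:::predictor_subsets())))
  # in-sample deviance never increases when predictors are added
  tc <- index_timecourse(co, "cumulative_days", nd_max = 3)
  d <- tc[tc$nd == 2, ]
  d <- d[stats::complete.cases(d[, index_names()]), ]
  y <- as.integer(d$outcome == "FAVORABLE")
  X <- as.matrix(d[, index_names()])
  subs <- pupildyn:::predictor_subsets()
  dev <- vapply(subs, function(s) fit_logistic(X[, s, drop = FALSE], y)$deviance,
                numeric(1))
  full <- dev[[paste(index_names(), collapse = "+")]]
  for (lab in names(subs)) {
    expect_lte(full, dev[[lab]] + 1e-6)
    for (lab2 in names(subs)) {
      if (all(subs[[lab]] %in% subs[[lab2]])) {
        expect_lte(dev[[lab2]], dev[[lab]] + 1e-6)
      }
    }
  }
})

test_that("best-model selection breaks ties by subset size then label", {
  sweep <- tibble::tibble(
    nd = 0L,
    subset = c("b", "a", "a+b"),
    n_predictors = c(1L, 1L, 2L),
    n = 20L,
    lr_pvalue = c(0.01, 0.01, 0.01),
    bic = c(10, 10 + 0.005, 9.9999),  # all within the 0.01 BIC tolerance
    loocv_accuracy = c(0.9, 0.9, 0.9),
    separation_flag = FALSE
  )
  best <- best_models(sweep)
  expect_equal(best$subset[best$criterion == "bic"], "a")
  expect_equal(best$subset[best$criterion == "lr_pvalue"], "a")
  expect_equal(best$subset[best$criterion == "loocv_accuracy"], "a")
})

test_that("AUC equals the exhaustive pairwise oracle, including ties", {
  expect_equal(roc_auc(rep(1, 10), c(rep(1, 5), rep(0, 5)),
                       use_model = FALSE)$auc, 0.5)
  expect_equal(roc_auc(c(rep(2, 5), rep(1, 5)), c(rep(1, 5), rep(0, 5)),
                       use_model = FALSE)$auc, 1.0)
  set.seed(55)
  for (i in 1:30) {
    y <- c(rep(1, 14), rep(0, 6))[sample(20)]
    score <- if (i %% 2) rnorm(20) else sample(1:4, 20, replace = TRUE) / 4
    got <- roc_auc(score, y, use_model = FALSE)$auc
    expect_equal(got, oracle_auc_pairwise(score, y), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(77)
  y <- rbinom(25, 1, 0.5); y[1:2] <- c(0, 1)
  x <- rnorm(25)
  base <- roc_auc(x, y, use_model = FALSE)$auc
  expect_equal(roc_auc(exp(x), y, use_model = FALSE)$auc, base)
  expect_equal(roc_auc(stats::qlogis(stats::plogis(x)), y,
                       use_model = FALSE)$auc, base, tolerance = 1e-9)
  # model-based in-sample scoring gives the same ranking for one predictor
  expect_equal(roc_auc(x, y)$auc, base, tolerance = 1e-9)
})

test_that("between-group signal exceeds its permutation distribution", {
  co <- generate_cohort(cohort_config(seed = 17))
  pp <- pre_post_indices(co)
  d <- data.frame(patient_id = pp$patient_id, group = pp$outcome,
                  period = pp$period, value = pp$ps_isochoria_pct)
  real <- mixed_anova(d)$F[1]
  set.seed(18)
  ids <- unique(d$patient_id)
  perm_F <- vapply(1:200, function(i) {
    relab <- setNames(sample(d$group[match(ids, d$patient_id)]), ids)
    dp <- d; dp$group <- relab[dp$patient_id]
    tryCatch(mixed_anova(dp)$F[1], error = function(e) NA_real_)
  }, numeric(1))
  expect_gt(real, stats::quantile(perm_F, 0.95, na.rm = TRUE))
})
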