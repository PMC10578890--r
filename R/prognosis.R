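# Day-by-day outcome prognosis: point-biserial screening, exhaustive
# logistic model selection scored by LR p-value / BIC / LOOCV accuracy,
# and ROC/AUC. Outcome coding throughout: FAVORABLE = 1, UNFAVORABLE = 0,
# so higher occupancy percentages correlate positively with outcome and
# jump rates negatively.

#' Point-biserial correlation with a binary outcome
#'
#' Pearson correlation between a continuous index and the 0/1 outcome
#' coding; the two-sided p-value comes from the t transform with n - 2
#' degrees of freedom.
#'
#' @param x Numeric index values.
#' @param y Binary outcome vector (0 = unfavorable, 1 = favorable).
#' @return List with `r`, `p`, `n`.
#' @export
point_biserial <- function(x, y) {
  if (length(x) != length(y)) stop_validation("x and y lengths differ")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- as.numeric(y[keep])
  if (length(x) < 3L) stop_validation("need at least 3 complete pairs")
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L) {
    stop_validation("y must contain both outcome classes coded 0/1")
  }
  if (stats::sd(x) == 0) {
    stop_validation("point-biserial undefined: index has zero variance")
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

# Firth-penalized logistic regression (Newton iterations on the modified
# score U*_r = sum_i (y_i - p_i + h_i (1/2 - p_i)) x_ir, h the leverages
# of the weighted design). Used for prediction when the MLE separates.
firth_fit <- function(X, y, maxit = 100L, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  penll <- function(beta) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    info <- crossprod(X, X * (mu * (1 - mu)))
    sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(info)$modulus[1]
  }
  ll_old <- penll(beta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    XW <- X * W
    info <- crossprod(X, XW)
    ch <- tryCatch(chol(info), error = function(e) NULL)
    if (is.null(ch)) break
    inv <- chol2inv(ch)
    h <- rowSums((X %*% inv) * XW)
    score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    delta <- drop(inv %*% score)
    # damp long steps, then halve until the penalized likelihood improves
    if (max(abs(delta)) > 5) delta <- delta * 5 / max(abs(delta))
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- penll(cand)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      step <- step / 2
      if (step < 1e-6) break
    }
    beta <- beta + step * delta
    ll_old <- penll(beta)
  }
  list(coefficients = beta, loglik_penalized = ll_old, converged = converged)
}

#' Fit a logistic outcome model with separation handling
#'
#' Maximum-likelihood logistic regression of the binary outcome on the
#' given index columns (intercept always included). Complete or
#' quasi-complete separation -- diverging coefficients, non-convergence,
#' or fitted probabilities pinned to 0/1 -- is detected and flagged; in
#' that case a Firth-penalized refit is stored and used for prediction,
#' while the (degenerate) MLE log-likelihood is retained for reporting.
#'
#' @param x Numeric matrix or data frame of predictors (may have zero
#'   columns for the intercept-only model).
#' @param y Binary outcome vector containing both classes.
#' @return Object of class `pupil_logit`: coefficients, `logLik`,
#'   `deviance`, `null_deviance`, `converged`, `separation`, and the
#'   Firth refit (or NULL).
#' @export
fit_logistic <- function(x, y) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) x <- matrix(numeric(0), nrow = length(y), ncol = 0)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_validation("y must be coded 0/1")
  if (length(unique(y)) < 2L) {
    stop_validation("outcome has a single class: logistic model undefined")
  }
  if (anyNA(x)) stop_validation("predictor matrix contains missing values")
  Xd <- cbind("(Intercept)" = 1, x)
  fit <- suppressWarnings(
    stats::glm.fit(Xd, y, family = stats::binomial(),
                   control = stats::glm.control(maxit = 100))
  )
  null <- suppressWarnings(
    stats::glm.fit(matrix(1, length(y)), y, family = stats::binomial())
  )
  mu <- fit$fitted.values
  separation <- !fit$converged || any(abs(fit$coefficients) > 15) ||
    any(mu > 1 - 1e-8 | mu < 1e-8)
  firth <- if (separation) firth_fit(Xd, y) else NULL
  structure(list(
    coefficients = fit$coefficients,
    logLik = -fit$deviance / 2,
    deviance = fit$deviance,
    null_deviance = null$deviance,
    converged = fit$converged,
    separation = separation,
    firth = firth,
    n = length(y),
    k = ncol(Xd)
  ), class = "pupil_logit")
}

#' @export
print.pupil_logit <- function(x, ...) {
  cat("<pupil_logit> n =", x$n, " predictors =", x$k - 1,
      " logLik =", format(x$logLik, digits = 4),
      if (x$separation) " [separation: Firth refit used for prediction]",
      "\n")
  invisible(x)
}

#' Predicted outcome probabilities
#'
#' @param object A `pupil_logit` fit.
#' @param newdata Predictor matrix with the columns the model was fit on.
#' @param ... Unused.
#' @return Vector of probabilities of the favorable (coded 1) outcome.
#'   Uses the Firth-penalized coefficients when the MLE separated.
#' @export
predict.pupil_logit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) return(numeric(0))
  Xd <- cbind(1, newdata)
  beta <- if (object$separation) object$firth$coefficients
          else object$coefficients
  drop(stats::plogis(Xd %*% beta))
}

#' Score one predictor subset: LR p-value, BIC, LOOCV accuracy
#'
#' The model's significance is the likelihood-ratio test against the
#' intercept-only model (chi-square with df = number of predictors);
#' `bic = k ln(n) - 2 lnL` with `k` = predictors + 1; the accuracy is the
#' fraction of held-out patients whose leave-one-out predicted probability
#' falls on the correct side of 0.5. A LOOCV fold whose training set
#' collapses to a single class is predicted by the training majority.
#'
#' @param x Predictor matrix (0 columns allowed: intercept-only model).
#' @param y Binary outcome vector.
#' @param label Optional subset label carried into the result.
#' @return Tibble row: `subset`, `n_predictors`, `n`, `lr_pvalue`, `bic`,
#'   `loocv_accuracy`, `separation_flag`. `lr_pvalue` is `NA` for the
#'   intercept-only model.
#' @export
score_model <- function(x, y, label = NULL) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) x <- matrix(numeric(0), nrow = length(y), ncol = 0)
  p <- ncol(x)
  fit <- fit_logistic(x, y)
  lr <- max(0, fit$null_deviance - fit$deviance)
  lr_p <- if (p == 0L) NA_real_ else stats::pchisq(lr, df = p, lower.tail = FALSE)
  bic <- (p + 1) * log(fit$n) - 2 * fit$logLik

  n <- length(y)
  correct <- logical(n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      maj <- if (mean(ytr) >= 0.5) 1 else 0
      message("LOOCV fold ", i, ": single-class training set, ",
              "predicting training majority")
      correct[i] <- maj == y[i]
      next
    }
    f <- fit_logistic(x[-i, , drop = FALSE], ytr)
    pr <- predict(f, x[i, , drop = FALSE])
    correct[i] <- (pr > 0.5) == (y[i] == 1)
  }
  tibble::tibble(
    subset = if (is.null(label)) paste(colnames(x), collapse = "+") else label,
    n_predictors = p, n = n,
    lr_pvalue = lr_p, bic = bic,
    loocv_accuracy = mean(correct),
    separation_flag = fit$separation
  )
}

# All 15 non-empty subsets of the four indices, labelled by "+"-joined
# names in the fixed index order.
predictor_subsets <- function() {
  nm <- index_names()
  subs <- unlist(lapply(1:4, function(k) {
    combn(nm, k, simplify = FALSE)
  }), recursive = FALSE)
  stats::setNames(subs, vapply(subs, paste, "", collapse = "+"))
}

#' Exhaustive day-by-day model selection sweep
#'
#' For each number of days ND in `nd_range`, evaluates the four indices
#' cumulatively on `[0, 24 (ND + 1))`, then scores every one of the
#' 2^4 - 1 = 15 predictor subsets with [score_model()]. Patients lacking
#' complete index values in a window (e.g. discharged before it) are
#' dropped from that ND and reported in the `n` column; an ND with fewer
#' than 3 patients in either outcome class is skipped with a message.
#'
#' @param cohort A [pupil_cohort()].
#' @param nd_range Integer vector of NDs (default 0:10).
#' @param denominator Passed to the index computation.
#' @return Tibble: `nd`, `subset`, `n_predictors`, `n`, `lr_pvalue`,
#'   `bic`, `loocv_accuracy`, `separation_flag`; skipped NDs recorded in
#'   attribute `"skipped"`.
#' @export
model_selection_sweep <- function(cohort, nd_range = 0:10,
                                  denominator = c("measurements", "transitions")) {
  stopifnot(inherits(cohort, "pupil_cohort"))
  denominator <- match.arg(denominator)
  tc <- index_timecourse(cohort, "cumulative_days", nd_max = max(nd_range),
                         denominator = denominator)
  subs <- predictor_subsets()
  skipped <- integer(0)
  rows <- list()
  for (nd in sort(unique(as.integer(nd_range)))) {
    d <- tc[tc$nd == nd, ]
    d <- d[stats::complete.cases(d[, index_names()]), ]
    y <- outcome_binary(d$outcome)
    if (sum(y == 1) < 3L || sum(y == 0) < 3L) {
      message("ND ", nd, " skipped: fewer than 3 patients per class (",
              sum(y == 1), " favorable / ", sum(y == 0), " unfavorable)")
      skipped <- c(skipped, nd)
      next
    }
    X <- as.matrix(d[, index_names()])
    for (lab in names(subs)) {
      sc <- score_model(X[, subs[[lab]], drop = FALSE], y, label = lab)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(tibble::tibble(nd = nd), sc)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}

#' Best model per day under each selection criterion
#'
#' Reports, per ND, the winning subset under each criterion separately:
#' smallest LR p-value, smallest BIC, largest LOOCV accuracy. Values
#' within a numeric tolerance of the optimum (BIC 0.01; p-value and
#' accuracy 1e-9) are treated as tied -- under complete separation every
#' separating model's MLE deviance is numerically ~0, so exact float
#' comparison would rank noise -- and ties are broken by smaller subset
#' size, then lexicographic subset label.
#'
#' @param sweep Output of [model_selection_sweep()].
#' @return Tibble: `nd`, `criterion`, `subset`, `value`.
#' @export
best_models <- function(sweep) {
  pick <- function(d, col, minimize, tol) {
    v <- d[[col]]
    if (all(is.na(v))) return(NULL)
    opt <- if (minimize) min(v, na.rm = TRUE) else max(v, na.rm = TRUE)
    tied <- !is.na(v) & (if (minimize) v <= opt + tol else v >= opt - tol)
    cand <- d[tied, ]
    cand <- cand[order(cand$n_predictors, cand$subset), ]
    tibble::tibble(nd = cand$nd[1], criterion = col,
                   subset = cand$subset[1], value = cand[[col]][1])
  }
  out <- lapply(split(sweep, sweep$nd), function(d) {
    dplyr::bind_rows(
      pick(d, "lr_pvalue", minimize = TRUE, tol = 1e-9),
      pick(d, "bic", minimize = TRUE, tol = 0.01),
      pick(d, "loocv_accuracy", minimize = FALSE, tol = 1e-9)
    )
  })
  dplyr::bind_rows(out)
}

#' Point-biserial screening of all indices across days
#'
#' Correlates each of the four cumulative indices with the outcome for
#' every ND, marking two-sided p < 0.05 (uncorrected) as significant.
#'
#' @inheritParams model_selection_sweep
#' @return Tibble: `nd`, `index`, `r`, `p`, `significant`, `n`.
#' @export
correlation_sweep <- function(cohort, nd_range = 0:10,
                              denominator = c("measurements", "transitions")) {
  denominator <- match.arg(denominator)
  tc <- index_timecourse(cohort, "cumulative_days", nd_max = max(nd_range),
                         denominator = denominator)
  rows <- list()
  for (nd in sort(unique(as.integer(nd_range)))) {
    d <- tc[tc$nd == nd, ]
    d <- d[stats::complete.cases(d[, index_names()]), ]
    y <- outcome_binary(d$outcome)
    if (length(unique(y)) < 2L || length(y) < 3L) next
    for (ix in index_names()) {
      pb <- tryCatch(point_biserial(d[[ix]], y), error = function(e) NULL)
      if (is.null(pb)) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        nd = nd, index = ix, r = pb$r, p = pb$p,
        significant = pb$p < 0.05, n = pb$n)
    }
  }
  dplyr::bind_rows(rows)
}

#' ROC curve and AUC for a single-predictor model
#'
#' Fits the logistic model on one index (Firth-refit under separation),
#' then computes the ROC of its predicted probabilities against the
#' outcome, with AUC by the trapezoidal rule -- equal to the Mann-Whitney
#' U statistic over `n1 * n0` pairs with ties counting one half. Because
#' AUC is invariant under strictly increasing transforms, scoring by the
#' fitted probabilities is equivalent to scoring by the raw index (up to
#' the sign of the fitted slope). `mode = "loocv"` scores each patient by
#' their leave-one-out held-out probability instead of the in-sample fit;
#' `use_model = FALSE` ranks the raw scores directly.
#'
#' @param x Numeric vector: one index evaluated per patient.
#' @param y Binary outcome vector (both classes present).
#' @param mode `"insample"` (default) or `"loocv"`.
#' @param use_model Fit the logistic model first (default) or rank raw x.
#' @return Object of class `pupil_roc`: `auc`, `thresholds`,
#'   `sensitivity`, `specificity`, `n_cases`, `n_controls`, `mode`.
#' @export
roc_auc <- function(x, y, mode = c("insample", "loocv"), use_model = TRUE) {
  mode <- match.arg(mode)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) {
    stop_validation("both outcome classes required for ROC")
  }
  if (!use_model) {
    score <- x
  } else if (mode == "insample") {
    fit <- fit_logistic(matrix(x, ncol = 1), y)
    score <- predict(fit, matrix(x, ncol = 1))
  } else {
    score <- vapply(seq_along(y), function(i) {
      ytr <- y[-i]
      if (length(unique(ytr)) < 2L) return(mean(ytr))
      f <- fit_logistic(matrix(x[-i], ncol = 1), ytr)
      predict(f, matrix(x[i], ncol = 1))
    }, numeric(1))
  }
  r <- pROC::roc(response = y, predictor = score, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  structure(list(
    auc = as.numeric(pROC::auc(r)),
    thresholds = r$thresholds,
    sensitivity = r$sensitivities,
    specificity = r$specificities,
    n_cases = sum(y == 1), n_controls = sum(y == 0),
    mode = if (use_model) mode else "raw"
  ), class = "pupil_roc")
}

#' @export
print.pupil_roc <- function(x, ...) {
  cat("<pupil_roc> AUC =", format(x$auc, digits = 4),
      " (", x$n_cases, "cases /", x$n_controls, "controls,",
      x$mode, "scores )\n")
  invisible(x)
}

#' ROC/AUC of one index across days
#'
#' @param cohort A [pupil_cohort()].
#' @param predictor One of [index_names()] (default the pupil-size
#'   isochoria percentage).
#' @param nd_range Integer NDs to evaluate.
#' @param mode,denominator Passed through to [roc_auc()] / indices.
#' @return Tibble: `nd`, `predictor`, `auc`, `n`; ROC objects in
#'   attribute `"curves"` (named by ND).
#' @export
roc_sweep <- function(cohort, predictor = "ps_isochoria_pct",
                      nd_range = 0:10, mode = c("insample", "loocv"),
                      denominator = c("measurements", "transitions")) {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  predictor <- match.arg(predictor, index_names())
  tc <- index_timecourse(cohort, "cumulative_days", nd_max = max(nd_range),
                         denominator = denominator)
  rows <- list(); curves <- list()
  for (nd in sort(unique(as.integer(nd_range)))) {
    d <- tc[tc$nd == nd & !is.na(tc[[predictor]]), ]
    y <- outcome_binary(d$outcome)
    if (length(unique(y)) < 2L) next
    rc <- roc_auc(d[[predictor]], y, mode = mode)
    curves[[as.character(nd)]] <- rc
    rows[[length(rows) + 1L]] <- tibble::tibble(
      nd = nd, predictor = predictor, auc = rc$auc, n = length(y))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "curves") <- curves
  out
}
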