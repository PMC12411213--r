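## Evaluation statistics, implemented from first principles: logistic
## regression by IRLS with Wald intervals, stratified 80:20 splitting, AUROC
## as the Mann-Whitney statistic, the DeLong paired AUROC comparison via
## placement values, Fisher's exact test by hypergeometric enumeration, and
## the Wilcoxon rank-sum test (exact by enumeration at small n, otherwise
## normal approximation with tie and continuity corrections).

## ---- logistic regression (IRLS) ----

drop_missing <- function(data, cols) {
  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  if (!all(keep)) {
    message(sprintf("dropping %d rows with missing values", sum(!keep)))
  }
  data[keep, , drop = FALSE]
}

#' Logistic regression via iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with Wald standard errors, odds ratios
#' `exp(coef)` and 95% Wald intervals `exp(coef +/- 1.96 se)`. Iteration is
#' capped at `max_iter`; non-convergence (including separation, where
#' coefficients diverge) is reported through the `converged` flag rather
#' than an error. Rows with missing values in modeled columns are dropped
#' with a message.
#'
#' @param data a data frame / tibble.
#' @param outcome_col name of the 0/1 outcome column.
#' @param predictor_cols character vector of predictor column names.
#' @param max_iter IRLS iteration cap.
#' @param tol convergence tolerance on the deviance change.
#' @return An object of class `logistic_fit`.
#' @export
fit_logistic <- function(data, outcome_col, predictor_cols,
                         max_iter = 100L, tol = 1e-10) {
  data <- drop_missing(tibble::as_tibble(data),
                       c(outcome_col, predictor_cols))
  n <- nrow(data)
  if (n < 10) {
    rlang::abort("need at least 10 complete rows to fit",
                 class = "nwuct_parameter_error")
  }
  y <- data[[outcome_col]]
  if (!all(y %in% c(0, 1))) {
    rlang::abort(sprintf("outcome column '%s' must be 0/1", outcome_col),
                 class = "nwuct_parameter_error")
  }
  if (length(unique(y)) < 2) {
    rlang::abort("outcome is constant; model is degenerate",
                 class = "nwuct_degenerate_outcome_error")
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, predictor_cols, drop = FALSE]))
  const <- apply(X[, -1, drop = FALSE], 2, function(v) length(unique(v)) == 1)
  if (any(const)) {
    rlang::abort(sprintf("constant predictor column(s): %s",
                         paste(predictor_cols[const], collapse = ", ")),
                 class = "nwuct_parameter_error")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    rlang::abort(sprintf("rank-deficient design; collinear column(s): %s",
                         paste(bad, collapse = ", ")),
                 class = "nwuct_collinearity_error")
  }
  beta <- rep(0, ncol(X))
  dev_trace <- numeric(0)
  dev_old <- Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    fit <- qr.solve(X * sw, z * sw)
    beta <- fit
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    dev <- -2 * sum(y * log(pmax(mu, 1e-300)) +
                      (1 - y) * log(pmax(1 - mu, 1e-300)))
    dev_trace <- c(dev_trace, dev)
    if (is.finite(dev_old) && abs(dev_old - dev) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    dev_old <- dev
  }
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(X * sqrt(w))
  se <- sqrt(diag(solve(info)))
  names(beta) <- names(se) <- colnames(X)
  structure(list(
    coefficients = beta, standard_errors = se,
    odds_ratios = exp(beta),
    ci95 = cbind(low = exp(beta - 1.96 * se), high = exp(beta + 1.96 * se)),
    p_values = 2 * stats::pnorm(-abs(beta / se)),
    converged = converged, iterations = iter,
    n_used = n, deviance = dev, deviance_trace = dev_trace,
    log_likelihood = -dev / 2,
    outcome_col = outcome_col, predictor_cols = predictor_cols
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, deviance = %.3f, converged: %s\n",
              x$n_used, x$deviance, x$converged))
  print(tidy.logistic_fit(x))
  invisible(x)
}

#' Tidy a logistic fit
#' @param x a `logistic_fit`.
#' @param ... unused.
#' @return Tibble with term, estimate, std.error, p.value, odds.ratio and
#'   95% Wald interval.
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$standard_errors),
                 p.value = unname(x$p_values),
                 odds.ratio = unname(x$odds_ratios),
                 conf.low = unname(x$ci95[, "low"]),
                 conf.high = unname(x$ci95[, "high"]))
}

#' @param x a `logistic_fit`.
#' @param ... unused.
#' @rdname tidy.logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(n = x$n_used, deviance = x$deviance,
                 logLik = x$log_likelihood, iterations = x$iterations,
                 converged = x$converged)
}

#' Predict outcome probabilities from a logistic fit
#' @param object a `logistic_fit`.
#' @param newdata data frame with the predictor columns.
#' @param ... unused.
#' @return Numeric vector of fitted probabilities.
#' @export
predict.logistic_fit <- function(object, newdata, ...) {
  X <- cbind(1, as.matrix(newdata[, object$predictor_cols, drop = FALSE]))
  stats::plogis(drop(X %*% object$coefficients))
}

## ---- stratified split ----

#' Stratified train/test split
#'
#' Splits rows into train and test sets preserving the outcome-class mix:
#' each class contributes `round(class_n * test_fraction)` rows to the test
#' set, with an exact-half rounded up in the larger class and down in the
#' others. Disjoint, exhaustive, and reproducible from the seed.
#'
#' @param data a data frame / tibble.
#' @param outcome_col name of the binary class column.
#' @param test_fraction fraction of each class assigned to the test set.
#' @param seed integer seed.
#' @return List with `train` and `test` tibbles.
#' @export
stratified_split <- function(data, outcome_col = "outcome",
                             test_fraction = 0.2, seed = 1L) {
  data <- tibble::as_tibble(data)
  if (test_fraction <= 0 || test_fraction >= 1) {
    rlang::abort("test_fraction must be in (0, 1)",
                 class = "nwuct_parameter_error")
  }
  cls <- data[[outcome_col]]
  levs <- sort(unique(cls))
  sizes <- vapply(levs, function(l) sum(cls == l), 0L)
  larger <- levs[which.max(sizes)]
  n_test <- vapply(seq_along(levs), function(i) {
    x <- sizes[i] * test_fraction
    if (abs(x - floor(x) - 0.5) < 1e-9) {
      if (levs[i] == larger) ceiling(x) else floor(x)
    } else round(x)
  }, 0)
  test_idx <- with_seed(seed, {
    unlist(lapply(seq_along(levs), function(i) {
      rows <- which(cls == levs[i])
      sample(rows, n_test[i])
    }))
  })
  list(train = data[-test_idx, , drop = FALSE],
       test = data[sort(test_idx), , drop = FALSE])
}

## ---- AUROC ----

check_labels <- function(labels) {
  if (!all(labels %in% c(0, 1))) {
    rlang::abort("labels must be 0/1", class = "nwuct_parameter_error")
  }
  if (length(unique(labels)) < 2) {
    rlang::abort("labels contain a single class; AUROC undefined",
                 class = "nwuct_degenerate_label_error")
  }
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' positive scores above a random negative, counting ties as one half, over
#' all positive-negative pairs (midrank formula).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 outcome labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  check_labels(labels)
  pos <- labels == 1
  r <- rank(scores)
  m <- sum(pos)
  n <- sum(!pos)
  (sum(r[pos]) - m * (m + 1) / 2) / (m * n)
}

## placement values (structural components): V10 per positive, V01 per
## negative, computed with midranks
placements <- function(scores, labels) {
  pos <- labels == 1
  r_all <- rank(scores)
  r_pos <- rank(scores[pos])
  r_neg <- rank(scores[!pos])
  m <- sum(pos)
  n <- sum(!pos)
  v10 <- (r_all[pos] - r_pos) / n
  v01 <- 1 - (r_all[!pos] - r_neg) / m
  list(v10 = v10, v01 = v01, auc = (sum(r_all[pos]) - m * (m + 1) / 2) / (m * n))
}

#' DeLong test for two correlated AUROCs
#'
#' Both score vectors must be computed on the same subjects (paired). The
#' variance of each AUROC and their covariance are estimated from the
#' empirical covariance of the placement values; the statistic is
#' `z = (auc_a - auc_b) / sqrt(var_a + var_b - 2 cov_ab)` referred to the
#' standard normal. When the variance of the difference is zero and the
#' AUROCs are equal, `z = 0, p = 1`.
#'
#' @param scores_a,scores_b paired score vectors from the two models.
#' @param labels 0/1 outcome labels.
#' @return List: `auc_a`, `auc_b`, `z`, `p`, `var_a`, `var_b`, `cov_ab`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    rlang::abort("scores_a, scores_b and labels must be paired (equal length)",
                 class = "nwuct_pairing_error")
  }
  check_labels(labels)
  pa <- placements(scores_a, labels)
  pb <- placements(scores_b, labels)
  m <- length(pa$v10)
  n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- pa$auc - pb$auc
  if (var_diff <= 0) {
    if (abs(d) < 1e-12) {
      z <- 0
    } else {
      z <- sign(d) * Inf
    }
  } else {
    z <- d / sqrt(var_diff)
  }
  p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z))
  if (z == 0) p <- 1
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = p,
       var_a = S[1, 1], var_b = S[2, 2], cov_ab = S[1, 2])
}

## ---- Fisher exact (2x2) ----

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-ordering convention: the sum of
#' hypergeometric probabilities of all tables with the same margins whose
#' probability does not exceed that of the observed table (within a small
#' relative tolerance). The reported odds ratio is the sample odds ratio
#' `ad/bc`, with a Haldane 0.5 correction applied to every cell when a zero
#' cell occurs.
#'
#' @param table 2x2 matrix of counts `rbind(c(a, b), c(c, d))`.
#' @return List with `odds_ratio` and `p`.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    rlang::abort("need a 2x2 table of non-negative counts",
                 class = "nwuct_parameter_error")
  }
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  m1 <- a + b          # row 1 total
  m2 <- cc + d         # row 2 total
  k <- a + cc          # column 1 total
  support <- max(0, k - m2):min(k, m1)
  probs <- stats::dhyper(support, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(p, 1)
  if (any(tab == 0)) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  list(odds_ratio = (a * d) / (b * cc), p = p)
}

## ---- Wilcoxon rank sum ----

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' The statistic is `U = sum of ranks of x minus nx(nx+1)/2`. The two-sided
#' p-value is exact — by enumeration over all label assignments — when
#' `nx + ny <= exact_max` and there are no ties, and otherwise uses the
#' normal approximation with tie and continuity corrections.
#'
#' @param x,y numeric samples.
#' @param exact_max combined sample size up to which enumeration is used.
#' @return List with `U`, `p`, and `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12L) {
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) {
    rlang::abort("both samples must be non-empty",
                 class = "nwuct_parameter_error")
  }
  all_v <- c(x, y)
  r <- rank(all_v)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(all_v))
  mu <- nx * ny / 2
  if (!ties && nx + ny <= exact_max) {
    combs <- utils::combn(nx + ny, nx)
    r0 <- rank(all_v)
    u_all <- apply(combs, 2, function(idx) sum(r0[idx]) - nx * (nx + 1) / 2)
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    N <- nx + ny
    tie_tab <- table(all_v)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- nx * ny / 12 * ((N + 1) - tie_corr)
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "degenerate"))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(U = U, p = p, method = method)
}

## ---- model comparison workflow ----

#' Compare two covariate-adjusted outcome models
#'
#' Reproduces the evaluation workflow for competing biomarkers: stratified
#' 80:20 split, logistic fits of both predictor sets on the training rows,
#' scoring of the held-out test rows, AUROC for each model, and the DeLong
#' paired comparison of the two test-set score vectors.
#'
#' @param data cohort tibble.
#' @param predictors_a,predictors_b predictor column sets for the two models.
#' @param outcome_col binary outcome column.
#' @param test_fraction held-out fraction per class.
#' @param seed split seed.
#' @return An object of class `model_comparison`: AUROCs, DeLong z and
#'   two-sided p, fitted models, test scores and provenance (seed, n_test).
#' @export
compare_models <- function(data, predictors_a, predictors_b,
                           outcome_col = "outcome", test_fraction = 0.2,
                           seed = 1L) {
  data <- drop_missing(tibble::as_tibble(data),
                       c(outcome_col, union(predictors_a, predictors_b)))
  parts <- stratified_split(data, outcome_col, test_fraction, seed)
  fit_a <- fit_logistic(parts$train, outcome_col, predictors_a)
  fit_b <- fit_logistic(parts$train, outcome_col, predictors_b)
  scores_a <- predict(fit_a, parts$test)
  scores_b <- predict(fit_b, parts$test)
  labels <- parts$test[[outcome_col]]
  dl <- delong_test(scores_a, scores_b, labels)
  structure(list(
    auroc_a = dl$auc_a, auroc_b = dl$auc_b,
    delong_z = dl$z, delong_p = dl$p,
    var_a = dl$var_a, var_b = dl$var_b, cov_ab = dl$cov_ab,
    fit_a = fit_a, fit_b = fit_b,
    scores_a = scores_a, scores_b = scores_b, test_labels = labels,
    predictors_a = predictors_a, predictors_b = predictors_b,
    n_test = nrow(parts$test), n_train = nrow(parts$train),
    split_seed = seed
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> AUROC %.3f (A: %s) vs %.3f (B: %s)\n",
              x$auroc_a, paste(x$predictors_a, collapse = "+"),
              x$auroc_b, paste(x$predictors_b, collapse = "+")))
  cat(sprintf("  DeLong z = %.3f, two-sided p = %.3f (n_test = %d, seed %d)\n",
              x$delong_z, x$delong_p, x$n_test, x$split_seed))
  invisible(x)
}

#' One-row summary of a model comparison
#' @param x a `model_comparison`.
#' @param ... unused.
#' @return Tibble with both AUROCs, the DeLong statistic and p-value, and
#'   split provenance.
#' @export
glance.model_comparison <- function(x, ...) {
  tibble::tibble(auroc_a = x$auroc_a, auroc_b = x$auroc_b,
                 delong_z = x$delong_z, delong_p = x$delong_p,
                 n_train = x$n_train, n_test = x$n_test,
                 split_seed = x$split_seed)
}

roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1)
  fp <- cumsum(labels[ord] == 0)
  tibble::tibble(fpr = c(0, fp / sum(labels == 0)),
                 tpr = c(0, tp / sum(labels == 1)))
}

#' ROC curves of a model comparison
#' @param object a `model_comparison`.
#' @param ... unused.
#' @return A ggplot with both test-set ROC curves.
#' @export
autoplot.model_comparison <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(roc_points(object$scores_a, object$test_labels),
                  model = sprintf("A (AUROC %.3f)", object$auroc_a)),
    dplyr::mutate(roc_points(object$scores_b, object$test_labels),
                  model = sprintf("B (AUROC %.3f)", object$auroc_b)))
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr,
                                   colour = .data$model)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  subtitle = sprintf("DeLong p = %.3f", object$delong_p)) +
    ggplot2::theme_minimal()
}

## ---- cohort description ----

quantile7 <- function(x, p) unname(stats::quantile(x, p, type = 7))

#' Describe a cohort with between-group tests
#'
#' For binary columns: per-group `n (%)` with a Fisher exact p-value; for
#' continuous columns: `median [IQR]` (type-7 quartiles) with a Wilcoxon
#' rank-sum p-value. Percentages are `100 * count / group_n` rounded to one
#' decimal.
#'
#' @param data cohort tibble.
#' @param group_col binary grouping column (e.g. the outcome).
#' @param vars columns to summarise; default all numeric columns except the
#'   group.
#' @return Tibble: variable, type, overall and per-group summaries, p-value.
#' @export
describe_cohort <- function(data, group_col, vars = NULL) {
  data <- tibble::as_tibble(data)
  g <- data[[group_col]]
  levs <- sort(unique(g))
  if (length(levs) != 2) {
    rlang::abort("group column must have exactly two levels",
                 class = "nwuct_parameter_error")
  }
  for (l in levs) {
    if (sum(g == l) == 0) {
      rlang::abort(sprintf("group '%s' is empty", l),
                   class = "nwuct_parameter_error")
    }
  }
  if (is.null(vars)) {
    vars <- setdiff(names(data)[vapply(data, is.numeric, TRUE)], group_col)
  }
  fmt_bin <- function(x) sprintf("%d (%.1f%%)", sum(x == 1),
                                 round(100 * sum(x == 1) / length(x), 1))
  fmt_cont <- function(x) sprintf("%g [%g, %g]", quantile7(x, 0.5),
                                  quantile7(x, 0.25), quantile7(x, 0.75))
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    x1 <- x[g == levs[1]]
    x2 <- x[g == levs[2]]
    if (all(x %in% c(0, 1))) {
      tab <- rbind(c(sum(x1 == 1), sum(x1 == 0)),
                   c(sum(x2 == 1), sum(x2 == 0)))
      p <- fisher_exact_2x2(tab)$p
      tibble::tibble(variable = v, type = "binary",
                     overall = fmt_bin(x), group1 = fmt_bin(x1),
                     group2 = fmt_bin(x2), p_value = p)
    } else {
      p <- wilcoxon_rank_sum(x1, x2)$p
      tibble::tibble(variable = v, type = "continuous",
                     overall = fmt_cont(x), group1 = fmt_cont(x1),
                     group2 = fmt_cont(x2), p_value = p)
    }
  })
  out <- dplyr::bind_rows(rows)
  names(out)[names(out) == "group1"] <- paste0(group_col, "=", levs[1])
  names(out)[names(out) == "group2"] <- paste0(group_col, "=", levs[2])
  out
}
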