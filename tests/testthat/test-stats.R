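test_that("IRLS logistic fit matches glm and decreases deviance monotonically", {
  tab <- generate_cohort(800, seed = 21L)
  fit <- fit_logistic(tab, "outcome", c("avg_nwu", "age", "nihss", "tpa", "evt"))
  ref <- stats::glm(outcome ~ avg_nwu + age + nihss + tpa + evt,
                    binomial(), tab)
  expect_equal(unname(fit$coefficients[names(coef(ref))]),
               unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$standard_errors),
               unname(summary(ref)$coefficients[names(fit$coefficients), 2]),
               tolerance = 1e-4)
  expect_true(all(diff(fit$deviance_trace) <= 1e-8))
  expect_true(fit$converged)
  # odds ratios and CIs: positive, CI brackets the point estimate
  expect_true(all(fit$odds_ratios > 0))
  expect_true(all(fit$ci95[, "low"] <= fit$odds_ratios &
                    fit$odds_ratios <= fit$ci95[, "high"]))
})

test_that("the 6-row fit beats a brute-force coefficient grid search", {
  df <- tibble::tibble(x = c(-2, -1, -0.5, 0.5, 1, 2, -1.5, 1.5, 0.2, -0.2),
                       outcome = c(0, 0, 1, 0, 1, 1, 0, 1, 1, 0))
  fit <- fit_logistic(df, "outcome", "x")
  ll <- function(b) {
    eta <- b[1] + b[2] * df$x
    sum(df$outcome * stats::plogis(eta, log.p = TRUE) +
          (1 - df$outcome) * stats::plogis(-eta, log.p = TRUE))
  }
  grid <- seq(-5, 5, by = 0.05)
  best_grid <- max(vapply(grid, function(b0) {
    max(vapply(grid, function(b1) ll(c(b0, b1)), 0))
  }, 0))
  expect_gte(ll(fit$coefficients) + 1e-9, best_grid)
})

test_that("null data at n = 4000 recovers a near-zero coefficient", {
  set.seed(22)
  df <- tibble::tibble(x = rnorm(4000), outcome = rep(c(0, 1), 2000))
  fit <- fit_logistic(df, "outcome", "x")
  expect_lt(abs(fit$coefficients[["x"]]), 0.1)
})

test_that("degenerate designs raise named errors", {
  df <- tibble::tibble(x = rnorm(50), y = rnorm(50), outcome = rbinom(50, 1, 0.5))
  df$z <- df$x + df$y
  expect_error(fit_logistic(df[1:5, ], "outcome", "x"),
               class = "nwuct_parameter_error")
  df2 <- df
  df2$outcome <- 1
  expect_error(fit_logistic(df2, "outcome", "x"),
               class = "nwuct_degenerate_outcome_error")
  expect_error(fit_logistic(df, "outcome", c("x", "y", "z")), "z",
               class = "nwuct_collinearity_error")
  df3 <- df
  df3$x <- 1
  expect_error(fit_logistic(df3, "outcome", "x"),
               class = "nwuct_parameter_error")
})

test_that("stratified split follows the per-class rounding rule", {
  tab <- tibble::tibble(outcome = rep(c(1, 0), c(40, 60)), i = 1:100)
  sp <- stratified_split(tab, "outcome", 0.2, seed = 5L)
  expect_equal(sum(sp$test$outcome == 1), 8)
  expect_equal(sum(sp$test$outcome == 0), 12)
  # partition: disjoint and exhaustive
  expect_setequal(c(sp$train$i, sp$test$i), 1:100)
  expect_length(intersect(sp$train$i, sp$test$i), 0)
  # determinism
  sp2 <- stratified_split(tab, "outcome", 0.2, seed = 5L)
  expect_identical(sp$test$i, sp2$test$i)
  sp3 <- stratified_split(tab, "outcome", 0.2, seed = 6L)
  expect_false(identical(sp$test$i, sp3$test$i))
  # exact .5 ties: larger class rounds up, smaller down (27 pos, 73 neg ->
  # 27*0.5 = 13.5 and 73*0.5 = 36.5 at fraction 0.5)
  tab2 <- tibble::tibble(outcome = rep(c(1, 0), c(27, 73)))
  sp4 <- stratified_split(tab2, "outcome", 0.5, seed = 1L)
  expect_equal(sum(sp4$test$outcome == 1), 13)
  expect_equal(sum(sp4$test$outcome == 0), 37)
})

test_that("AUROC equals pair counting, including edge cases", {
  # perfect separation and all-ties
  expect_equal(auroc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1.0)
  expect_equal(auroc(rep(4, 10), rep(c(0, 1), 5)), 0.5)
  # hand example, 8 subjects
  s <- c(0.1, 0.4, 0.35, 0.8, 0.65, 0.2, 0.9, 0.5)
  l <- c(0, 0, 1, 1, 0, 0, 1, 1)
  expect_equal(auroc(s, l), pair_count_auroc(s, l))
  # exhaustive random trials at n <= 12, with ties
  set.seed(23)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    l <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq_len(6), n, replace = TRUE) / 2
    expect_equal(auroc(s, l), pair_count_auroc(s, l))
  }
  expect_error(auroc(1:4, rep(1, 4)), class = "nwuct_degenerate_label_error")
})

test_that("DeLong agrees with pROC and handles identical models", {
  set.seed(24)
  l <- c(rep(1, 40), rep(0, 60))
  sa <- rnorm(100) + l
  sb <- 0.8 * sa + rnorm(100, sd = 0.6)
  dl <- delong_test(sa, sb, l)
  ra <- pROC::roc(l, sa, quiet = TRUE, direction = "<")
  rb <- pROC::roc(l, sb, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong")
  expect_equal(dl$z, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(dl$p, ref$p.value, tolerance = 1e-9)
  expect_equal(dl$auc_a, as.numeric(pROC::auc(ra)))
  # identical scores: z = 0, p = 1
  same <- delong_test(sa, sa, l)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  expect_error(delong_test(sa, sb[1:50], l), class = "nwuct_pairing_error")
  expect_error(delong_test(sa, sb, rep(1, 100)),
               class = "nwuct_degenerate_label_error")
})

test_that("DeLong variance matches a stratified bootstrap at n = 30", {
  set.seed(25)
  scores <- rexp(30)
  labels <- c(rep(1, 14), rep(0, 16))
  v_dl <- delong_test(scores, scores, labels)$var_a
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  boots <- replicate(20000, {
    s <- c(scores[sample(pos, replace = TRUE)],
           scores[sample(neg, replace = TRUE)])
    auroc(s, labels[c(pos, neg)])
  })
  expect_lt(abs(v_dl / stats::var(boots) - 1), 0.15)
})

test_that("DeLong type-I error is near the nominal level", {
  set.seed(26)
  rej <- mean(replicate(2000, {
    l <- rbinom(100, 1, 0.5)
    if (length(unique(l)) < 2) l[1] <- 1 - l[1]
    delong_test(rnorm(100), rnorm(100), l)$p < 0.05
  }))
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("Fisher exact p matches hypergeometric enumeration", {
  res <- fisher_exact_2x2(rbind(c(5, 5), c(5, 5)))
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p, 1)
  tab <- rbind(c(1, 9), c(11, 3))
  res2 <- fisher_exact_2x2(tab)
  # independent enumeration over the hypergeometric support
  k <- 12; m1 <- 10; m2 <- 14
  supp <- max(0, k - m2):min(k, m1)
  pr <- dhyper(supp, m1, m2, k)
  p_enum <- sum(pr[pr <= dhyper(1, m1, m2, k) * (1 + 1e-7)])
  expect_equal(res2$p, p_enum)
  expect_equal(res2$p, stats::fisher.test(tab)$p.value, tolerance = 1e-12)
  # simultaneous row/column swap leaves p unchanged
  res3 <- fisher_exact_2x2(tab[2:1, 2:1])
  expect_equal(res3$p, res2$p)
  # Haldane correction on a zero cell
  res4 <- fisher_exact_2x2(rbind(c(0, 10), c(5, 5)))
  expect_equal(res4$odds_ratio, (0.5 * 5.5) / (10.5 * 5.5))
})

test_that("Wilcoxon rank-sum matches enumeration and is antisymmetric", {
  # identical samples with ties: no evidence of shift
  x <- c(1, 2, 2, 3, 4)
  expect_gte(wilcoxon_rank_sum(x, x)$p, 0.99)
  # 4 vs 4 distinct: exact enumeration over all 70 assignments
  x4 <- c(1.1, 2.3, 3.1, 4.7)
  y4 <- c(2.0, 5.5, 6.1, 7.2)
  res <- wilcoxon_rank_sum(x4, y4)
  expect_equal(res$method, "exact enumeration")
  expect_equal(res$p, stats::wilcox.test(x4, y4, exact = TRUE)$p.value)
  swapped <- wilcoxon_rank_sum(y4, x4)
  expect_equal(swapped$p, res$p)
  expect_equal(swapped$U, length(x4) * length(y4) - res$U)
  # large samples with ties: normal approximation matches wilcox.test
  set.seed(27)
  xl <- round(rnorm(30), 1)
  yl <- round(rnorm(40, 0.3), 1)
  expect_equal(wilcoxon_rank_sum(xl, yl)$p,
               stats::wilcox.test(xl, yl, exact = FALSE,
                                  correct = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("compare_models is paired, seeded, and detects a real difference", {
  tab <- generate_cohort(1500, seed = 28L)
  # identical predictor sets: equal AUROCs, p = 1
  cmp0 <- compare_models(tab, c("avg_nwu", "age"), c("avg_nwu", "age"),
                         seed = 3L)
  expect_equal(cmp0$auroc_a, cmp0$auroc_b)
  expect_equal(cmp0$delong_p, 1)
  # signal vs pure noise biomarker
  set.seed(29)
  tab$noise <- rnorm(nrow(tab))
  cmp <- compare_models(tab, c("avg_nwu", "nihss"), c("noise", "nihss"),
                        seed = 4L)
  expect_gt(cmp$auroc_a, cmp$auroc_b)
  # reproducibility from the seed
  cmp2 <- compare_models(tab, c("avg_nwu", "nihss"), c("noise", "nihss"),
                         seed = 4L)
  expect_equal(glance(cmp), glance(cmp2))
  expect_s3_class(autoplot(cmp), "ggplot")
})

test_that("signal-vs-noise comparison rejects in most replicates", {
  set.seed(30)
  hits <- 0L
  n_rep <- 25L
  for (i in seq_len(n_rep)) {
    tab <- generate_cohort(3000, cohort_model(b_nwu = 0.25), seed = 300L + i)
    tab$noise <- rnorm(nrow(tab))
    cmp <- compare_models(tab, "avg_nwu", "noise", seed = i)
    hits <- hits + (cmp$auroc_a > cmp$auroc_b && cmp$delong_p < 0.05)
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("describe_cohort reports n (%), median [IQR], and p-values", {
  # the percentage convention: 139 events among 157 -> 88.5%
  tab <- tibble::tibble(
    grp = rep(c(1, 0), c(157, 100)),
    event = c(rep(c(1, 0), c(139, 18)), rep(c(1, 0), c(50, 50))),
    score = c(seq_len(157), seq(200, 299))
  )
  out <- describe_cohort(tab, "grp")
  row <- out[out$variable == "event", ]
  expect_match(row[["grp=1"]], "139 (88.5%)", fixed = TRUE)
  expect_equal(row$type, "binary")
  srow <- out[out$variable == "score", ]
  expect_equal(srow$type, "continuous")
  # median [IQR] of 1..5 is 3 [2, 4] (type-7 quartiles)
  tiny <- tibble::tibble(grp = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                         v = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))
  d <- describe_cohort(tiny, "grp", "v")
  expect_match(d[["grp=1"]], "3 [2, 4]", fixed = TRUE)
  expect_error(describe_cohort(tibble::tibble(grp = rep(1, 5), v = 1:5), "grp"),
               class = "nwuct_parameter_error")
})
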