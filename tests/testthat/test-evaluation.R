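fake_matrix <- function(g1, g0) {
  # build a minimal feature matrix from two per-class feature data frames
  tibble::tibble(
    lesion_id = sprintf("l%02d", seq_len(nrow(g1) + nrow(g0))),
    dplyr::bind_rows(g1, g0),
    target = c(rep(1L, nrow(g1)), rep(0L, nrow(g0)))
  )
}

test_that("duplicated groups give t = 0 and p = 1 everywhere", {
  set.seed(1)
  g <- tibble::tibble(f1 = rnorm(10), f2 = rnorm(10))
  res <- ttest_features(fake_matrix(g, g))
  expect_true(all(res$t == 0))
  expect_true(all(res$p == 1))
  expect_false(any(res$significant))
})

test_that("Welch statistics match the textbook formula to 1e-10", {
  set.seed(2)
  for (i in 1:25) {
    a <- rnorm(8 + i %% 5, sd = runif(1, 0.5, 2))
    b <- rnorm(12, mean = runif(1, -1, 1))
    m <- fake_matrix(tibble::tibble(f1 = a), tibble::tibble(f1 = b))
    res <- ttest_features(m)
    ref <- brute_welch(a, b)
    expect_equal(res$t, ref$t, tolerance = 1e-10)
    expect_equal(res$p, ref$p, tolerance = 1e-10)
  }
})

test_that("a 3-sd mean shift at n = 40 per group is always flagged at 0.05/94", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    m <- fake_matrix(tibble::tibble(f1 = rnorm(40, mean = 3)),
                     tibble::tibble(f1 = rnorm(40)))
    ttest_features(m, n_tests = 94)$significant
  }, logical(1))
  expect_true(all(hits))
})

test_that("zero-variance features degrade gracefully", {
  m <- fake_matrix(tibble::tibble(f1 = rep(1, 5), f2 = rep(1, 5)),
                   tibble::tibble(f1 = rep(1, 5), f2 = rep(2, 5)))
  res <- ttest_features(m)
  expect_equal(res$p[res$feature == "f1"], 1)
  expect_false(res$exact_separation[res$feature == "f1"])
  expect_equal(res$p[res$feature == "f2"], 0)
  expect_true(res$exact_separation[res$feature == "f2"])
})

test_that("pooled co-occurrence tests use the 0.05/20 threshold", {
  m <- default_feature_matrix()
  res <- pooled_glcm_tests(m)
  expect_equal(nrow(res), 20)
  expect_equal(unique(res$threshold), 0.0025)
  # pooling then testing equals testing the hand-pooled columns
  pooled <- pooled_glcm_matrix(m)
  a <- pooled$pooled_contrast[pooled$target == 1]
  b <- pooled$pooled_contrast[pooled$target == 0]
  ref <- brute_welch(a, b)
  expect_equal(res$t[res$feature == "contrast"], ref$t, tolerance = 1e-10)
})

test_that("confusion metrics reproduce the radiologist worked example", {
  cm <- confusion_metrics(tp = 43, fn = 6, tn = 30, fp = 12)
  expect_equal(cm$sensitivity, 100 * 43 / 49, tolerance = 1e-12)
  expect_equal(cm$accuracy, 100 * 73 / 91, tolerance = 1e-12)  # 80.22 -> 80.2%
  expect_equal(round(cm$accuracy, 1), 80.2)
  expect_equal(round(cm$sensitivity, 2), 87.76)
  expect_equal(round(cm$specificity, 2), 71.43)

  perfect <- confusion_metrics(10, 0, 10, 0)
  expect_true(all(unlist(perfect) == 100))
  worst <- confusion_metrics(0, 10, 0, 10)
  expect_equal(worst$sensitivity, 0)
  expect_equal(worst$specificity, 0)
  expect_error(confusion_metrics(0, 0, 5, 5), "each true class")
})

test_that("confusion metric identities hold on random confusion matrices", {
  set.seed(4)
  for (i in 1:50) {
    k <- sample(0:20, 4, replace = TRUE)
    if (k[1] + k[2] == 0 || k[3] + k[4] == 0) next
    cm <- confusion_metrics(k[1], k[2], k[3], k[4])
    n <- sum(k)
    expect_equal(cm$accuracy, 100 * (k[1] + k[3]) / n)
    prev <- (k[1] + k[2]) / n
    if (k[1] + k[4] > 0) {
      ppv <- (cm$sensitivity / 100 * prev) /
        (cm$sensitivity / 100 * prev + (1 - cm$specificity / 100) * (1 - prev))
      expect_equal(cm$ppv, 100 * ppv)
    }
  }
})

test_that("ROC examples and the pairwise-ordering equivalence hold", {
  r <- roc_curve(c(0, 1, 1, 0, 1), c(0, 1, 1, 0, 1))
  expect_equal(r$auc, 1.0)
  r2 <- roc_curve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r2$auc, 0.75)
  expect_error(roc_curve(c(1, 2), c(1, 1)), "both classes")

  set.seed(6)
  for (i in 1:50) {
    n <- sample(6:25, 1)
    scores <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, brute_auc(scores, labels), tolerance = 1e-12)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
  }
})

test_that("the Youden threshold maximizes sensitivity + specificity - 1", {
  scores <- c(0.1, 0.2, 0.6, 0.7, 0.8, 0.9)
  labels <- c(0, 0, 0, 1, 1, 1)
  r <- roc_curve(scores, labels)
  thr <- youden_threshold(r)
  expect_equal(thr, 0.7)
  pred <- as.integer(scores >= thr)
  expect_equal(sum(pred == labels), 6)
})

test_that("one-way ANOVA across AUC lists matches the sums-of-squares oracle", {
  set.seed(8)
  lists <- lapply(1:4, function(i) rnorm(30, mean = 0.8 + 0.02 * i, sd = 0.05))
  names(lists) <- c("attenuation", "glcm", "lbp", "all")
  res <- compare_auc_distributions(lists)
  expect_equal(res$omnibus$f_statistic, brute_anova_f(lists), tolerance = 1e-10)
  expect_equal(nrow(res$pairwise), 6)
  expect_equal(res$pairwise$p_adjusted, pmin(res$pairwise$p * 6, 1))

  same <- rep(list(rnorm(20)), 4)
  res2 <- compare_auc_distributions(same)
  expect_equal(res2$omnibus$f_statistic, 0)
  expect_equal(res2$omnibus$p, 1)
})

test_that("a strongly shifted AUC distribution is significant after adjustment", {
  set.seed(9)
  base <- lapply(1:3, function(i) rnorm(100, 0.85, 0.01))
  shifted <- list(rnorm(100, 0.95, 0.01))
  res <- compare_auc_distributions(c(base, shifted))
  pw <- res$pairwise
  involves4 <- pw$group1 == "model_4" | pw$group2 == "model_4"
  expect_true(all(pw$p_adjusted[involves4] < 0.05))
  expect_lt(res$omnibus$p, 1e-10)
})

test_that("the network separates two disjoint Gaussian blobs almost perfectly", {
  set.seed(11)
  n <- 30
  g1 <- tibble::tibble(f1 = rnorm(n, 5), f2 = rnorm(n, 5))
  g0 <- tibble::tibble(f1 = rnorm(n, -5), f2 = rnorm(n, -5))
  m <- fake_matrix(g1, g0)
  ev <- train_eval_ann(m, "all", hidden_units = 10, folds = 5, cycles = 3,
                       seed = 1)
  expect_gte(ev$summary$mean[ev$summary$metric == "auc"], 0.99)
})

test_that("cross-validation is deterministic under the seed", {
  m <- default_feature_matrix()
  e1 <- train_eval_ann(m, "lbp", folds = 5, cycles = 2, seed = 7)
  e2 <- train_eval_ann(m, "lbp", folds = 5, cycles = 2, seed = 7)
  expect_identical(e1$cycle_metrics, e2$cycle_metrics)
  expect_identical(e1$pooled_roc$auc, e2$pooled_roc$auc)
  e3 <- train_eval_ann(m, "lbp", folds = 5, cycles = 2, seed = 8)
  expect_false(identical(e1$cycle_metrics$auc, e3$cycle_metrics$auc))
})

test_that("scaling and training artifacts never see test rows", {
  m <- default_feature_matrix()
  X <- as.matrix(m[, feature_set_columns("lbp")])
  y <- as.integer(m$target)
  train_rows <- which(seq_along(y) %% 3 != 0)
  fit1 <- nodtex:::ann_fold_fit(X, y, train_rows, hidden = 5, seed = 3)
  Xp <- X
  Xp[-train_rows, ] <- Xp[-train_rows, ] * 100 + 7  # perturb test rows only
  fit2 <- nodtex:::ann_fold_fit(Xp, y, train_rows, hidden = 5, seed = 3)
  expect_identical(fit1$scaler, fit2$scaler)
  expect_identical(fit1$net$params, fit2$net$params)
})

test_that("too few lesions per class for the fold count is an error", {
  m <- default_feature_matrix()
  expect_error(train_eval_ann(m[c(1:5, 50:60), ], "lbp", folds = 10),
               "per class")
})

test_that("tidy and glance summarize a cross-validation run", {
  m <- default_feature_matrix()
  ev <- train_eval_ann(m, "attenuation", folds = 5, cycles = 2, seed = 2)
  td <- tidy(ev)
  expect_setequal(unique(td$metric),
                  c("auc", "sensitivity", "specificity", "accuracy", "ppv", "npv"))
  gl <- glance(ev)
  expect_equal(gl$feature_set[1], "attenuation")
  expect_equal(nrow(gl), 6)
})
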