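#' Welch t-tests across feature columns with Bonferroni threshold
#'
#' Two-sided Welch (unequal-variance) two-sample t-test per feature between
#' the NCH (`target == 1`) and adenocarcinoma (`target == 0`) groups, with a
#' significance flag at the Bonferroni-corrected level
#' `alpha / n_tests` (0.05/94 = 0.0005 for the full panel).
#'
#' A feature with zero variance in both groups has no test: its `p` is set
#' to 1 when the group means are equal, and the row is flagged
#' `exact_separation` (with `p = 0`) when they differ.
#'
#' @param m A feature matrix from [build_feature_matrix()] (needs a
#'   `target` column).
#' @param cols Feature columns to test; default every `f*` column.
#' @param alpha Family-wise error level (default 0.05).
#' @param n_tests Bonferroni divisor; defaults to `length(cols)`.
#' @return A tibble: `feature`, `mean_nch`, `mean_aca`, `t`, `p`,
#'   `threshold`, `significant`, `exact_separation`.
#' @export
ttest_features <- function(m, cols = NULL, alpha = 0.05, n_tests = NULL) {
  stopifnot("target" %in% names(m))
  if (is.null(cols)) cols <- grep("^f[0-9]+$", names(m), value = TRUE)
  if (is.null(n_tests)) n_tests <- length(cols)
  g1 <- m[m$target == 1, , drop = FALSE]
  g0 <- m[m$target == 0, , drop = FALSE]
  if (nrow(g1) < 2L || nrow(g0) < 2L) {
    stop("group tests need at least 2 lesions per class (got ",
         nrow(g1), " nch / ", nrow(g0), " aca)")
  }
  threshold <- alpha / n_tests
  purrr::map_dfr(cols, function(f) {
    a <- g1[[f]]; b <- g0[[f]]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      same <- isTRUE(all.equal(mean(a), mean(b)))
      tibble::tibble(
        feature = f, mean_nch = mean(a), mean_aca = mean(b),
        t = if (same) 0 else Inf * sign(mean(a) - mean(b)),
        p = if (same) 1 else 0,
        threshold = threshold, significant = !same, exact_separation = !same
      )
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
      tibble::tibble(
        feature = f, mean_nch = mean(a), mean_aca = mean(b),
        t = unname(tt$statistic), p = tt$p.value,
        threshold = threshold, significant = tt$p.value < threshold,
        exact_separation = FALSE
      )
    }
  })
}

#' Group tests on the orientation-pooled co-occurrence features
#'
#' Averages each co-occurrence feature over its four orientations and runs
#' the same Welch tests at the pooled Bonferroni threshold 0.05/20 = 0.0025.
#'
#' @inheritParams ttest_features
#' @return A tibble as in [ttest_features()] with `feature` = pooled names.
#' @export
pooled_glcm_tests <- function(m, alpha = 0.05) {
  pooled <- pooled_glcm_matrix(m)
  cols <- grep("^pooled_", names(pooled), value = TRUE)
  res <- ttest_features(
    dplyr::rename_with(pooled, function(x) sub("^pooled_", "tmpf_", x),
                       dplyr::all_of(cols)),
    cols = sub("^pooled_", "tmpf_", cols),
    alpha = alpha, n_tests = length(cols)
  )
  res$feature <- sub("^tmpf_", "", res$feature)
  res
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity, specificity, accuracy, positive and negative predictive
#' value, all in percent. The positive class throughout the package is the
#' non-calcified hamartoma.
#'
#' @param tp,fn,tn,fp Confusion counts (true/false positive/negative).
#' @return A tibble with columns `sensitivity`, `specificity`, `accuracy`,
#'   `ppv`, `npv` (percent).
#' @examples
#' confusion_metrics(43, 6, 30, 12) # accuracy 80.22%
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  if (tp + fn <= 0 || tn + fp <= 0) {
    stop("confusion metrics need at least one case in each true class")
  }
  tibble::tibble(
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / (tp + fn + tn + fp),
    ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_
  )
}

#' Receiver operating characteristic curve
#'
#' Sweeps a decision threshold over the unique scores (score >= threshold
#' gives a positive call) and records (FPR, TPR) at every step; the area
#' under the curve is computed by the trapezoid rule, which equals the
#' Mann-Whitney pairwise-ordering probability (ties counted 1/2).
#'
#' @param scores Numeric classifier scores, larger meaning more
#'   positive-like.
#' @param labels 0/1 vector (1 = positive class, NCH).
#' @return A `roc_curve` object: list with `points` (tibble `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    stop("ROC needs both classes present (got ", npos, " positives, ",
         nneg, " negatives)")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp_cum <- cumsum(y)
  fp_cum <- cumsum(1 - y)
  steps <- which(!duplicated(s, fromLast = TRUE))
  points <- tibble::tibble(
    threshold = c(Inf, s[steps]),
    fpr = c(0, fp_cum[steps] / nneg),
    tpr = c(0, tp_cum[steps] / npos)
  )
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                   utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve>", nrow(x$points), "points, AUC =",
      sprintf("%.4f", x$auc), "\n")
  invisible(x)
}

#' Youden-optimal operating threshold of a ROC curve
#'
#' The threshold maximizing sensitivity + specificity - 1 (ties break to the
#' first, i.e. most stringent, threshold).
#'
#' @param roc A `roc_curve`.
#' @return A single threshold value.
#' @export
youden_threshold <- function(roc) {
  j <- roc$points$tpr - roc$points$fpr
  roc$points$threshold[which.max(j)]
}

## ---- feedforward network -------------------------------------------------

# Min-max scaler estimated from training rows only; constant columns map to
# a flat 0.5 so they carry no information into the network.
scale_minmax_train <- function(X) {
  mn <- apply(X, 2, min)
  rg <- apply(X, 2, max) - mn
  list(min = mn, range = rg)
}

scale_minmax_apply <- function(X, sc) {
  out <- sweep(X, 2, sc$min)
  out <- sweep(out, 2, ifelse(sc$range == 0, 1, sc$range), "/")
  out[, sc$range == 0] <- 0.5
  out
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

xent <- function(P, y) -mean(log(pmax(P[cbind(seq_along(y), y + 1L)], 1e-12)))

# Single-hidden-layer feedforward network: tanh hidden units, softmax
# output, cross-entropy loss, full-batch Adam with early stopping on a
# stratified validation split of the training rows.
train_mlp <- function(X, y, hidden = 50L, seed = 1L,
                      max_epochs = 400L, patience = 25L, lr = 0.02,
                      val_frac = 0.1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  n <- nrow(X); d <- ncol(X)
  # stratified validation split
  val <- unlist(lapply(c(0L, 1L), function(cl) {
    idx <- which(y == cl)
    k <- max(1L, round(val_frac * length(idx)))
    sample(idx, min(k, length(idx) - 1L))
  }))
  tr <- setdiff(seq_len(n), val)
  Xt <- X[tr, , drop = FALSE]; yt <- y[tr]
  Xv <- X[val, , drop = FALSE]; yv <- y[val]

  s1 <- sqrt(6 / (d + hidden)); s2 <- sqrt(6 / (hidden + 2))
  W1 <- matrix(stats::runif(d * hidden, -s1, s1), d, hidden)
  b1 <- rep(0, hidden)
  W2 <- matrix(stats::runif(hidden * 2, -s2, s2), hidden, 2)
  b2 <- rep(0, 2)

  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  mom1 <- lapply(params, function(p) p * 0)
  mom2 <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  forward <- function(p, X) {
    H <- tanh(sweep(X %*% p$W1, 2, p$b1, "+"))
    P <- softmax_rows(sweep(H %*% p$W2, 2, p$b2, "+"))
    list(H = H, P = P)
  }

  Yt <- cbind(1 - yt, yt)  # one-hot: col 1 = class 0, col 2 = class 1
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(max_epochs)) {
    fw <- forward(params, Xt)
    dZ <- (fw$P - Yt) / nrow(Xt)
    gW2 <- t(fw$H) %*% dZ
    gb2 <- colSums(dZ)
    dH <- dZ %*% t(params$W2) * (1 - fw$H^2)
    gW1 <- t(Xt) %*% dH
    gb1 <- colSums(dH)
    grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
    for (k in names(params)) {
      mom1[[k]] <- beta1 * mom1[[k]] + (1 - beta1) * grads[[k]]
      mom2[[k]] <- beta2 * mom2[[k]] + (1 - beta2) * grads[[k]]^2
      m_hat <- mom1[[k]] / (1 - beta1^epoch)
      v_hat <- mom2[[k]] / (1 - beta2^epoch)
      params[[k]] <- params[[k]] - lr * m_hat / (sqrt(v_hat) + eps)
    }
    val_loss <- xent(forward(params, Xv)$P, yv)
    if (!is.finite(val_loss)) {
      return(list(params = best$params, converged = FALSE,
                  forward = forward, val_loss = best$loss))
    }
    if (val_loss < best$loss - 1e-6) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  list(params = best$params, converged = is.finite(best$loss),
       forward = forward, val_loss = best$loss)
}

predict_mlp <- function(net, X) {
  net$forward(net$params, X)[["P"]][, 2]  # probability of class 1 (NCH)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over folds.
stratified_folds <- function(y, folds, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  assign <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

# Fit one fold: scaling and the network see training rows only.
# Exposed internally so leakage can be asserted directly in tests.
ann_fold_fit <- function(X, y, train_rows, hidden, seed) {
  sc <- scale_minmax_train(X[train_rows, , drop = FALSE])
  Xt <- scale_minmax_apply(X[train_rows, , drop = FALSE], sc)
  net <- train_mlp(Xt, y[train_rows], hidden = hidden, seed = seed)
  if (!net$converged) {
    net <- train_mlp(Xt, y[train_rows], hidden = hidden,
                     seed = derive_seed(seed, 104729L))
    net$retried <- TRUE
  }
  list(scaler = sc, net = net)
}

#' Repeated cross-validated neural-network evaluation
#'
#' Evaluates a single-hidden-layer feedforward network (tanh hidden units,
#' two softmax outputs, cross-entropy loss, early stopping on a 10%
#' validation split of the training rows) on one feature set by stratified
#' k-fold cross-validation repeated over many training-testing cycles. Fold
#' assignment is reseeded every cycle so repeated cycles explore different
#' partitions. Within each fold the feature columns are min-max scaled on
#' training rows only (no leakage). Test-fold scores are pooled within each
#' cycle; cycle metrics are taken at the Youden-optimal threshold of the
#' cycle's ROC curve, with NCH as the positive class.
#'
#' @param m A feature matrix from [build_feature_matrix()].
#' @param feature_set `"attenuation"`, `"glcm"`, `"lbp"` or `"all"`.
#' @param hidden_units Hidden layer width (default 50).
#' @param folds Number of cross-validation folds (default 10).
#' @param cycles Number of training-testing cycles (default 100).
#' @param seed Master seed; every random choice derives from it.
#' @return An `ann_eval` object: list with `cycle_metrics` (tibble: `cycle`,
#'   `auc`, `sensitivity`, `specificity`, `accuracy`, `ppv`, `npv`,
#'   `threshold`, `retrained`), `summary` (tibble of mean and sd per
#'   metric), `pooled_roc` (ROC over all cycles' pooled scores) and the
#'   configuration.
#' @export
train_eval_ann <- function(m, feature_set = c("all", "attenuation", "glcm", "lbp"),
                           hidden_units = 50L, folds = 10L, cycles = 100L,
                           seed = 1L) {
  feature_set <- match.arg(feature_set)
  # "all" takes whatever f-columns the table carries, so reduced panels
  # (and small test fixtures) evaluate too; named sets need their block.
  cols <- if (feature_set == "all") {
    grep("^f[0-9]+$", names(m), value = TRUE)
  } else {
    feature_set_columns(feature_set)
  }
  stopifnot(length(cols) > 0, all(cols %in% names(m)), "target" %in% names(m))
  X <- as.matrix(m[, cols])
  y <- as.integer(m$target)
  if (min(sum(y == 1), sum(y == 0)) < folds) {
    stop("need at least ", folds, " lesions per class for ", folds,
         "-fold cross-validation")
  }

  all_scores <- numeric(0); all_labels <- integer(0)
  cyc <- purrr::map_dfr(seq_len(cycles), function(cycle) {
    cycle_seed <- derive_seed(seed, cycle)
    fold_of <- stratified_folds(y, folds, cycle_seed)
    scores <- numeric(length(y))
    retrained <- FALSE
    for (f in seq_len(folds)) {
      test_rows <- which(fold_of == f)
      train_rows <- which(fold_of != f)
      fit <- ann_fold_fit(X, y, train_rows, hidden_units,
                          seed = derive_seed(cycle_seed, f))
      if (isTRUE(fit$net$retried)) retrained <- TRUE
      Xte <- scale_minmax_apply(X[test_rows, , drop = FALSE], fit$scaler)
      scores[test_rows] <- predict_mlp(fit$net, Xte)
    }
    all_scores <<- c(all_scores, scores)
    all_labels <<- c(all_labels, y)
    roc <- roc_curve(scores, y)
    thr <- youden_threshold(roc)
    pred <- as.integer(scores >= thr)
    cm <- confusion_metrics(
      tp = sum(pred == 1 & y == 1), fn = sum(pred == 0 & y == 1),
      tn = sum(pred == 0 & y == 0), fp = sum(pred == 1 & y == 0)
    )
    dplyr::bind_cols(
      tibble::tibble(cycle = cycle, auc = roc$auc), cm,
      tibble::tibble(threshold = thr, retrained = retrained)
    )
  })

  metric_cols <- c("auc", "sensitivity", "specificity", "accuracy", "ppv", "npv")
  summary <- tidyr::pivot_longer(
    cyc[, metric_cols], dplyr::everything(),
    names_to = "metric", values_to = "value"
  ) |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$metric, metric_cols))

  structure(
    list(cycle_metrics = cyc, summary = summary,
         pooled_roc = roc_curve(all_scores, all_labels),
         feature_set = feature_set, hidden_units = hidden_units,
         folds = folds, cycles = cycles, seed = seed),
    class = "ann_eval"
  )
}

#' @export
print.ann_eval <- function(x, ...) {
  cat("<ann_eval>", x$feature_set, "features:", x$cycles, "cycles x",
      x$folds, "folds,", x$hidden_units, "hidden units\n")
  s <- x$summary
  for (k in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %7.3f +/- %.3f\n", s$metric[k], s$mean[k], s$sd[k]))
  }
  invisible(x)
}

#' Compare AUC distributions across classifier feature sets
#'
#' One-way ANOVA across the per-cycle AUC lists of several models, followed
#' by all pairwise Welch comparisons with Bonferroni adjustment.
#'
#' @param auc_lists Named list of equal-length numeric AUC vectors (one per
#'   model, length >= 2 each).
#' @return A list with `omnibus` (tibble: `f_statistic`, `p`, `df_between`,
#'   `df_within`) and `pairwise` (tibble: `group1`, `group2`, `mean_diff`,
#'   `p`, `p_adjusted`).
#' @export
compare_auc_distributions <- function(auc_lists) {
  if (length(auc_lists) < 2L) stop("need at least 2 AUC distributions")
  lens <- lengths(auc_lists)
  if (any(lens < 2L)) stop("every AUC list needs at least 2 values")
  if (length(unique(lens)) != 1L) stop("AUC lists must have equal length")
  if (is.null(names(auc_lists))) {
    names(auc_lists) <- paste0("model_", seq_along(auc_lists))
  }
  df <- tibble::tibble(
    model = factor(rep(names(auc_lists), lens)),
    auc = unlist(auc_lists, use.names = FALSE)
  )
  fit <- stats::aov(auc ~ model, data = df)
  an <- stats::anova(fit)
  fstat <- an[["F value"]][1]
  p <- an[["Pr(>F)"]][1]
  if (!is.finite(fstat)) { fstat <- 0; p <- 1 }  # zero between-group variance

  pairs <- utils::combn(names(auc_lists), 2, simplify = FALSE)
  pw <- purrr::map_dfr(pairs, function(pr) {
    a <- auc_lists[[pr[1]]]; b <- auc_lists[[pr[2]]]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      praw <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    } else {
      praw <- stats::t.test(a, b, var.equal = FALSE)$p.value
    }
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   mean_diff = mean(a) - mean(b), p = praw)
  })
  pw$p_adjusted <- pmin(pw$p * length(pairs), 1)
  list(
    omnibus = tibble::tibble(f_statistic = fstat, p = p,
                             df_between = an$Df[1], df_within = an$Df[2]),
    pairwise = pw
  )
}
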