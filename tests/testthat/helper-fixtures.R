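# Shared fixtures and independent oracles for the test suite.

# Build a quantized_slice directly from a levels matrix (rows = y, cols = x);
# values default to (levels - 0.5) / n so quantization would reproduce them.
make_slice <- function(levels, mask = NULL, values = NULL, n_levels = 8L) {
  levels <- as.matrix(levels)
  if (is.null(mask)) mask <- !is.na(levels)
  levels[!mask] <- NA_integer_
  if (is.null(values)) values <- (levels - 0.5) / n_levels
  values[!mask] <- NA_real_
  structure(
    list(levels = levels, values = values, mask = mask,
         slice_index = 0L, n_levels = as.integer(n_levels),
         offset = c(x = 0L, y = 0L)),
    class = "quantized_slice"
  )
}

# Brute-force co-occurrence oracle: explicit double loop over every pixel
# and its displaced partner, fully independent of the vectorized code path.
brute_glcm <- function(levels, mask, drow, dcol, n_levels = 8L) {
  counts <- matrix(0, n_levels, n_levels)
  nr <- nrow(levels); nc <- ncol(levels)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + drow; c2 <- c + dcol
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          isTRUE(mask[r, c]) && isTRUE(mask[r2, c2])) {
        a <- levels[r, c]; b <- levels[r2, c2]
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
      }
    }
  }
  if (sum(counts) == 0) stop("no pairs")
  counts / sum(counts)
}

# Pairwise-ordering AUC oracle (Mann-Whitney with ties at 1/2).
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Welch t statistic and two-sided p, written out from the textbook formula.
brute_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# One-way ANOVA F from sums of squares, independent of stats::aov.
brute_anova_f <- function(groups) {
  all <- unlist(groups)
  grand <- mean(all)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 0) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1
  dfw <- length(all) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# A small deterministic random masked slice for oracle sweeps.
random_masked_slice <- function(seed, nr = 10L, nc = 10L) {
  set.seed(seed)
  lev <- matrix(sample(1:8, nr * nc, replace = TRUE), nr, nc)
  msk <- matrix(runif(nr * nc) < 0.7, nr, nc)
  lev[!msk] <- NA_integer_
  make_slice(lev, msk)
}

# --- cached expensive fixtures (built once per test run) -------------------

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_cohort <- function() {
  cached("cohort", function() generate_cohort(cohort_config(seed = 1)))
}

default_feature_matrix <- function() {
  cached("fm", function() {
    suppressWarnings(build_feature_matrix(default_cohort()))
  })
}

# A small but feature-rich lesion for per-lesion pipeline tests.
small_lesion <- function(label = "nch", seed = 11) {
  cached(paste0("lesion_", label, "_", seed), function() {
    cfg <- cohort_config(volume_shape = c(32L, 32L, 32L),
                         diameter_mean_sd_nch = c(14, 3),
                         diameter_mean_sd_aca = c(16, 3),
                         diameter_range_mm = c(8, 26), seed = 1)
    generate_nodule(cfg, label, seed = seed)
  })
}
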