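#' Orientations used for co-occurrence analysis
#'
#' Displacement vectors `(drow, dcol)` at unit distance for the four
#' standard orientations: 0 degrees `(0, 1)`, 45 `(-1, 1)`, 90 `(-1, 0)`,
#' 135 `(-1, -1)` (rows increase downward, so -1 is "up").
#'
#' @return Named list of integer length-2 vectors.
#' @export
glcm_orientations <- function() {
  list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L), `135` = c(-1L, -1L))
}

#' Gray-level co-occurrence matrix of a quantized slice
#'
#' Counts ordered pairs of gray levels separated by the orientation's unit
#' displacement, restricted to pairs whose two pixels both lie inside the
#' in-slice mask (background never contaminates the counts). The count
#' matrix is symmetrized (each pair contributes to `(i, j)` and `(j, i)`)
#' and normalized to sum 1.
#'
#' @param q A `quantized_slice` from [quantize_gray_levels()].
#' @param orientation One of `"0"`, `"45"`, `"90"`, `"135"` (degrees).
#' @return A `glcm` object: list with `p` (`n_levels` x `n_levels` matrix of
#'   pair probabilities), `orientation` and `pair_count` (number of
#'   contributing displaced pairs before symmetrization).
#' @export
compute_glcm <- function(q, orientation = c("0", "45", "90", "135")) {
  stopifnot(inherits(q, "quantized_slice"))
  orientation <- match.arg(as.character(orientation),
                           c("0", "45", "90", "135"))
  d <- glcm_orientations()[[orientation]]
  ng <- q$n_levels
  lev <- q$levels
  nr <- nrow(lev); nc <- ncol(lev)

  # rows/cols of the "from" pixel such that from + d stays in the box
  rlo <- max(1L, 1L - d[1]); rhi <- min(nr, nr - d[1])
  clo <- max(1L, 1L - d[2]); chi <- min(nc, nc - d[2])
  if (rlo > rhi || clo > chi) {
    stop("no valid pixel pairs at orientation ", orientation, " degrees")
  }
  r1 <- rlo:rhi
  c1 <- clo:chi
  a <- lev[r1, c1, drop = FALSE]
  b <- lev[r1 + d[1], c1 + d[2], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) {
    stop("no valid pixel pairs at orientation ", orientation, " degrees")
  }
  idx <- (a[ok] - 1L) * ng + b[ok]
  counts <- matrix(tabulate(idx, nbins = ng * ng), nrow = ng, byrow = TRUE)
  sym <- counts + t(counts)
  structure(
    list(p = sym / sum(sym), orientation = orientation,
         pair_count = sum(ok)),
    class = "glcm"
  )
}

#' @export
print.glcm <- function(x, ...) {
  cat("<glcm>", x$orientation, "degrees,", x$pair_count, "pairs\n")
  print(round(x$p, 3))
  invisible(x)
}

#' Names of the 20 co-occurrence (Haralick-family) features, in panel order
#' @return Character vector of length 20.
#' @export
glcm_feature_names <- function() {
  c("autocorrelation", "contrast", "correlation", "cluster_prominence",
    "cluster_shade", "dissimilarity", "energy", "entropy", "homogeneity",
    "maximum_probability", "sum_of_squares", "sum_average", "sum_variance",
    "sum_entropy", "difference_variance", "difference_entropy", "imc1",
    "imc2", "inverse_difference_normalized", "inverse_difference_moment_normalized")
}

# base-2 log with the 0 * log(0) = 0 convention
xlog2 <- function(p) ifelse(p > 0, log2(p), 0)

#' The 20 Haralick-family texture features of one co-occurrence matrix
#'
#' Standard formulas on the normalized symmetric matrix `p(i, j)`,
#' `i, j = 1..N`: marginals `px = py`, sum distribution `p_{x+y}` over
#' `k = 2..2N`, difference distribution `p_{x-y}` over `k = 0..N-1`.
#' Logarithms are base 2 with `0 log 0 = 0`. Sum variance is taken about the
#' sum average; the normalized inverse difference (moment) variants divide
#' `|i-j|` by `N` (`(i-j)^2` by `N^2`).
#'
#' @param g A `glcm` object or a normalized symmetric matrix.
#' @return Named numeric vector of the 20 features (see
#'   [glcm_feature_names()]).
#' @export
haralick_features <- function(g) {
  p <- if (inherits(g, "glcm")) g$p else as.matrix(g)
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)          # row index
  j <- t(i)                                 # col index
  px <- rowSums(p)
  py <- colSums(p)
  mux <- sum(seq_len(ng) * px)
  muy <- sum(seq_len(ng) * py)
  sigx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(ng) - muy)^2 * py))

  # sum / difference distributions
  psum <- vapply(2:(2 * ng), function(k) sum(p[i + j == k]), numeric(1))
  ksum <- 2:(2 * ng)
  pdiff <- vapply(0:(ng - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  kdiff <- 0:(ng - 1)

  autocorrelation <- sum(i * j * p)
  contrast <- sum((i - j)^2 * p)
  correlation <- if (sigx > 0 && sigy > 0) {
    (autocorrelation - mux * muy) / (sigx * sigy)
  } else 0
  cluster_prominence <- sum((i + j - mux - muy)^4 * p)
  cluster_shade <- sum((i + j - mux - muy)^3 * p)
  dissimilarity <- sum(abs(i - j) * p)
  energy <- sum(p^2)
  entropy <- -sum(p * xlog2(p))
  homogeneity <- sum(p / (1 + (i - j)^2))
  maximum_probability <- max(p)
  sum_of_squares <- sum((i - mux)^2 * p)
  sum_average <- sum(ksum * psum)
  sum_variance <- sum((ksum - sum_average)^2 * psum)
  sum_entropy <- -sum(psum * xlog2(psum))
  mu_diff <- sum(kdiff * pdiff)
  difference_variance <- sum((kdiff - mu_diff)^2 * pdiff)
  difference_entropy <- -sum(pdiff * xlog2(pdiff))

  hx <- -sum(px * xlog2(px))
  hy <- -sum(py * xlog2(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(p * xlog2(pxy))
  hxy2 <- -sum(pxy * xlog2(pxy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  inverse_difference_normalized <- sum(p / (1 + abs(i - j) / ng))
  inverse_difference_moment_normalized <- sum(p / (1 + (i - j)^2 / ng^2))

  out <- c(autocorrelation, contrast, correlation, cluster_prominence,
           cluster_shade, dissimilarity, energy, entropy, homogeneity,
           maximum_probability, sum_of_squares, sum_average, sum_variance,
           sum_entropy, difference_variance, difference_entropy, imc1, imc2,
           inverse_difference_normalized, inverse_difference_moment_normalized)
  stats::setNames(out, glcm_feature_names())
}

#' Average co-occurrence features over the four orientations
#'
#' Per-feature arithmetic mean of the four orientation-specific blocks,
#' giving the 20 orientation-pooled features used for group testing.
#'
#' @param blocks A list of exactly 4 named numeric vectors as returned by
#'   [haralick_features()], one per orientation.
#' @return Named numeric vector of 20 pooled features.
#' @export
pool_orientations <- function(blocks) {
  if (length(blocks) != 4L) {
    stop("orientation pooling needs exactly 4 feature blocks, got ",
         length(blocks))
  }
  nm <- glcm_feature_names()
  ok <- vapply(blocks, function(b) all(nm %in% names(b)), logical(1))
  if (!all(ok)) stop("feature block(s) missing named features: ",
                     paste(which(!ok), collapse = ", "))
  m <- do.call(rbind, lapply(blocks, function(b) b[nm]))
  colMeans(m)
}
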