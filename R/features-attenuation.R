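#' Mass feature: mean raw attenuation of the ROI
#'
#' Sum of the ROI's raw (pre-normalization) voxel Hounsfield values divided
#' by the number of voxels.
#'
#' @param roi ROI voxel list (data frame with a `value` column of HU).
#' @return A single number (HU).
#' @export
mass_feature <- function(roi) {
  stopifnot(is.data.frame(roi), "value" %in% names(roi))
  if (nrow(roi) == 0L) stop("cannot compute mass of an empty ROI")
  mean(roi$value)
}

#' Fit a logistic (sigmoid) curve to the attenuation distribution
#'
#' Fits `f(x) = f2 / (1 + exp(-(x - f3) / f4))` by Levenberg-Marquardt least
#' squares to the cumulative distribution of the normalized attenuation
#' values: `x` runs over the sorted values and the target is the midpoint
#' cumulative fraction `(i - 1/2) / n`. The three parameters summarize the
#' amplitude (`f2`), centre (`f3`) and spread (`f4`) of the lesion's
#' attenuation profile. A logistic CDF-shaped input is recovered exactly.
#'
#' For very large ROIs the curve is represented by 2000 evenly spaced order
#' statistics (a deterministic thinning that preserves the curve shape).
#'
#' @param roi A `normalized_roi` from [normalize_attenuation()].
#' @param tol Residual convergence tolerance (default 1e-8).
#' @param max_iter Maximum optimizer iterations (default 500).
#' @return A `sigmoid_fit` object with elements `f2`, `f3`, `f4`,
#'   `converged` (logical) and `rss`. Use [tidy()][generics::tidy] to get a
#'   parameter tibble.
#' @export
fit_sigmoid <- function(roi, tol = 1e-8, max_iter = 500L) {
  stopifnot(inherits(roi, "normalized_roi"))
  v <- sort(roi$voxels$value)
  if (length(unique(v)) < 4L) {
    stop("degenerate input: sigmoid fit needs at least 4 distinct ",
         "normalized values (constant or near-constant ROI)")
  }
  n <- length(v)
  frac <- (seq_len(n) - 0.5) / n
  if (n > 2000L) {
    keep <- unique(round(seq(1L, n, length.out = 2000L)))
    v <- v[keep]; frac <- frac[keep]
  }
  dat <- data.frame(x = v, y = frac)
  start <- list(f2 = 1, f3 = stats::median(v), f4 = max(stats::sd(v) / 2, 1e-3))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ f2 / (1 + exp(-(x - f3) / f4)),
      data = dat, start = start,
      control = minpack.lm::nls.lm.control(
        maxiter = as.integer(max_iter), ftol = tol, ptol = tol
      )
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warning("sigmoid fit did not converge; returning the starting parameters")
    return(structure(
      list(f2 = start$f2, f3 = start$f3, f4 = start$f4,
           converged = FALSE, rss = NA_real_),
      class = "sigmoid_fit"
    ))
  }
  cf <- stats::coef(fit)
  conv <- fit$convInfo$isConv %||% TRUE
  if (!isTRUE(conv)) warning("sigmoid fit flagged as not converged")
  structure(
    list(f2 = unname(cf["f2"]), f3 = unname(cf["f3"]), f4 = unname(cf["f4"]),
         converged = isTRUE(conv), rss = sum(stats::residuals(fit)^2)),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> f2 = %.4f, f3 = %.4f, f4 = %.4f (%s, rss %.3g)\n",
              x$f2, x$f3, x$f4,
              if (x$converged) "converged" else "NOT converged", x$rss))
  invisible(x)
}

#' Moments of the normalized attenuation distribution
#'
#' Mean, sample standard deviation (n - 1 denominator), skewness (third
#' standardized moment) and excess kurtosis (fourth standardized moment
#' minus 3) of the normalized voxel values. Skewness and kurtosis use
#' bias-uncorrected standardized moments and are defined as 0 for a
#' zero-variance ROI.
#'
#' @param roi A `normalized_roi`.
#' @return A named numeric vector `c(f5, f6, f7, f8)` =
#'   (mean, sd, skewness, excess kurtosis).
#' @export
attenuation_moments <- function(roi) {
  stopifnot(inherits(roi, "normalized_roi"))
  v <- roi$voxels$value
  m <- mean(v)
  s <- if (length(v) > 1L) stats::sd(v) else 0
  if (s == 0) {
    return(c(f5 = m, f6 = 0, f7 = 0, f8 = 0))
  }
  m2 <- mean((v - m)^2)
  skew <- mean((v - m)^3) / m2^1.5
  kurt <- mean((v - m)^4) / m2^2 - 3
  c(f5 = m, f6 = s, f7 = skew, f8 = kurt)
}

#' Full 3D attenuation feature block (f1-f8)
#'
#' @param roi Raw ROI voxel list (HU).
#' @param nroi Matching `normalized_roi`; computed from `roi` if missing.
#' @return Named numeric vector `f1`..`f8`.
#' @export
attenuation_features <- function(roi, nroi = NULL) {
  if (is.null(nroi)) nroi <- normalize_attenuation(roi)
  sig <- fit_sigmoid(nroi)
  mom <- attenuation_moments(nroi)
  c(f1 = mass_feature(roi), f2 = sig$f2, f3 = sig$f3, f4 = sig$f4, mom)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
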