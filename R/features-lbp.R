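#' Rotation-invariant uniform local binary pattern codes of a slice
#'
#' For every in-slice pixel whose full 8-neighborhood (radius 1) also lies
#' inside the mask, thresholds the 8 neighbors at the center's value
#' (neighbor >= center gives bit 1) and maps the 8-bit ring to the
#' rotation-invariant uniform ("riu2") alphabet: patterns with at most two
#' 0/1 transitions around the ring take their set-bit count (0..8), all
#' other patterns collapse to the non-uniform code 9. Codes are computed on
#' the continuous normalized attenuation, not on the quantized gray levels.
#'
#' @param q A `quantized_slice` (its `values` and `mask` components are
#'   used).
#' @return An `lbp_map` object: list with `codes` (integer matrix, `NA`
#'   where the neighborhood is incomplete) and `values` (vector of the
#'   defined codes).
#' @export
lbp_codes <- function(q) {
  stopifnot(inherits(q, "quantized_slice"))
  v <- q$values
  m <- q$mask
  nr <- nrow(v); nc <- ncol(v)
  codes <- matrix(NA_integer_, nr, nc)
  if (nr >= 3L && nc >= 3L) {
    # ring order: E, NE, N, NW, W, SW, S, SE (counter-clockwise)
    offs <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L),
                 c(0L, -1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
    rr <- 2L:(nr - 1L); cc <- 2L:(nc - 1L)
    centre <- v[rr, cc, drop = FALSE]
    eligible <- m[rr, cc, drop = FALSE]
    bits <- vector("list", 8L)
    for (k in seq_along(offs)) {
      o <- offs[[k]]
      nb <- v[rr + o[1], cc + o[2], drop = FALSE]
      eligible <- eligible & m[rr + o[1], cc + o[2], drop = FALSE]
      bits[[k]] <- nb >= centre
    }
    bmat <- vapply(bits, as.vector, logical(length(centre)))
    if (is.null(dim(bmat))) bmat <- matrix(bmat, nrow = 1L)
    trans <- rowSums(bmat != bmat[, c(2:8, 1), drop = FALSE])
    ones <- rowSums(bmat)
    code <- ifelse(trans <= 2L, ones, 9L)
    code[!as.vector(eligible)] <- NA_integer_
    codes[rr, cc] <- matrix(as.integer(code), length(rr), length(cc))
  }
  vals <- codes[!is.na(codes)]
  if (length(vals) == 0L) {
    stop("no pixel has a complete masked 8-neighborhood: ",
         "the lesion slice is too small for LBP analysis")
  }
  structure(list(codes = codes, values = as.integer(vals)), class = "lbp_map")
}

#' @export
print.lbp_map <- function(x, ...) {
  cat("<lbp_map>", length(x$values), "codes; histogram:\n")
  print(table(factor(x$values, levels = 0:9)))
  invisible(x)
}

#' The 6 local-binary-pattern features (f89-f94)
#'
#' Spatial moments of the code values — mean, sample standard deviation,
#' skewness, excess kurtosis (same conventions as
#' [attenuation_moments()]) — plus two histogram features on the normalized
#' code histogram `h`: the mean height of its occupied bins (`1/k` for `k`
#' occupied bins) and the Shannon entropy `-sum h log2 h` (bits).
#'
#' @param codes An `lbp_map` from [lbp_codes()].
#' @return Named numeric vector `c(f89, ..., f94)`.
#' @export
lbp_features <- function(codes) {
  stopifnot(inherits(codes, "lbp_map"))
  v <- as.numeric(codes$values)
  m <- mean(v)
  s <- if (length(v) > 1L) stats::sd(v) else 0
  if (s == 0) {
    skew <- 0; kurt <- 0
  } else {
    m2 <- mean((v - m)^2)
    skew <- mean((v - m)^3) / m2^1.5
    kurt <- mean((v - m)^4) / m2^2 - 3
  }
  h <- tabulate(codes$values + 1L, nbins = 10L) / length(v)
  occupied <- h[h > 0]
  c(f89 = m, f90 = s, f91 = skew, f92 = kurt,
    f93 = mean(occupied), f94 = -sum(occupied * log2(occupied)))
}
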