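#' Normalize ROI attenuation within mu +/- 3 sigma
#'
#' Rescales the Hounsfield values of an ROI voxel list to `[0, 1]` using the
#' lesion's own mean `mu` and sample standard deviation `sigma`:
#' `v -> clip((v - (mu - 3 sigma)) / (6 sigma), 0, 1)`. Normalizing each
#' lesion against its own attenuation distribution suppresses inter-scanner
#' offset and gain differences before texture analysis. A constant ROI
#' (`sigma = 0`) maps every voxel to 0.5 so degenerate phantoms remain
#' processable.
#'
#' @param roi An ROI voxel list as returned by [mask_to_voxel_list()]:
#'   a data frame with columns `x`, `y`, `z`, `value`.
#' @param id Optional lesion identifier carried through for auditability.
#' @return A `normalized_roi` object: list with `voxels` (tibble `x`, `y`,
#'   `z`, `value` where `value` is the unitless normalized attenuation),
#'   `mu`, `sigma` (the recorded normalization parameters, HU) and `id`.
#' @export
normalize_attenuation <- function(roi, id = NULL) {
  stopifnot(is.data.frame(roi), all(c("x", "y", "z", "value") %in% names(roi)))
  if (nrow(roi) == 0L) stop("cannot normalize an empty ROI")
  mu <- mean(roi$value)
  sigma <- if (nrow(roi) > 1L) stats::sd(roi$value) else 0
  v <- if (sigma == 0) {
    rep(0.5, nrow(roi))
  } else {
    pmin(pmax((roi$value - (mu - 3 * sigma)) / (6 * sigma), 0), 1)
  }
  structure(
    list(
      voxels = tibble::tibble(x = roi$x, y = roi$y, z = roi$z, value = v),
      mu = mu, sigma = sigma, id = id
    ),
    class = "normalized_roi"
  )
}

#' @export
print.normalized_roi <- function(x, ...) {
  cat("<normalized_roi>", nrow(x$voxels), "voxels;",
      sprintf("mu = %.2f HU, sigma = %.2f HU", x$mu, x$sigma),
      if (!is.null(x$id)) paste0("[", x$id, "]") else "", "\n")
  invisible(x)
}

#' Index of the maximum-area axial slice
#'
#' The 2D texture features (GLCM, LBP) are computed on the axial slice with
#' the most ROI pixels. Ties break to the smallest slice index.
#'
#' @param mask A `roi_mask` or 3D array.
#' @return The 0-based index of the maximum-area slice.
#' @export
select_max_area_slice <- function(mask) {
  m <- as_volume_array(mask)
  counts <- apply(m != 0, 3, sum)
  if (sum(counts) == 0L) stop("mask is empty: no slice to select")
  as.integer(which.max(counts) - 1L)
}

#' Quantize the normalized attenuation of one slice to 8 gray levels
#'
#' Extracts the in-slice portion of a normalized ROI on its bounding box and
#' decimates the normalized values to 8 equal-width gray levels on `[0, 1]`:
#' `level = 1 + floor(8 v)`, with `v = 1` assigned to level 8 (top edge
#' inclusive). The continuous normalized values are retained alongside the
#' levels because local binary patterns are computed on them directly.
#'
#' @param roi A `normalized_roi` from [normalize_attenuation()].
#' @param slice_index 0-based axial slice index, typically from
#'   [select_max_area_slice()].
#' @param n_levels Number of gray levels (default 8).
#' @return A `quantized_slice` object: list with matrices `levels` (integer
#'   gray levels, `NA` outside the mask), `values` (normalized attenuation,
#'   `NA` outside), `mask` (logical), plus `slice_index`, `n_levels` and the
#'   bounding-box `offset` (0-based `x`, `y` of the box origin).
#' @export
quantize_gray_levels <- function(roi, slice_index, n_levels = 8L) {
  stopifnot(inherits(roi, "normalized_roi"))
  vox <- roi$voxels[roi$voxels$z == slice_index, , drop = FALSE]
  if (nrow(vox) == 0L) stop("slice ", slice_index, " contains no masked voxels")
  x0 <- min(vox$x); y0 <- min(vox$y)
  nc <- max(vox$x) - x0 + 1L  # columns  (x)
  nr <- max(vox$y) - y0 + 1L  # rows     (y)
  values <- matrix(NA_real_, nrow = nr, ncol = nc)
  inmask <- matrix(FALSE, nrow = nr, ncol = nc)
  ij <- cbind(vox$y - y0 + 1L, vox$x - x0 + 1L)  # (row, col)
  values[ij] <- vox$value
  inmask[ij] <- TRUE
  levels <- matrix(NA_integer_, nrow = nr, ncol = nc)
  levels[ij] <- pmin(1L + as.integer(floor(vox$value * n_levels)), n_levels)
  structure(
    list(levels = levels, values = values, mask = inmask,
         slice_index = as.integer(slice_index), n_levels = as.integer(n_levels),
         offset = c(x = x0, y = y0)),
    class = "quantized_slice"
  )
}

#' @export
print.quantized_slice <- function(x, ...) {
  cat("<quantized_slice> slice", x$slice_index, "-",
      sum(x$mask), "masked pixels in a",
      nrow(x$levels), "x", ncol(x$levels), "box,",
      x$n_levels, "gray levels\n")
  invisible(x)
}
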