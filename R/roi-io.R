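#' Read a CT volume from a NIfTI file
#'
#' Loads a 3D volume of Hounsfield-unit attenuation values together with its
#' voxel dimensions. The array is indexed `[x, y, z]` with `x` the in-slice
#' column, `y` the in-slice row and `z` the axial slice, matching the 0-based
#' coordinate convention used by [mask_to_voxel_list()].
#'
#' @param path Path to a NIfTI (`.nii` / `.nii.gz`) file.
#' @return A `ct_volume` object: a list with elements `data` (3D numeric
#'   array), `voxel_size_mm` (length-3 numeric) and `axis_order` (`"xyz"`).
#' @seealso [read_mask()], [mask_to_voxel_list()]
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) != 3L) {
    stop("expected a 3D volume, got ", length(dim(data)), " dimensions: ", path)
  }
  if (!all(is.finite(data))) stop("volume contains non-finite values: ", path)
  new_ct_volume(data, voxel_size_mm = RNifti::pixdim(img)[1:3])
}

new_ct_volume <- function(data, voxel_size_mm = c(1, 1, 1)) {
  structure(
    list(data = data, voxel_size_mm = as.numeric(voxel_size_mm), axis_order = "xyz"),
    class = "ct_volume"
  )
}

#' Read a binary region-of-interest mask from a NIfTI file
#'
#' Any nonzero voxel is treated as inside the ROI.
#'
#' @inheritParams read_volume
#' @return A `roi_mask` object: list with `data` (3D array of 0/1) and
#'   `voxel_size_mm`.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) != 3L) {
    stop("expected a 3D mask, got ", length(dim(data)), " dimensions: ", path)
  }
  new_roi_mask(data, voxel_size_mm = RNifti::pixdim(img)[1:3])
}

new_roi_mask <- function(data, voxel_size_mm = c(1, 1, 1)) {
  structure(
    list(data = array(as.numeric(data != 0), dim = dim(data)),
         voxel_size_mm = as.numeric(voxel_size_mm)),
    class = "roi_mask"
  )
}

# Accept a ct_volume/roi_mask object or a bare 3D array in any mask/volume slot.
as_volume_array <- function(x) {
  if (inherits(x, "ct_volume") || inherits(x, "roi_mask")) x$data else x
}

check_same_shape <- function(volume, mask) {
  dv <- dim(as_volume_array(volume))
  dm <- dim(as_volume_array(mask))
  if (!identical(dv, dm)) {
    stop("volume shape (", paste(dv, collapse = "x"),
         ") does not match mask shape (", paste(dm, collapse = "x"), ")")
  }
  invisible(TRUE)
}

#' Convert a masked volume to an ROI voxel list
#'
#' Flattens the masked voxels of a volume into one record per voxel, the
#' tabular "ROI list" representation used by all downstream feature
#' extraction: 0-based `x` (column), `y` (row), `z` (slice) indices plus the
#' Hounsfield attenuation `value`. Records are ordered by `z`, then `y`,
#' then `x`, ascending.
#'
#' @param volume A `ct_volume` or 3D numeric array of HU values.
#' @param mask A `roi_mask` or 3D array; nonzero means inside the ROI.
#' @return A tibble with columns `x`, `y`, `z` (0-based integers) and
#'   `value` (HU).
#' @examples
#' vol <- array(rnorm(64), c(4, 4, 4))
#' msk <- array(0, c(4, 4, 4))
#' msk[2, 3, 4] <- 1
#' mask_to_voxel_list(vol, msk) # one record: x = 1, y = 2, z = 3
#' @export
mask_to_voxel_list <- function(volume, mask) {
  check_same_shape(volume, mask)
  v <- as_volume_array(volume)
  m <- as_volume_array(mask)
  idx <- which(m != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty: no voxels to list")
  out <- tibble::tibble(
    x = as.integer(idx[, 1] - 1L),
    y = as.integer(idx[, 2] - 1L),
    z = as.integer(idx[, 3] - 1L),
    value = v[idx]
  )
  dplyr::arrange(out, .data$z, .data$y, .data$x)
}

#' Dice similarity coefficient between two segmentation masks
#'
#' Computes `2|A intersect B| / (|A| + |B|)`, the standard overlap agreement
#' between two binary segmentations of the same volume. Values above 0.7 are
#' conventionally read as excellent inter-observer agreement.
#'
#' @param a,b `roi_mask` objects or 3D arrays of identical shape.
#' @return A single number in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  check_same_shape(a, b)
  ma <- as_volume_array(a) != 0
  mb <- as_volume_array(b) != 0
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0L) stop("Dice coefficient undefined: both masks are empty")
  2 * sum(ma & mb) / (na + nb)
}

#' Summarize Dice agreement across a cohort of paired segmentations
#'
#' Per-lesion Dice coefficients with the conventional `> 0.7` excellent-
#' agreement flag, plus the cohort mean and standard deviation as attributes.
#'
#' @param masks_a,masks_b Lists of masks (same length, paired by position).
#' @param ids Optional character ids; defaults to positions.
#' @return A tibble with columns `id`, `dice`, `excellent` and attributes
#'   `mean_dice`, `sd_dice`.
#' @export
dice_agreement <- function(masks_a, masks_b, ids = NULL) {
  stopifnot(length(masks_a) == length(masks_b))
  if (is.null(ids)) ids <- sprintf("lesion_%03d", seq_along(masks_a))
  d <- purrr::map2_dbl(masks_a, masks_b, dice_coefficient)
  out <- tibble::tibble(id = ids, dice = d, excellent = d > 0.7)
  attr(out, "mean_dice") <- mean(d)
  attr(out, "sd_dice") <- stats::sd(d)
  out
}
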