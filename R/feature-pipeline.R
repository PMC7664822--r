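#' The frozen 94-feature panel dictionary
#'
#' The column ordering of the feature panel is a fixed contract:
#' f1 mass; f2-f4 sigmoid parameters; f5-f8 attenuation moments; f9-f28
#' co-occurrence features at 0 degrees; f29-f48 at 45; f49-f68 at 90;
#' f69-f88 at 135; f89-f94 local binary patterns.
#'
#' @return A tibble with columns `feature` (`"f1"`..`"f94"`), `block`
#'   (`attenuation`, `glcm_0`, `glcm_45`, `glcm_90`, `glcm_135`, `lbp`) and
#'   `name` (descriptive feature name).
#' @export
feature_dictionary <- function() {
  atten <- c("mass", "sigmoid_amplitude", "sigmoid_location", "sigmoid_scale",
             "mean", "sd", "skewness", "kurtosis")
  lbp <- c("lbp_mean", "lbp_sd", "lbp_skewness", "lbp_kurtosis",
           "lbp_histogram_mean", "lbp_entropy")
  tibble::tibble(
    feature = paste0("f", 1:94),
    block = c(rep("attenuation", 8),
              rep(paste0("glcm_", c(0, 45, 90, 135)), each = 20),
              rep("lbp", 6)),
    name = c(atten,
             paste0(rep(glcm_feature_names(), 4), "_",
                    rep(c(0, 45, 90, 135), each = 20)),
             lbp)
  )
}

#' Columns of the panel belonging to each feature set
#'
#' @param set One of `"attenuation"` (f1-f8), `"glcm"` (f9-f88), `"lbp"`
#'   (f89-f94) or `"all"`.
#' @return Character vector of feature column names.
#' @export
feature_set_columns <- function(set = c("all", "attenuation", "glcm", "lbp")) {
  set <- match.arg(set)
  switch(set,
    attenuation = paste0("f", 1:8),
    glcm = paste0("f", 9:88),
    lbp = paste0("f", 89:94),
    all = paste0("f", 1:94)
  )
}

#' Extract the full 94-feature vector of one lesion
#'
#' Runs the whole per-lesion pipeline: ROI list conversion, mu +/- 3 sigma
#' attenuation normalization, maximum-area slice selection, 8-level gray
#' quantization, co-occurrence matrices on four orientations, local binary
#' patterns, and the 3D attenuation block. Deterministic for a given
#' volume/mask pair.
#'
#' @param volume A `ct_volume` or 3D HU array.
#' @param mask Matching `roi_mask` or 3D array.
#' @param id Optional lesion id attached to error messages and metadata.
#' @return A 1-row tibble with columns `f1`..`f94`, plus attribute
#'   `metadata` (list: normalization `mu`/`sigma`, `slice_index`, pair
#'   counts, convention tags).
#' @export
extract_feature_vector <- function(volume, mask, id = NULL) {
  who <- if (is.null(id)) "" else paste0(" [", id, "]")
  res <- tryCatch({
    roi <- mask_to_voxel_list(volume, mask)
    nroi <- normalize_attenuation(roi, id = id)
    zmax <- select_max_area_slice(mask)
    q <- quantize_gray_levels(nroi, zmax)
    glcms <- lapply(names(glcm_orientations()), function(o) compute_glcm(q, o))
    blocks <- lapply(glcms, haralick_features)
    glcm_vals <- unlist(blocks, use.names = FALSE)
    lbp <- lbp_features(lbp_codes(q))
    att <- attenuation_features(roi, nroi)
    vec <- c(unname(att), glcm_vals, unname(lbp))
    list(
      vec = vec,
      meta = list(
        id = id, mu = nroi$mu, sigma = nroi$sigma, slice_index = zmax,
        pair_counts = stats::setNames(
          vapply(glcms, function(g) g$pair_count, numeric(1)),
          names(glcm_orientations())
        ),
        conventions = list(
          gray_levels = 8L, glcm_distance = 1L, glcm_symmetric = TRUE,
          log_base = 2, lbp_variant = "riu2_r1_p8",
          sd = "sample (n-1)", kurtosis = "excess",
          sigmoid_target = "midpoint empirical CDF"
        )
      )
    )
  }, error = function(e) {
    stop("feature extraction failed", who, ": ", conditionMessage(e),
         call. = FALSE)
  })
  out <- tibble::as_tibble(as.list(stats::setNames(res$vec, paste0("f", 1:94))))
  attr(out, "metadata") <- res$meta
  out
}

#' Build the cohort feature matrix
#'
#' Extracts the 94-feature panel for every lesion and assembles the
#' lesion-by-feature table with the class target on the last column
#' (0 = adenocarcinoma, 1 = non-calcified hamartoma).
#'
#' @param cohort A `synthetic_cohort`, or a named list of lesions each with
#'   `volume` and `mask` elements.
#' @param labels A data frame with columns `id` and `label`
#'   (`"nch"`/`"aca"`); taken from the cohort if omitted.
#' @param progress Emit one message per lesion to stderr.
#' @return A `feature_matrix` tibble: `lesion_id`, `f1`..`f94`, `target`.
#' @export
build_feature_matrix <- function(cohort, labels = NULL, progress = FALSE) {
  lesions <- if (inherits(cohort, "synthetic_cohort")) cohort$lesions else cohort
  if (is.null(labels) && inherits(cohort, "synthetic_cohort")) {
    labels <- cohort$labels
  }
  stopifnot(is.data.frame(labels), all(c("id", "label") %in% names(labels)))
  if (!all(labels$label %in% c("nch", "aca"))) {
    stop("unknown label value(s): ",
         paste(setdiff(unique(labels$label), c("nch", "aca")), collapse = ", "))
  }
  rows <- purrr::imap(lesions, function(les, id) {
    if (progress) message("extracting ", id)
    extract_feature_vector(les$volume, les$mask, id = id)
  })
  feat <- dplyr::bind_rows(rows)
  out <- dplyr::bind_cols(
    tibble::tibble(lesion_id = labels$id),
    feat,
    tibble::tibble(target = as.integer(labels$label == "nch"))
  )
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Min-max normalize feature columns to [0, 1]
#'
#' The column-wise linear rescaling used for visualization and export of the
#' patterns-features matrix; a constant column maps to 0.5. Model evaluation
#' does not use this (scaling there is re-estimated inside each
#' cross-validation fold from training rows only).
#'
#' @param m A feature matrix from [build_feature_matrix()].
#' @param cols Columns to rescale (default all `f*` columns).
#' @return The matrix with rescaled feature columns.
#' @export
normalize_feature_columns <- function(m, cols = NULL) {
  if (is.null(cols)) cols <- grep("^f[0-9]+$", names(m), value = TRUE)
  dplyr::mutate(m, dplyr::across(
    dplyr::all_of(cols),
    function(v) {
      r <- range(v)
      if (r[1] == r[2]) rep(0.5, length(v)) else (v - r[1]) / (r[2] - r[1])
    }
  ))
}

#' Orientation-pooled co-occurrence features of a feature matrix
#'
#' Averages each of the 20 co-occurrence features over its four orientation
#' columns, yielding the pooled 20-feature table used for group testing.
#'
#' @param m A feature matrix with columns `f9`..`f88`.
#' @return A tibble with `lesion_id`, the 20 pooled features (named
#'   `pooled_<feature>`), and `target` if present.
#' @export
pooled_glcm_matrix <- function(m) {
  nm <- glcm_feature_names()
  pooled <- purrr::map_dfc(seq_along(nm), function(k) {
    cols <- paste0("f", 8 + k + c(0, 20, 40, 60))
    tibble::tibble(!!paste0("pooled_", nm[k]) :=
                     rowMeans(as.matrix(m[, cols])))
  })
  out <- dplyr::bind_cols(tibble::tibble(lesion_id = m$lesion_id), pooled)
  if ("target" %in% names(m)) out$target <- m$target
  out
}
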