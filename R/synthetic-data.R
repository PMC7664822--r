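#' Configuration for the synthetic two-class nodule cohort
#'
#' Defines the study conditions emulated by the phantom generator: a cohort
#' of solid, non-calcified lesions of two classes with distinct intra-lesion
#' texture. Non-calcified hamartomas (NCH) are modelled as multi-component
#' lesions (soft tissue, fat-like and cartilage-like pockets) with a
#' short-range correlated attenuation field, i.e. heterogeneous; lung
#' adenocarcinomas (ACA) as single-component lesions with a longer-range,
#' smoother field. Defaults follow the reported cohort: 42 NCH vs 49 ACA,
#' largest diameters 14.3 +/- 6.0 mm vs 22.6 +/- 7.4 mm (truncated to
#' 6-41 mm), and no voxel at or above the 120 HU calcification bound.
#'
#' @param n_class_nch,n_class_aca Lesions per class.
#' @param volume_shape Voxels per axis (length 3).
#' @param voxel_size_mm Voxel edge lengths in mm (length 3).
#' @param diameter_mean_sd_nch,diameter_mean_sd_aca Mean and sd (mm) of the
#'   largest-diameter distribution per class.
#' @param diameter_range_mm Truncation bounds for diameter draws (mm).
#' @param background_hu Mean and sd of the lung-parenchyma background (HU).
#' @param nch_component_hus Mean HU of the NCH tissue components
#'   (default soft tissue 40, fat-admixed -40, cartilage-like 80).
#' @param aca_hu Mean HU of the adenocarcinoma interior.
#' @param nch_correlation_length_mm,aca_correlation_length_mm Correlation
#'   length of the intra-lesion Gaussian texture field per class; the NCH
#'   length must be strictly smaller (finer, more heterogeneous texture).
#' @param texture_sd_hu Standard deviation of the correlated texture field (HU).
#' @param noise_sd_hu Standard deviation of additive white voxel noise (HU).
#' @param hu_ceiling Calcification exclusion bound: every masked voxel is
#'   kept strictly below this attenuation (default 120 HU).
#' @param seed Cohort seed; per-lesion seeds are derived from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_class_nch = 42L,
                          n_class_aca = 49L,
                          volume_shape = c(48L, 48L, 48L),
                          voxel_size_mm = c(1, 1, 1),
                          diameter_mean_sd_nch = c(14.3, 6.0),
                          diameter_mean_sd_aca = c(22.6, 7.4),
                          diameter_range_mm = c(6, 41),
                          background_hu = c(-800, 30),
                          nch_component_hus = c(40, -40, 80),
                          aca_hu = 30,
                          nch_correlation_length_mm = 1.0,
                          aca_correlation_length_mm = 4,
                          texture_sd_hu = 55,
                          noise_sd_hu = 10,
                          hu_ceiling = 120,
                          seed = 1L) {
  cfg <- list(
    n_class_nch = as.integer(n_class_nch),
    n_class_aca = as.integer(n_class_aca),
    volume_shape = as.integer(volume_shape),
    voxel_size_mm = as.numeric(voxel_size_mm),
    diameter_mean_sd_nch = as.numeric(diameter_mean_sd_nch),
    diameter_mean_sd_aca = as.numeric(diameter_mean_sd_aca),
    diameter_range_mm = as.numeric(diameter_range_mm),
    background_hu = as.numeric(background_hu),
    nch_component_hus = as.numeric(nch_component_hus),
    aca_hu = as.numeric(aca_hu),
    nch_correlation_length_mm = as.numeric(nch_correlation_length_mm),
    aca_correlation_length_mm = as.numeric(aca_correlation_length_mm),
    texture_sd_hu = as.numeric(texture_sd_hu),
    noise_sd_hu = as.numeric(noise_sd_hu),
    hu_ceiling = as.numeric(hu_ceiling),
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_class_nch < 1L || cfg$n_class_aca < 1L) {
    stop("class sizes must be >= 1")
  }
  if (any(cfg$diameter_mean_sd_nch <= 0) || any(cfg$diameter_mean_sd_aca <= 0)) {
    stop("diameter mean and sd must be strictly positive")
  }
  if (!(cfg$nch_correlation_length_mm < cfg$aca_correlation_length_mm)) {
    stop("heterogeneity ordering violated: nch_correlation_length_mm must be ",
         "strictly smaller than aca_correlation_length_mm")
  }
  if (length(cfg$volume_shape) != 3L || any(cfg$volume_shape < 8L)) {
    stop("volume_shape must give 3 axes of at least 8 voxels")
  }
  if (length(cfg$nch_component_hus) < 2L) {
    stop("NCH lesions need at least 2 tissue components")
  }
  invisible(cfg)
}

# Deterministic per-lesion seed from the cohort seed and lesion index,
# kept inside the 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}

# Zero-mean, unit-sd Gaussian random field with Gaussian autocorrelation,
# built by circular FFT convolution of white noise with a Gaussian kernel.
gaussian_random_field <- function(shape, sigma_vox) {
  noise <- array(stats::rnorm(prod(shape)), dim = shape)
  if (sigma_vox <= 0) return(noise)
  kern1 <- function(n, s) {
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))  # wrapped distances
    k <- exp(-d^2 / (2 * s^2))
    k / sum(k)
  }
  kx <- kern1(shape[1], sigma_vox)
  ky <- kern1(shape[2], sigma_vox)
  kz <- kern1(shape[3], sigma_vox)
  kernel <- outer(outer(kx, ky), kz)
  dim(kernel) <- shape
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(kernel), inverse = TRUE)) /
    prod(shape)
  s <- stats::sd(sm)
  if (s == 0) sm else sm / s
}

#' Generate one synthetic lesion phantom
#'
#' Draws a largest diameter from the class's truncated normal distribution,
#' places an approximately ellipsoidal mask at the volume centre, and fills
#' it with class-specific attenuation: a correlated Gaussian texture field
#' (short correlation length for NCH, long for ACA) plus, for NCH only, a
#' random Voronoi partition of the mask into tissue components with distinct
#' mean HU, emulating the mixed fibrous/cartilage/fat composition that makes
#' hamartomas locally heterogeneous. White voxel noise is added everywhere
#' and all masked voxels are clipped strictly below the calcification bound.
#'
#' @param cfg A [cohort_config()].
#' @param label `"nch"` or `"aca"`.
#' @param seed Integer seed; the lesion is a deterministic function of
#'   `(cfg, label, seed)`.
#' @return A `synthetic_lesion`: list with `volume` (3D HU array), `mask`
#'   (3D 0/1 array), `label`, `true_diameter_mm` and `seed`.
#' @export
generate_nodule <- function(cfg, label = c("nch", "aca"), seed = 1L) {
  validate_cohort_config(cfg)
  label <- match.arg(label)
  shape <- cfg$volume_shape
  vs <- cfg$voxel_size_mm

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  dm <- if (label == "nch") cfg$diameter_mean_sd_nch else cfg$diameter_mean_sd_aca
  d <- draw_truncated_diameter(dm[1], dm[2], cfg$diameter_range_mm)
  if (any(d >= shape * vs)) {
    stop("drawn diameter ", round(d, 1), " mm exceeds the volume extent (",
         paste(shape * vs, collapse = "x"), " mm)")
  }

  # Ellipsoid: longest semi-axis d/2, the two others shrunk by random factors.
  semi <- (d / 2) * c(1, stats::runif(2, 0.7, 1))
  centre <- (shape + 1) / 2
  ax <- (seq_len(shape[1]) - centre[1]) * vs[1]
  ay <- (seq_len(shape[2]) - centre[2]) * vs[2]
  az <- (seq_len(shape[3]) - centre[3]) * vs[3]
  r2 <- outer(outer((ax / semi[1])^2, (ay / semi[2])^2, `+`), (az / semi[3])^2, `+`)
  mask <- array(as.numeric(r2 <= 1), dim = shape)
  inside <- which(mask != 0)

  corr_mm <- if (label == "nch") cfg$nch_correlation_length_mm else cfg$aca_correlation_length_mm
  field <- gaussian_random_field(shape, corr_mm / mean(vs))

  base <- array(cfg$background_hu[1], dim = shape)
  if (label == "nch") {
    base[inside] <- voronoi_components(inside, shape, vs, cfg$nch_component_hus)
  } else {
    base[inside] <- cfg$aca_hu
  }

  vol <- base + cfg$texture_sd_hu * field +
    array(stats::rnorm(prod(shape), sd = cfg$noise_sd_hu), dim = shape)
  # background keeps only white noise around its own mean
  outside <- which(mask == 0)
  vol[outside] <- cfg$background_hu[1] +
    stats::rnorm(length(outside), sd = cfg$background_hu[2])
  vol[inside] <- pmin(vol[inside], cfg$hu_ceiling - 1)

  structure(
    list(volume = vol, mask = mask, label = label,
         true_diameter_mm = d, seed = as.integer(seed),
         voxel_size_mm = vs),
    class = "synthetic_lesion"
  )
}

draw_truncated_diameter <- function(mean, sd, range, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    d <- stats::rnorm(1, mean, sd)
    if (d >= range[1] && d <= range[2]) return(d)
  }
  stop("failed to draw a diameter inside [", range[1], ", ", range[2], "] mm")
}

# Random Voronoi partition of the masked voxels into tissue components:
# k seed points drawn inside the mask, each voxel takes the mean HU of its
# nearest seed; component means cycle through `hus`.
voronoi_components <- function(inside, shape, vs, hus) {
  coords <- arrayInd(inside, shape)
  k <- sample(3:6, 1)
  seeds <- coords[sample(nrow(coords), min(k, nrow(coords))), , drop = FALSE]
  pts <- sweep(coords, 2, vs, `*`)
  spts <- sweep(seeds, 2, vs, `*`)
  d2 <- outer(rowSums(pts^2), rep(1, nrow(spts))) -
    2 * pts %*% t(spts) + outer(rep(1, nrow(pts)), rowSums(spts^2))
  nearest <- max.col(-d2, ties.method = "first")
  comp_hu <- hus[((seq_len(nrow(spts)) - 1L) %% length(hus)) + 1L]
  comp_hu[nearest]
}

#' @export
print.synthetic_lesion <- function(x, ...) {
  cat("<synthetic_lesion>", x$label, "-",
      sprintf("%.1f mm, %d voxels, HU range [%.0f, %.0f]",
              x$true_diameter_mm, sum(x$mask != 0),
              min(x$volume[x$mask != 0]), max(x$volume[x$mask != 0])), "\n")
  invisible(x)
}

#' Generate a labeled synthetic cohort
#'
#' Draws `n_class_nch` NCH and `n_class_aca` ACA lesions with per-lesion
#' seeds derived deterministically from the cohort seed, and optionally
#' writes each volume/mask pair as NIfTI plus a `labels.csv` table.
#'
#' @param cfg A [cohort_config()].
#' @param dir Optional output directory; when given, writes
#'   `<id>_volume.nii.gz`, `<id>_mask.nii.gz` per lesion and `labels.csv`
#'   (columns `id`, `label`, `diameter_mm`).
#' @return A `synthetic_cohort`: list with `lesions` (list of
#'   [generate_nodule()] results) and `labels` (tibble `id`, `label`,
#'   `diameter_mm`).
#' @export
generate_cohort <- function(cfg, dir = NULL) {
  validate_cohort_config(cfg)
  labels <- c(rep("nch", cfg$n_class_nch), rep("aca", cfg$n_class_aca))
  ids <- sprintf("lesion_%03d", seq_along(labels))
  lesions <- purrr::map(seq_along(labels), function(i) {
    generate_nodule(cfg, labels[i], seed = derive_seed(cfg$seed, i))
  })
  tab <- tibble::tibble(
    id = ids, label = labels,
    diameter_mm = purrr::map_dbl(lesions, "true_diameter_mm")
  )
  cohort <- structure(list(lesions = stats::setNames(lesions, ids), labels = tab),
                      class = "synthetic_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' Write a synthetic cohort to disk
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  purrr::iwalk(cohort$lesions, function(les, id) {
    vs <- les$voxel_size_mm
    vol <- RNifti::asNifti(les$volume, pixdim = vs)
    msk <- RNifti::asNifti(les$mask, pixdim = vs)
    RNifti::writeNifti(vol, file.path(dir, paste0(id, "_volume.nii.gz")))
    RNifti::writeNifti(msk, file.path(dir, paste0(id, "_mask.nii.gz")))
  })
  utils::write.csv(cohort$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$labels), "lesions:",
      sum(x$labels$label == "nch"), "nch /",
      sum(x$labels$label == "aca"), "aca\n")
  invisible(x)
}

# Save/restore the caller's RNG state so seeded generation is side-effect free.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
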