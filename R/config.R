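#' Optical model of the imaging setup
#'
#' Bundles the physical parameters that link pixels on a 2D section image to
#' micrometers in the tissue block: lateral pixel size, axial depth of field
#' of the optical plane, and the sectioning gap along the anterior-posterior
#' axis. Intensity conventions for rendering phantoms (background brighter
#' than nuclei, as in autofluorescence imaging) live here as well.
#'
#' @param pixel_size Lateral pixel size in micrometers per pixel.
#' @param depth_of_field Axial depth of field `d` in micrometers: the extent
#'   of tissue above/below the optical plane that contributes signal. Enters
#'   the slab model as slab thickness `2R + d`.
#' @param section_gap Spacing between consecutive coronal sections, in
#'   micrometers.
#' @param background_level Background (neuropil autofluorescence) intensity
#'   on the 0--255 scale used for phantom rendering.
#' @param nucleus_level Intensity of nucleus interiors; must be darker
#'   (smaller) than `background_level`.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise used
#'   when rendering phantom sections.
#'
#' @return An object of class `optical_model`.
#' @export
optical_model <- function(pixel_size = 0.35, depth_of_field = 1.5,
                          section_gap = 100, background_level = 120,
                          nucleus_level = 40, noise_sd = 5) {
  stopifnot(pixel_size > 0, depth_of_field >= 0, section_gap > 0,
            noise_sd >= 0)
  if (!(nucleus_level < background_level))
    stop("nucleus_level must be darker (smaller) than background_level")
  structure(list(pixel_size = pixel_size, depth_of_field = depth_of_field,
                 section_gap = section_gap,
                 background_level = background_level,
                 nucleus_level = nucleus_level, noise_sd = noise_sd),
            class = "optical_model")
}

#' Tiling configuration for section images
#'
#' Sections are processed as overlapping square tiles; the stride between
#' tile origins is `tile_px - 2 * overlap_px`, so each interior seam is
#' covered twice and objects cut at a tile border are seen whole by the
#' neighbouring tile.
#'
#' @param tile_px Tile side length in pixels.
#' @param overlap_px Overlap on each side of a tile, in pixels.
#' @return An object of class `tile_config`.
#' @export
tile_config <- function(tile_px = 312L, overlap_px = 20L) {
  tile_px <- as.integer(tile_px); overlap_px <- as.integer(overlap_px)
  stopifnot(overlap_px >= 0, tile_px > 2L * overlap_px)
  structure(list(tile_px = tile_px, overlap_px = overlap_px),
            class = "tile_config")
}

#' Coverage / dense-sparse split configuration
#'
#' @param window_px Side of the square window (even, >= 2) centred on a cell
#'   centroid in which cell-mask pixels are counted ("coverage").
#' @param k Number of clusters for the dense/sparse split (fixed at 2).
#' @param min_subregion_area Connected components of a subregion mask smaller
#'   than this (in pixels) are discarded as spurious.
#' @param closing_radius Radius (pixels) of the disc structuring element used
#'   for morphological closing when drawing subregion outlines.
#' @return An object of class `coverage_config`.
#' @export
coverage_config <- function(window_px = 64L, k = 2L,
                            min_subregion_area = 500L, closing_radius = 3L) {
  window_px <- as.integer(window_px)
  stopifnot(window_px >= 2L, window_px %% 2L == 0L, k == 2L,
            min_subregion_area >= 0L, closing_radius >= 1L)
  structure(list(window_px = window_px, k = 2L,
                 min_subregion_area = as.integer(min_subregion_area),
                 closing_radius = as.integer(closing_radius)),
            class = "coverage_config")
}

#' Quality-control thresholds for brains and regions
#'
#' Defaults implement the exclusion rules of the analysis: dark brains
#' (median gray-matter brightness below 25/255), brains with more than three
#' regions whose cell count is a one-sided robust outlier (beyond
#' median + 3 robust SDs, robust SD = MAD * 1.4826), regions with small
#' median volume (< 0.3 mm^3) or low median cell count (< 500), regions with
#' a mean left/right count imbalance above 15.5% of the regional total, and
#' regions whose counts correlate with image brightness (Pearson r > 0.3).
#'
#' @param brightness_min Minimum median gray-matter brightness (0--255).
#' @param outlier_z Number of robust SDs above the median defining a count
#'   outlier.
#' @param mad_scale MAD-to-SD consistency factor under normality.
#' @param max_outlier_regions A brain is discarded when it has strictly more
#'   than this many outlier regions.
#' @param min_region_median_volume Minimum median volume across brains, mm^3.
#' @param min_region_median_count Minimum median cell count (see
#'   `count_rule`).
#' @param count_rule `"section_median"` applies the count threshold to the
#'   median per-section detected count of the region (pooled over sections
#'   and brains); `"total"` applies it to the median per-brain total count.
#' @param max_lr_diff_frac Maximum mean per-brain fractional left/right count
#'   difference `|N_L - N_R| / (N_L + N_R)`.
#' @param max_brightness_count_corr Maximum admissible Pearson correlation
#'   between per-brain brightness and regional count.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(brightness_min = 25, outlier_z = 3,
                      mad_scale = 1.4826, max_outlier_regions = 3L,
                      min_region_median_volume = 0.3,
                      min_region_median_count = 500,
                      count_rule = c("section_median", "total"),
                      max_lr_diff_frac = 0.155,
                      max_brightness_count_corr = 0.3) {
  count_rule <- match.arg(count_rule)
  stopifnot(brightness_min > 0, outlier_z > 0, mad_scale == 1.4826,
            max_outlier_regions >= 0, min_region_median_volume > 0,
            min_region_median_count > 0, max_lr_diff_frac > 0,
            max_brightness_count_corr > 0)
  structure(list(brightness_min = brightness_min, outlier_z = outlier_z,
                 mad_scale = mad_scale,
                 max_outlier_regions = as.integer(max_outlier_regions),
                 min_region_median_volume = min_region_median_volume,
                 min_region_median_count = min_region_median_count,
                 count_rule = count_rule,
                 max_lr_diff_frac = max_lr_diff_frac,
                 max_brightness_count_corr = max_brightness_count_corr),
            class = "qc_config")
}

#' Batch-correction configuration
#'
#' Each brain's volumes are multiplied by a batch-specific factor chosen so
#' that the median whole-brain gray volume of every batch equals
#' `target_median_volume`. Densities are rescaled accordingly; cell counts
#' are left untouched.
#'
#' @param target_median_volume Target batch median gray volume, mm^3.
#' @return An object of class `batch_config`.
#' @export
batch_config <- function(target_median_volume = 380) {
  stopifnot(target_median_volume > 0)
  structure(list(target_median_volume = target_median_volume),
            class = "batch_config")
}

#' Population-statistics configuration
#'
#' @param effect_threshold Minimum absolute median effect size, in percent,
#'   for a region to be called dimorphic.
#' @param q_threshold_dimorphism FDR threshold for the sex-dimorphism screen.
#' @param q_threshold_strain FDR threshold for the strain screen.
#' @param laterality_min_volume Regions with median volume (mm^3) at or below
#'   this are omitted from the laterality screen.
#' @param laterality_exclude_pattern Perl regular expression on region
#'   acronyms; matches are omitted from the laterality screen. The default
#'   drops cortical layer 1 and layer 6b acronyms.
#' @param svm_C Soft-margin penalty of the linear SVM.
#' @param svm_train_frac Fraction of brains used for training in each random
#'   split.
#' @param svm_repeats Number of random train/test splits.
#' @param corr_sig_abs Absolute volume-density correlation above which a
#'   region is reported as significantly correlated.
#' @return An object of class `stats_config`.
#' @export
stats_config <- function(effect_threshold = 5,
                         q_threshold_dimorphism = 0.01,
                         q_threshold_strain = 0.05,
                         laterality_min_volume = 0.05,
                         laterality_exclude_pattern = "(?<![0-9])1$|6b$",
                         svm_C = 100, svm_train_frac = 2 / 3,
                         svm_repeats = 100L, corr_sig_abs = 0.14) {
  stopifnot(effect_threshold >= 0,
            q_threshold_dimorphism > 0, q_threshold_dimorphism <= 1,
            q_threshold_strain > 0, q_threshold_strain <= 1,
            laterality_min_volume >= 0, svm_C > 0,
            svm_train_frac > 0, svm_train_frac < 1, svm_repeats >= 1,
            corr_sig_abs >= 0, corr_sig_abs <= 1)
  structure(list(effect_threshold = effect_threshold,
                 q_threshold_dimorphism = q_threshold_dimorphism,
                 q_threshold_strain = q_threshold_strain,
                 laterality_min_volume = laterality_min_volume,
                 laterality_exclude_pattern = laterality_exclude_pattern,
                 svm_C = svm_C, svm_train_frac = svm_train_frac,
                 svm_repeats = as.integer(svm_repeats),
                 corr_sig_abs = corr_sig_abs),
            class = "stats_config")
}

# Run `code` with a private, restored RNG state seeded by `seed`.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
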