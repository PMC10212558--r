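#' Median gray-matter brightness of a brain
#'
#' Median intensity over all gray-matter pixels pooled across the brain's
#' sections; the quantity the dark-brain exclusion rule thresholds.
#'
#' @param images List of section image matrices.
#' @param masks List of gray-matter masks: logical matrices, or integer label
#'   rasters in which any positive label counts as gray matter.
#' @return Median intensity (0--255 scale).
#' @export
median_gray_brightness <- function(images, masks) {
  stopifnot(length(images) == length(masks))
  vals <- unlist(lapply(seq_along(images), function(s) {
    m <- masks[[s]]
    if (!is.logical(m)) m <- m > 0
    if (!all(dim(m) == dim(images[[s]])))
      stop("mask/image shape mismatch in section ", s - 1)
    images[[s]][m]
  }))
  if (!length(vals)) stop("empty gray-matter mask: brightness undefined")
  stats::median(vals)
}

#' Flag dark brains
#'
#' A brain is discarded when its median gray-matter brightness is strictly
#' below `brightness_min` (default 25 of 255).
#'
#' @param brightness Named numeric vector, one value per brain.
#' @param config A [qc_config()].
#' @return Logical `keep` vector (same names).
#' @export
filter_dark_brains <- function(brightness, config = qc_config()) {
  brightness >= config$brightness_min
}

#' Robust per-region count outliers
#'
#' For each region, counts across brains are summarized by their median and a
#' robust SD (`MAD * 1.4826`, the normal-consistency scaling); a brain-region
#' pair is flagged when its count exceeds `median + outlier_z * robustSD`.
#' The rule is one-sided: only excess counts (the signature of the
#' resolution-degradation artifact) are flagged. Regions with zero MAD are
#' degenerate and produce no flags (with a warning).
#'
#' @param counts Numeric matrix, brains x regions (dimnames respected).
#' @param config A [qc_config()].
#' @return Logical matrix of flags, same shape as `counts`.
#' @export
robust_outlier_regions <- function(counts, config = qc_config()) {
  stopifnot(is.matrix(counts), nrow(counts) >= 3)
  flags <- matrix(FALSE, nrow(counts), ncol(counts),
                  dimnames = dimnames(counts))
  degenerate <- character(0)
  for (j in seq_len(ncol(counts))) {
    x <- counts[, j]
    med <- stats::median(x, na.rm = TRUE)
    rsd <- stats::mad(x, constant = config$mad_scale, na.rm = TRUE)
    if (is.na(rsd) || rsd == 0) {
      degenerate <- c(degenerate, colnames(counts)[j] %||% as.character(j))
      next
    }
    fl <- x > med + config$outlier_z * rsd
    fl[is.na(fl)] <- FALSE
    flags[, j] <- fl
  }
  if (length(degenerate))
    warning("zero MAD (no outlier flags possible) in region(s): ",
            paste(degenerate, collapse = ", "))
  flags
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Discard brains with many outlier regions
#'
#' A brain is discarded when strictly more than `max_outlier_regions`
#' (default 3) of its regions are flagged by [robust_outlier_regions()].
#'
#' @param flags Logical matrix from [robust_outlier_regions()].
#' @param config A [qc_config()].
#' @return Logical `keep` vector, one per brain (row).
#' @export
discard_artifact_brains <- function(flags, config = qc_config()) {
  keep <- rowSums(flags) <= config$max_outlier_regions
  names(keep) <- rownames(flags)
  keep
}

#' Region-level exclusion rules
#'
#' Applies the four region rules to cohort-level metrics: median volume
#' across brains below `min_region_median_volume`; median cell count below
#' `min_region_median_count` (per-section counts when `section_counts` is
#' supplied and `count_rule = "section_median"`, per-brain totals otherwise);
#' mean per-brain hemispheric count imbalance `|N_L - N_R| / (N_L + N_R)`
#' above `max_lr_diff_frac`; and Pearson correlation between per-brain
#' brightness and count above `max_brightness_count_corr`.
#'
#' @param metrics Long data frame across brains with `brain_id`, `region_id`,
#'   `V_mm3` (or `V`), `N`, `N_left`, `N_right`.
#' @param brightness Named numeric vector of per-brain brightness (names =
#'   brain_id).
#' @param section_counts Optional data frame with `region_id` and per-section
#'   counts `n` (pooled across brains) for the literal "median count across
#'   sections" reading.
#' @param config A [qc_config()].
#' @return Data frame: `region_id`, `keep`, `reasons` (`;`-separated among
#'   `small_volume`, `low_count`, `lr_imbalance`, `brightness_correlated`).
#' @export
filter_regions <- function(metrics, brightness = NULL,
                           section_counts = NULL, config = qc_config()) {
  v_col <- if ("V_mm3" %in% names(metrics)) "V_mm3" else "V"
  out <- lapply(split(metrics, metrics$region_id), function(g) {
    reasons <- character(0)
    if (stats::median(g[[v_col]]) < config$min_region_median_volume)
      reasons <- c(reasons, "small_volume")
    med_count <- if (!is.null(section_counts) &&
                     config$count_rule == "section_median") {
      stats::median(section_counts$n[
        section_counts$region_id == g$region_id[1]])
    } else stats::median(g$N)
    if (is.na(med_count) || med_count < config$min_region_median_count)
      reasons <- c(reasons, "low_count")
    tot <- g$N_left + g$N_right
    frac <- abs(g$N_left - g$N_right) / ifelse(tot > 0, tot, NA)
    if (mean(frac, na.rm = TRUE) > config$max_lr_diff_frac)
      reasons <- c(reasons, "lr_imbalance")
    if (!is.null(brightness)) {
      b <- brightness[as.character(g$brain_id)]
      if (sum(!is.na(b)) >= 3 && stats::sd(g$N) > 0 &&
          stats::sd(b, na.rm = TRUE) > 0) {
        r <- stats::cor(b, g$N, use = "complete.obs")
        if (!is.na(r) && r > config$max_brightness_count_corr)
          reasons <- c(reasons, "brightness_correlated")
      }
    }
    data.frame(region_id = g$region_id[1], keep = !length(reasons),
               reasons = paste(reasons, collapse = ";"))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Batch-correction factors for brain volumes
#'
#' Computes a multiplicative factor per batch such that each batch's median
#' volume equals the target (default 380 mm^3), and applies it.
#'
#' @param volumes Per-brain volumes (whole-brain gray), mm^3.
#' @param batches Batch id per brain.
#' @param config A [batch_config()].
#' @return List with `factors` (named by batch) and `corrected` volumes.
#' @export
batch_correct_volumes <- function(volumes, batches,
                                  config = batch_config()) {
  stopifnot(length(volumes) == length(batches))
  med <- tapply(volumes, batches, stats::median)
  if (any(med <= 0)) stop("batch median volume is zero")
  factors <- stats::setNames(as.numeric(config$target_median_volume / med),
                             names(med))
  list(factors = factors,
       corrected = unname(volumes * factors[as.character(batches)]))
}

#' Apply batch correction to a cohort metrics table
#'
#' Scales every volume column of `metrics` by the brain's batch factor
#' (derived from per-brain total gray volume) and recomputes densities as
#' `N / V`; counts are untouched.
#'
#' @param metrics Long metrics table with `brain_id`, volume columns and `N`.
#' @param brains Data frame with `brain_id` and `batch`.
#' @param config A [batch_config()].
#' @return List with `metrics` (corrected) and `factors`.
#' @export
apply_batch_correction <- function(metrics, brains,
                                   config = batch_config()) {
  v_col <- if ("V_mm3" %in% names(metrics)) "V_mm3" else "V"
  totals <- tapply(metrics[[v_col]], metrics$brain_id, sum)
  batch <- brains$batch[match(names(totals), brains$brain_id)]
  bc <- batch_correct_volumes(as.numeric(totals), batch, config)
  f_brain <- bc$factors[as.character(batch)]
  names(f_brain) <- names(totals)
  f <- f_brain[as.character(metrics$brain_id)]
  for (col in intersect(c(v_col, "V_left", "V_right"), names(metrics)))
    metrics[[col]] <- metrics[[col]] * f
  d_col <- if ("D_per_mm3" %in% names(metrics)) "D_per_mm3" else "D"
  if (d_col %in% names(metrics))
    metrics[[d_col]] <- metrics$N / metrics[[v_col]]
  for (dh in c("D_left", "D_right")) {
    vh <- sub("D", "V", dh); nh <- sub("D", "N", dh)
    if (all(c(dh, vh, nh) %in% names(metrics)))
      metrics[[dh]] <- metrics[[nh]] / metrics[[vh]]
  }
  list(metrics = metrics, factors = bc$factors)
}

#' Run the full QC cascade over a cohort
#'
#' Applies the exclusion rules in their fixed order -- dark brains, artifact
#' brains (robust count outliers), small/low-count regions, left-right
#' imbalanced regions together with brightness-correlated regions -- each
#' rule operating on the survivors of the previous one, then batch-corrects
#' volumes.
#'
#' @param metrics Long cohort metrics table (`brain_id`, `region_id`, volume
#'   and count columns).
#' @param brains Data frame with `brain_id`, `batch`, `brightness`.
#' @param section_counts Optional per-section counts, see [filter_regions()].
#' @param config A [qc_config()].
#' @param batch Batch configuration, or `NULL` to skip correction.
#' @return List: `metrics` (surviving, corrected rows), `report` (data frame
#'   of rule decisions), `kept_brains`, `kept_regions`, `batch_factors`.
#' @export
apply_qc <- function(metrics, brains, section_counts = NULL,
                     config = qc_config(), batch = batch_config()) {
  report <- list()
  note <- function(rule, unit, value, threshold, keep)
    data.frame(rule = rule, unit = as.character(unit), value = value,
               threshold = threshold, decision = ifelse(keep, "keep",
                                                        "discard"))
  bright <- stats::setNames(brains$brightness, brains$brain_id)
  keep_dark <- filter_dark_brains(bright, config)
  report$dark <- note("dark_brain", names(keep_dark), bright,
                      config$brightness_min, keep_dark)
  metrics <- metrics[metrics$brain_id %in% names(keep_dark)[keep_dark], ]

  counts <- tapply(metrics$N, list(metrics$brain_id, metrics$region_id),
                   mean)
  flags <- suppressWarnings(robust_outlier_regions(counts, config))
  keep_art <- discard_artifact_brains(flags, config)
  report$artifact <- note("artifact_brain", names(keep_art),
                          rowSums(flags), config$max_outlier_regions,
                          keep_art)
  metrics <- metrics[metrics$brain_id %in% names(keep_art)[keep_art], ]

  reg <- filter_regions(metrics, brightness = bright,
                        section_counts = section_counts, config = config)
  report$regions <- data.frame(rule = "region_filter",
                               unit = as.character(reg$region_id),
                               value = NA_real_, threshold = NA_real_,
                               decision = ifelse(reg$keep, "keep",
                                                 paste0("discard:",
                                                        reg$reasons)))
  metrics <- metrics[metrics$region_id %in% reg$region_id[reg$keep], ]

  factors <- NULL
  if (!is.null(batch)) {
    bcor <- apply_batch_correction(metrics, brains, batch)
    metrics <- bcor$metrics
    factors <- bcor$factors
  }
  list(metrics = metrics, report = do.call(rbind, report),
       kept_brains = names(keep_art)[keep_art],
       kept_regions = reg$region_id[reg$keep],
       batch_factors = factors)
}
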