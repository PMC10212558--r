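#' Write / read section images as 8-bit grayscale TIFF
#'
#' One file per section, named `sec_<index>.tif` with 0-based indices.
#'
#' @param images List of matrices with integer intensities 0--255.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_section_images <- function(images, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(images), function(s) {
    p <- file.path(dir, sprintf("sec_%d.tif", s - 1L))
    tiff::writeTIFF(images[[s]] / 255, p, bits.per.sample = 8)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_section_images
#' @param pattern Filename pattern whose single `%d` captures the section
#'   index.
#' @return `read_section_images`: list of integer matrices ordered by
#'   section index.
#' @export
read_section_images <- function(dir, pattern = "^sec_([0-9]+)\\.tif$") {
  files <- list.files(dir, pattern = pattern)
  idx <- as.integer(sub(pattern, "\\1", files))
  files <- files[order(idx)]
  lapply(files, function(f) {
    m <- tiff::readTIFF(file.path(dir, f), as.is = TRUE)
    storage.mode(m) <- "integer"
    m
  })
}

#' Write / read label rasters as 16-bit TIFF
#'
#' One file per section, `labels_<index>.tif`, pixel-aligned with the
#' corresponding section image. Region ids up to 65535 round-trip exactly.
#'
#' @param labels List of integer matrices (0 = unannotated).
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_label_rasters <- function(labels, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(labels), function(s) {
    if (max(labels[[s]]) > 65535) stop("region id exceeds 16-bit range")
    p <- file.path(dir, sprintf("labels_%d.tif", s - 1L))
    tiff::writeTIFF(labels[[s]] / 65535, p, bits.per.sample = 16)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_label_rasters
#' @param pattern Filename pattern whose single `%d` captures the section
#'   index.
#' @export
read_label_rasters <- function(dir, pattern = "^labels_([0-9]+)\\.tif$") {
  read_section_images(dir, pattern)
}

#' Tolerant CSV table reader with schema check
#'
#' Reads a CSV and verifies that the required columns are present; unknown
#' extra columns are preserved with a warning (tolerant-reader policy).
#'
#' @param path CSV path.
#' @param required Character vector of required column names.
#' @return Data frame.
#' @export
read_table_checked <- function(path, required = character(0)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema mismatch in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(df), required)
  if (length(required) && length(extra))
    warning("extra column(s) preserved in ", basename(path), ": ",
            paste(extra, collapse = ", "))
  df
}

#' Write a data frame as CSV (full precision)
#'
#' @param df Data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table_csv <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Nested configuration for [run_pipeline()]: optics, tiling, QC, and
#' statistics blocks plus synthesis settings for phantom cohorts and a single
#' global seed from which every stage's randomness is derived. The QC block
#' overrides the region-size thresholds of [qc_config()] (which default to
#' whole-brain scales) with values suited to the synthesized phantom scale,
#' and `batch_target = "auto"` equalizes batch medians at the cohort median
#' rather than at a fixed absolute volume.
#'
#' @param seed Global seed.
#' @return A list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    optics = list(pixel_size = 0.7, depth_of_field = 1.5, section_gap = 100,
                  background_level = 120, nucleus_level = 40, noise_sd = 5),
    tiles = list(tile_px = 312L, overlap_px = 20L),
    synth = list(n_brains = 4L, n_regions = 2L, field_um = c(360, 220, 420),
                 densities = c(1.5e5, 3e5)),
    quantify = list(radius_percentile = 90, min_cells_for_R = 10L),
    qc = list(enabled = TRUE, batch_target = "auto",
              min_region_volume = 0.001, min_region_count = 20),
    stats = list(enabled = TRUE, svm_repeats = 10L),
    stages = c("synth", "detect", "regionize", "quantify", "qc", "stats")),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_pipeline_config()]; unknown keys are an error.
#'
#' @param path YAML file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  merge_into <- function(base, upd, where = "") {
    for (k in names(upd)) {
      if (!k %in% names(base))
        stop("unknown config key: ", where, k)
      if (is.list(base[[k]]) && is.list(upd[[k]]))
        base[[k]] <- merge_into(base[[k]], upd[[k]], paste0(where, k, "."))
      else base[[k]] <- upd[[k]]
    }
    base
  }
  structure(merge_into(unclass(cfg), user), class = "pipeline_config")
}
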