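# Region layout used for synthesized pipeline runs: bilateral box regions
# stacked top-to-bottom, mirrored about the vertical midline.
synth_region_specs <- function(cfg) {
  n <- cfg$synth$n_regions
  field <- cfg$synth$field_um
  dens <- rep_len(cfg$synth$densities, n)
  margin <- 10
  h <- (field[2] - (n + 1) * margin) / n     # per-region y extent
  w <- field[1] / 2 - 2 * margin             # one hemisphere's x extent
  specs <- list()
  for (i in seq_len(n)) {
    cy <- margin * i + h * (i - 0.5)
    left <- region_spec(region_id = i, acronym = sprintf("PH%02d", i),
                        shape = "box",
                        center = c(margin + w / 2, cy, field[3] / 2),
                        half_size = c(w / 2, h / 2, field[3] / 2 + 6),
                        density = dens[i])
    specs[[length(specs) + 1]] <- left
    specs[[length(specs) + 1]] <- mirror_spec(left, field[1])
  }
  specs
}

#' Run the end-to-end pipeline
#'
#' Executes the stages in order -- phantom synthesis (optional), nucleus
#' detection, region assignment, 3D quantification, QC with batch
#' correction, and population statistics -- writing every stage's tables and
#' rasters plus a provenance manifest into `out_dir`. Re-running with the
#' same configuration and seed reproduces all CSV outputs bit-identically.
#'
#' @param config A `pipeline_config` (see [default_pipeline_config()] /
#'   [read_pipeline_config()]).
#' @param out_dir Run directory; created if needed.
#' @return Invisibly, a list with the cohort metrics table, QC result, and
#'   stats tables (where computed).
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config") || is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  optics <- do.call(optical_model, config$optics)
  tiles <- do.call(tile_config, config$tiles)

  brains <- NULL
  if ("synth" %in% stages) {
    specs <- synth_region_specs(config)
    n_brains <- config$synth$n_brains
    brains <- data.frame(
      brain_id = sprintf("phantom%02d", seq_len(n_brains)),
      strain = "C57BL/6J",
      sex = rep_len(c("F", "M"), n_brains),
      batch = rep_len(1:2, n_brains))
    for (b in seq_len(n_brains)) {
      ph <- generate_phantom_brain(specs, optics,
                                   field_um = config$synth$field_um,
                                   strain = brains$strain[b],
                                   sex = brains$sex[b],
                                   batch = brains$batch[b],
                                   seed = config$seed + 1000L * b)
      bdir <- file.path(out_dir, "sections", brains$brain_id[b])
      write_section_images(ph$images, bdir)
      write_label_rasters(ph$labels, bdir)
      write_table_csv(ph$truth$regions,
                      file.path(bdir, "regions_truth.csv"))
      write_table_csv(ph$truth$cells, file.path(bdir, "cells_truth.csv"))
      if (b == 1L)
        write_table_csv(ph$hierarchy, file.path(out_dir, "hierarchy.csv"))
    }
    write_table_csv(brains, file.path(out_dir, "brains.csv"))
  } else {
    roster <- file.path(out_dir, "brains.csv")
    if (!file.exists(roster))
      stop("detect stage: no brain roster at ", roster,
           " (run the synth stage or provide inputs first)")
    brains <- read_table_checked(roster,
                                 c("brain_id", "strain", "sex", "batch"))
  }
  hierarchy <- read_table_checked(file.path(out_dir, "hierarchy.csv"),
                                  c("region_id", "parent_id", "acronym",
                                    "level"))

  brain_dirs <- file.path(out_dir, "sections", brains$brain_id)
  if (any(!dir.exists(brain_dirs)))
    stop("detect stage: missing section directory: ",
         brain_dirs[!dir.exists(brain_dirs)][1])

  metrics <- NULL
  section_counts <- NULL
  if (any(c("detect", "regionize", "quantify") %in% stages)) {
    all_metrics <- vector("list", nrow(brains))
    all_counts <- vector("list", nrow(brains))
    brightness <- numeric(nrow(brains))
    for (b in seq_len(nrow(brains))) {
      bdir <- brain_dirs[b]
      images <- read_section_images(bdir)
      labels <- read_label_rasters(bdir)
      det <- detect_brain(images, tiles, optics)
      cells <- assign_cells_to_regions(det$cells, labels, hierarchy)
      write_table_csv(cells, file.path(bdir, "cells.csv"))
      q <- quantify_brain(cells, labels, optics,
                          gap_um = optics$section_gap,
                          percentile = config$quantify$radius_percentile,
                          min_cells_for_R = config$quantify$min_cells_for_R,
                          brain_id = brains$brain_id[b],
                          hierarchy = hierarchy)
      all_metrics[[b]] <- q$region_metrics
      all_counts[[b]] <- q$section_quant[, c("brain_id", "section_index",
                                             "region_id", "n")]
      brightness[b] <- median_gray_brightness(images, labels)
      message("quantified ", brains$brain_id[b], ": ",
              nrow(cells), " cells assigned (",
              attr(cells, "n_dropped"), " dropped), ",
              nrow(q$region_metrics), " regions")
    }
    metrics <- do.call(rbind, all_metrics)
    section_counts <- do.call(rbind, all_counts)
    brains$brightness <- brightness
    write_table_csv(metrics, file.path(out_dir, "region_metrics.csv"))
  }

  qc_res <- NULL
  if ("qc" %in% stages && !is.null(metrics)) {
    if (isTRUE(config$qc$enabled)) {
      target <- config$qc$batch_target
      if (identical(target, "auto"))
        target <- stats::median(tapply(metrics$V_mm3, metrics$brain_id, sum))
      qcc <- qc_config(
        min_region_median_volume = config$qc$min_region_volume,
        min_region_median_count = config$qc$min_region_count)
      qc_res <- apply_qc(metrics, brains, section_counts = section_counts,
                         config = qcc, batch = batch_config(target))
      write_table_csv(qc_res$report, file.path(out_dir, "qc_report.csv"))
      write_table_csv(data.frame(batch = names(qc_res$batch_factors),
                                 factor = as.numeric(qc_res$batch_factors)),
                      file.path(out_dir, "batch_factors.csv"))
      write_table_csv(qc_res$metrics,
                      file.path(out_dir, "region_metrics_qc.csv"))
      metrics <- qc_res$metrics
    }
  }

  stats_out <- list()
  if ("stats" %in% stages && isTRUE(config$stats$enabled) &&
      !is.null(metrics)) {
    cohort <- metrics
    cohort$sex <- brains$sex[match(cohort$brain_id, brains$brain_id)]
    cohort$strain <- brains$strain[match(cohort$brain_id, brains$brain_id)]
    names(cohort)[names(cohort) == "V_mm3"] <- "V"
    names(cohort)[names(cohort) == "D_per_mm3"] <- "D"
    cohort$D_left <- cohort$N_left / cohort$V_left
    cohort$D_right <- cohort$N_right / cohort$V_right
    scfg <- stats_config(svm_repeats = config$stats$svm_repeats)
    tab <- table(cohort$sex[!duplicated(cohort$brain_id)])
    enough <- length(tab) == 2 && all(tab >= 2)
    if (enough) {
      for (v in c("V", "D", "N")) {
        volc <- dimorphism_screen(cohort, "sex", v, scfg)
        write_table_csv(volc, file.path(out_dir,
                                        sprintf("volcano_%s_sex.csv", v)))
        stats_out[[paste0("volcano_", v)]] <- volc
      }
      lat <- laterality_screen(cohort, "D", scfg)
      write_table_csv(lat, file.path(out_dir, "laterality_D.csv"))
      stats_out$laterality <- lat
      vd <- volume_density_correlation(cohort, scfg)
      write_table_csv(vd, file.path(out_dir, "vd_correlation.csv"))
      stats_out$vd_correlation <- vd
    }
  }

  manifest <- list(
    package = "cytoarch",
    version = as.character(utils::packageVersion("cytoarch")),
    r_version = R.version.string,
    seed = config$seed,
    config = unclass(config),
    created = "run",
    outputs = local({
      csvs <- list.files(out_dir, pattern = "\\.csv$", recursive = TRUE,
                         full.names = TRUE)
      stats::setNames(as.list(unname(tools::md5sum(csvs))),
                      sub(paste0("^", out_dir, "/?"), "", csvs))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(metrics = metrics, qc = qc_res, stats = stats_out,
                 brains = brains))
}
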