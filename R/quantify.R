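#' Percentile of in-plane cell radii
#'
#' The slab model needs a per-region, per-section cell radius `R`; it is
#' taken as the 90th percentile of measured (projected) cell radii, computed
#' with linear interpolation. Because projected radii understate the true
#' sphere radius for cells away from the optical plane, a high percentile
#' targets the full radius; the 50th percentile would give a thinner slab and
#' hence larger density and count estimates.
#'
#' @param radii Non-empty numeric vector of radii, micrometers.
#' @param percentile Percentile in (0, 100].
#' @return The interpolated percentile, micrometers.
#' @export
radius_percentile <- function(radii, percentile = 90) {
  if (!length(radii)) stop("radius percentile of an empty set is undefined")
  stopifnot(percentile > 0, percentile <= 100)
  stats::quantile(radii, percentile / 100, type = 7, names = FALSE)
}

#' Per-section slab density
#'
#' Cells detected on a 2D section originate from a slab of volume
#' `v_s = a_s * (2R + d)`: region area times slab thickness, where `R` is the
#' regional cell radius and `d` the optical depth of field. The section
#' density is the detected count divided by this slab volume.
#'
#' @param n Detected cell count in the region-section.
#' @param area_um2 Region area on the section, square micrometers.
#' @param R_um Regional cell radius (see [radius_percentile()]), micrometers.
#' @param optics An [optical_model()] (for `d`).
#' @return Density in cells/mm^3 (`0` when `n = 0`).
#' @export
section_density <- function(n, area_um2, R_um, optics = optical_model()) {
  stopifnot(n >= 0)
  if (n == 0) return(0)
  if (area_um2 <= 0)
    stop("cells detected outside any annotated area (a_s = 0, n > 0)")
  v_um3 <- area_um2 * (2 * R_um + optics$depth_of_field)
  n / v_um3 * 1e9
}

#' Region volume from per-section areas
#'
#' Linear (trapezoidal) interpolation between sections: the volume between
#' two adjacent sections in which the region is present is the mean of its
#' two areas times the gap; the regional volume is the sum over consecutive
#' present pairs. Sections where the region is absent contribute no segment.
#'
#' @param section_index Integer section indices (0-based, strictly unique).
#' @param areas_mm2 Region area per section, square millimeters.
#' @param gap_mm Section spacing, millimeters.
#' @return Volume in mm^3, with attribute `single_section = TRUE` (and value
#'   0) when the region appears in fewer than two sections.
#' @export
region_volume <- function(section_index, areas_mm2, gap_mm) {
  stopifnot(length(section_index) == length(areas_mm2), gap_mm > 0)
  if (anyDuplicated(section_index)) stop("duplicate section index")
  o <- order(section_index)
  s <- section_index[o]; a <- areas_mm2[o]
  if (length(s) < 2) {
    v <- 0
    attr(v, "single_section") <- TRUE
    return(v)
  }
  adj <- which(diff(s) == 1L)
  v <- sum((a[adj] + a[adj + 1]) / 2 * gap_mm)
  attr(v, "single_section") <- length(adj) == 0L
  v
}

#' Region cell count from per-section densities and areas
#'
#' The count between two adjacent sections is the mean of their slab
#' densities times the inter-section volume (mean area times gap); the
#' regional count sums these over consecutive present pairs.
#'
#' @param section_index Integer section indices (0-based, unique).
#' @param rho Per-section slab densities, cells/mm^3.
#' @param areas_mm2 Region area per section, square millimeters.
#' @param gap_mm Section spacing, millimeters.
#' @return Estimated cell count.
#' @export
region_count <- function(section_index, rho, areas_mm2, gap_mm) {
  stopifnot(length(section_index) == length(rho),
            length(rho) == length(areas_mm2), gap_mm > 0)
  if (anyDuplicated(section_index)) stop("duplicate section index")
  o <- order(section_index)
  s <- section_index[o]; r <- rho[o]; a <- areas_mm2[o]
  if (length(s) < 2) return(0)
  adj <- which(diff(s) == 1L)
  sum((r[adj] + r[adj + 1]) / 2 * (a[adj] + a[adj + 1]) / 2 * gap_mm)
}

#' Overall region density
#'
#' @param N Regional cell count.
#' @param V Regional volume, mm^3.
#' @return `N / V` (cells/mm^3); `NA` with a `zero_volume` attribute when
#'   `V = 0`.
#' @export
region_density <- function(N, V) {
  if (V <= 0) {
    d <- NA_real_
    attr(d, "zero_volume") <- TRUE
    return(d)
  }
  N / V
}

#' Soma diameter implied by a nucleus diameter
#'
#' Converts a nucleus (equivalent) diameter to the cell-body diameter under
#' an assumed nucleus-to-soma volumetric ratio:
#' `d_soma = d_nucleus * ratio^(-1/3)`.
#'
#' @param d_nucleus Nucleus diameter, micrometers.
#' @param volumetric_ratio Nucleus/soma volume ratio in (0, 1].
#' @return Soma diameter, micrometers.
#' @export
nucleus_to_soma_diameter <- function(d_nucleus, volumetric_ratio = 0.08) {
  stopifnot(all(d_nucleus > 0), volumetric_ratio > 0, volumetric_ratio <= 1)
  d_nucleus * volumetric_ratio^(-1 / 3)
}

#' Per-section region areas from label rasters
#'
#' @param labels List of integer label rasters (index 1 = section 0).
#' @param optics An [optical_model()] (pixel size).
#' @return Data frame: `section_index`, `region_id`, `area_px`, `area_um2`,
#'   and left/right splits (`area_px_left`, `area_px_right`, `area_um2_left`,
#'   `area_um2_right`). The hemisphere split uses the vertical centre column
#'   with ties to the right, matching [assign_cells_to_regions()].
#' @export
section_area_table <- function(labels, optics = optical_model()) {
  px2 <- optics$pixel_size^2
  rows <- lapply(seq_along(labels), function(s) {
    ras <- labels[[s]]
    ids <- ras[ras > 0L]
    if (!length(ids)) return(NULL)
    mid <- (ncol(ras) + 1) / 2
    left <- col(ras) < mid
    tot <- table(ids)
    lef <- table(ras[ras > 0L & left])
    rid <- as.integer(names(tot))
    a_l <- as.integer(lef[match(names(tot), names(lef))])
    a_l[is.na(a_l)] <- 0L
    data.frame(section_index = s - 1L, region_id = rid,
               area_px = as.integer(tot), area_px_left = a_l,
               area_px_right = as.integer(tot) - a_l)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(section_index = integer(0), region_id = integer(0),
                      area_px = integer(0), area_px_left = integer(0),
                      area_px_right = integer(0))
  out$area_um2 <- out$area_px * px2
  out$area_um2_left <- out$area_px_left * px2
  out$area_um2_right <- out$area_px_right * px2
  rownames(out) <- NULL
  out
}

#' Quantify a brain: per-region 3D volume, density, and count
#'
#' The core 2D-to-3D estimator. For every region and section it computes the
#' slab density from the detected count, region area, and the percentile cell
#' radius; regional volume comes from trapezoidal interpolation of areas
#' across adjacent sections, the count from density-weighted interpolation,
#' and the overall density from `N / V`. Sections where a region is annotated
#' but holds no detected cell contribute density 0 but still bound volume
#' segments. When a region-section has fewer than `min_cells_for_R` cells the
#' radius percentile is pooled over all of the region's cells in the brain.
#'
#' @param cells Assigned cell table ([assign_cells_to_regions()]): needs
#'   `section_index`, `region_id`, `hemisphere`, `radius_um`.
#' @param labels List of label rasters, or a precomputed
#'   [section_area_table()].
#' @param optics An [optical_model()].
#' @param gap_um Section spacing, micrometers.
#' @param percentile Radius percentile for the slab thickness.
#' @param min_cells_for_R Below this per-section cell count the regional
#'   radius pool is used instead.
#' @param brain_id Identifier recorded on the output rows.
#' @param hierarchy Optional hierarchy table for acronyms.
#' @return List with `region_metrics` (one row per region: `brain_id`,
#'   `region_id`, `acronym`, `V_mm3`, `D_per_mm3`, `N`, `V_left`, `V_right`,
#'   `N_left`, `N_right`, `flags`) and `section_quant` (per region-section:
#'   areas, counts, radius `R_um`, slab volume `v_um3`, density
#'   `rho_per_mm3`).
#' @export
quantify_brain <- function(cells, labels, optics = optical_model(),
                           gap_um = optics$section_gap, percentile = 90,
                           min_cells_for_R = 10L, brain_id = "brain",
                           hierarchy = NULL) {
  areas <- if (is.data.frame(labels)) labels
           else section_area_table(labels, optics)
  gap_mm <- gap_um / 1000
  d <- optics$depth_of_field

  key <- paste(areas$section_index, areas$region_id)
  ckey <- paste(cells$section_index, cells$region_id)
  if (nrow(cells) && any(!ckey %in% key))
    stop("cells detected outside any annotated area (a_s = 0, n > 0)")

  pool <- split(cells$radius_um, cells$region_id)
  sq <- areas
  sq$n <- as.integer(table(factor(ckey, levels = key)))
  sq$n_left <- as.integer(table(factor(
    ckey[cells$hemisphere == "left"], levels = key)))
  sq$n_right <- sq$n - sq$n_left
  sq$R_um <- NA_real_
  for (i in seq_len(nrow(sq))) {
    if (sq$n[i] == 0) next
    radii <- cells$radius_um[ckey == key[i]]
    if (sq$n[i] < min_cells_for_R)
      radii <- pool[[as.character(sq$region_id[i])]]
    sq$R_um[i] <- radius_percentile(radii, percentile)
  }
  sq$v_um3 <- ifelse(is.na(sq$R_um), NA_real_,
                     sq$area_um2 * (2 * sq$R_um + d))
  sq$rho_per_mm3 <- ifelse(sq$n == 0, 0, sq$n / sq$v_um3 * 1e9)
  rho_hemi <- function(nh, ah) ifelse(nh == 0 | ah == 0, 0,
                                      nh / (ah * (2 * sq$R_um + d)) * 1e9)
  sq$rho_left <- rho_hemi(sq$n_left, sq$area_um2_left)
  sq$rho_right <- rho_hemi(sq$n_right, sq$area_um2_right)
  sq$brain_id <- brain_id

  metrics <- lapply(split(sq, sq$region_id), function(g) {
    a_mm2 <- g$area_um2 * 1e-6
    V <- region_volume(g$section_index, a_mm2, gap_mm)
    N <- region_count(g$section_index, g$rho_per_mm3, a_mm2, gap_mm)
    V_l <- region_volume(g$section_index, g$area_um2_left * 1e-6, gap_mm)
    V_r <- region_volume(g$section_index, g$area_um2_right * 1e-6, gap_mm)
    N_l <- region_count(g$section_index, g$rho_left,
                        g$area_um2_left * 1e-6, gap_mm)
    N_r <- region_count(g$section_index, g$rho_right,
                        g$area_um2_right * 1e-6, gap_mm)
    D <- region_density(N, as.numeric(V))
    flags <- c(if (isTRUE(attr(V, "single_section"))) "single_section",
               if (isTRUE(attr(D, "zero_volume"))) "zero_volume")
    data.frame(brain_id = brain_id, region_id = g$region_id[1],
               V_mm3 = as.numeric(V), D_per_mm3 = as.numeric(D), N = N,
               V_left = as.numeric(V_l), V_right = as.numeric(V_r),
               N_left = N_l, N_right = N_r,
               flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  metrics$acronym <- if (!is.null(hierarchy))
    hierarchy$acronym[match(metrics$region_id, hierarchy$region_id)]
  else paste0("R", metrics$region_id)
  metrics <- metrics[, c("brain_id", "region_id", "acronym", "V_mm3",
                         "D_per_mm3", "N", "V_left", "V_right",
                         "N_left", "N_right", "flags")]
  list(region_metrics = metrics, section_quant = sq)
}
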