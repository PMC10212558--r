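#' Assign detected cells to atlas regions and hemispheres
#'
#' Looks up the label-raster value at each cell centroid and assigns the
#' hemisphere by the section midline: centroids strictly left of the vertical
#' centre column are `left`, everything else (ties included) `right`. Cells
#' landing on label 0 (unannotated tissue) are dropped; the number dropped is
#' returned in the attribute `n_dropped` so that
#' `assigned + dropped = detected` can be audited.
#'
#' @param cells Data frame from [extract_cells()]; when `labels` is a list,
#'   rows are matched to rasters by `section_index` (0-based).
#' @param labels Integer label raster (matrix) or list of rasters.
#' @param hierarchy Optional region-hierarchy table (`region_id`, `acronym`);
#'   when given, an `acronym` column is added.
#' @return `cells` with `region_id` and `hemisphere` columns, unannotated
#'   rows removed.
#' @export
assign_cells_to_regions <- function(cells, labels, hierarchy = NULL) {
  if (!is.list(labels)) labels <- list(labels)
  if (nrow(cells)) {
    sec <- cells$section_index + 1L
    if (any(sec < 1L | sec > length(labels)))
      stop("section_index outside the label stack")
    region <- integer(nrow(cells))
    hemi <- character(nrow(cells))
    for (s in unique(sec)) {
      ras <- labels[[s]]
      idx <- which(sec == s)
      ri <- pmin(pmax(round(cells$centroid_row[idx]), 1L), nrow(ras))
      ci <- pmin(pmax(round(cells$centroid_col[idx]), 1L), ncol(ras))
      region[idx] <- ras[cbind(ri, ci)]
      mid <- (ncol(ras) + 1) / 2
      hemi[idx] <- ifelse(cells$centroid_col[idx] < mid, "left", "right")
    }
    cells$region_id <- region
    cells$hemisphere <- hemi
    dropped <- sum(region == 0L)
    cells <- cells[region != 0L, , drop = FALSE]
    rownames(cells) <- NULL
  } else {
    cells$region_id <- integer(0)
    cells$hemisphere <- character(0)
    dropped <- 0L
  }
  if (!is.null(hierarchy))
    cells$acronym <- hierarchy$acronym[match(cells$region_id,
                                             hierarchy$region_id)]
  attr(cells, "n_dropped") <- dropped
  cells
}

#' Local cell coverage around centroids
#'
#' Counts the cell-mask pixels inside a `window_px` square window centred on
#' each centroid. Windows are clipped at the image border and the count is
#' not rescaled, so edge cells are biased low; the downstream dense/sparse
#' split is threshold-like and tolerates this.
#'
#' @param mask Logical section mask (post-stitch).
#' @param centroids Two-column matrix or data frame of `(row, col)` centroid
#'   positions (pixels).
#' @param config A [coverage_config()].
#' @return Integer vector of coverage counts, in `[0, window_px^2]`.
#' @export
coverage <- function(mask, centroids, config = coverage_config()) {
  centroids <- as.matrix(centroids)
  if (!nrow(centroids)) return(integer(0))
  half <- config$window_px %/% 2L
  nr <- nrow(mask); nc <- ncol(mask)
  # summed-area table with a zero first row/col: S[i+1, j+1] = sum mask[1:i, 1:j]
  S <- matrix(0, nr + 1L, nc + 1L)
  cs <- apply(mask * 1L, 2, cumsum)            # column-wise cumsum
  S[-1, -1] <- t(apply(cs, 1, cumsum))         # then row-wise
  ri <- pmin(pmax(round(centroids[, 1]), 1L), nr)
  ci <- pmin(pmax(round(centroids[, 2]), 1L), nc)
  r0 <- pmax(ri - half, 1L); r1 <- pmin(ri + half - 1L, nr)
  c0 <- pmax(ci - half, 1L); c1 <- pmin(ci + half - 1L, nc)
  as.integer(S[cbind(r1 + 1L, c1 + 1L)] - S[cbind(r0, c1 + 1L)] -
             S[cbind(r1 + 1L, c0)] + S[cbind(r0, c0)])
}

#' Split a composite region's cells into dense and sparse clusters
#'
#' One-dimensional 2-means on the coverage values; the cluster with the
#' higher centroid is labelled `dense`. Used where the atlas annotation does
#' not separate a cell-dense band (e.g. a pyramidal layer) from its sparse
#' surround. For 1D data, 2-means is equivalent to the optimal single
#' threshold, which is the test oracle.
#'
#' @param coverages Integer/numeric coverage values, one per cell.
#' @param config A [coverage_config()].
#' @param seed Seed for the k-means restarts.
#' @return Factor with levels `dense`, `sparse`, one per cell. If all
#'   coverage values are identical no split is possible: all cells are
#'   labelled `sparse` with a warning.
#' @export
split_dense_sparse <- function(coverages, config = coverage_config(),
                               seed = 1L) {
  stopifnot(length(coverages) >= 2)
  if (length(unique(coverages)) < 2) {
    warning("all coverage values identical: no dense/sparse split")
    return(factor(rep("sparse", length(coverages)),
                  levels = c("dense", "sparse")))
  }
  km <- with_seed(seed,
    stats::kmeans(matrix(as.numeric(coverages)), centers = 2, nstart = 10))
  dense_cl <- which.max(km$centers)
  factor(ifelse(km$cluster == dense_cl, "dense", "sparse"),
         levels = c("dense", "sparse"))
}

#' Draw subregion masks from clustered cell centroids
#'
#' Rasterizes each cluster's centroids, applies morphological closing with a
#' disc structuring element to merge nearby cells into a contiguous outline,
#' and discards spurious components smaller than `min_subregion_area`.
#'
#' @param centroids Two-column `(row, col)` matrix of cell centroids.
#' @param cluster Factor/vector of cluster labels, one per centroid.
#' @param image_dim Integer length-2 output mask size.
#' @param config A [coverage_config()].
#' @return Named list of logical masks, one per cluster level.
#' @export
subregion_masks <- function(centroids, cluster, image_dim,
                            config = coverage_config()) {
  centroids <- as.matrix(centroids)
  stopifnot(nrow(centroids) == length(cluster))
  brush <- EBImage::makeBrush(2L * config$closing_radius + 1L, shape = "disc")
  out <- list()
  for (lv in levels(factor(cluster))) {
    m <- matrix(FALSE, image_dim[1], image_dim[2])
    sel <- cluster == lv
    ri <- pmin(pmax(round(centroids[sel, 1]), 1L), image_dim[1])
    ci <- pmin(pmax(round(centroids[sel, 2]), 1L), image_dim[2])
    m[cbind(ri, ci)] <- TRUE
    m <- EBImage::imageData(EBImage::closing(m * 1, brush)) > 0
    if (any(m) && config$min_subregion_area > 0) {
      lab <- label8(m)
      sizes <- tabulate(lab[lab > 0])
      m <- matrix(lab %in% which(sizes >= config$min_subregion_area),
                  image_dim[1], image_dim[2])
    }
    out[[lv]] <- m
  }
  out
}
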