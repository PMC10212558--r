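#' Split a section image into overlapping tiles
#'
#' Tiles are `tile_px` square with stride `tile_px - 2 * overlap_px`; the
#' last tile along each axis is anchored to the image edge (overlapping its
#' neighbour by more than `overlap_px` where needed), so the union of tiles
#' covers the image exactly. Images smaller than one tile are padded at the
#' bottom/right with `pad_value`.
#'
#' @param image Numeric matrix (grayscale section).
#' @param config A [tile_config()].
#' @param pad_value Intensity for padding; defaults to the image median.
#' @return List with one element per tile: `list(tile, origin)` where
#'   `origin` is the 0-based `(row, col)` offset of the tile in the (padded)
#'   image. The attribute `padded_dim` carries the padded image size.
#' @export
tile_image <- function(image, config = tile_config(),
                       pad_value = stats::median(image)) {
  t_px <- config$tile_px
  stride <- t_px - 2L * config$overlap_px
  dim0 <- dim(image)
  pad_dim <- pmax(dim0, t_px)
  if (any(pad_dim > dim0)) {
    padded <- matrix(pad_value, pad_dim[1], pad_dim[2])
    padded[seq_len(dim0[1]), seq_len(dim0[2])] <- image
    image <- padded
  }
  starts <- function(n) {
    s <- seq(0L, max(0L, n - t_px), by = stride)
    unique(c(s, n - t_px))
  }
  out <- list()
  for (r0 in starts(pad_dim[1])) for (c0 in starts(pad_dim[2])) {
    out[[length(out) + 1L]] <- list(
      tile = image[r0 + seq_len(t_px), c0 + seq_len(t_px)],
      origin = c(r0, c0))
  }
  attr(out, "padded_dim") <- pad_dim
  out
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a union-find pass over label adjacencies.
label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  pairs <- NULL
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]       # down-right diagonal
  sel <- a > 0 & b > 0 & a != b
  if (any(sel)) pairs <- cbind(a[sel], b[sel])
  a <- lab[-nr, -1]; b <- lab[-1, -nc]       # down-left diagonal
  sel <- a > 0 & b > 0 & a != b
  if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  if (is.null(pairs)) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(pairs))) {
    ri <- find(pairs[k, 1]); rj <- find(pairs[k, 2])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

#' Detect dark nucleus-like objects in a tile (reference detector)
#'
#' Classical reference implementation of the pluggable detector contract:
#' light Gaussian smoothing, thresholding at a fixed contrast below the tile
#' median (the local background), watershed splitting of touching blobs on
#' the distance map, and a minimum-area gate. Any function mapping a
#' grayscale tile to a boolean mask of the same shape satisfies the contract
#' and can be swapped in wherever a `detector` argument is accepted.
#'
#' @param tile Numeric matrix, 8-bit grayscale intensities (0--255).
#' @param min_area Discard detected components smaller than this (pixels).
#' @param min_contrast Pixels darker than `median(tile) - min_contrast`
#'   after smoothing are candidate nucleus pixels.
#' @param dark_floor If the tile median is below this the tile is considered
#'   unusable (all-dark): an empty mask is returned with a warning and the
#'   attribute `all_dark = TRUE`.
#' @param blur_sigma Gaussian smoothing sigma in pixels.
#' @param split_touching Carve watershed boundaries between touching blobs?
#' @return Logical matrix the size of `tile`.
#' @export
detect_nuclei <- function(tile, min_area = 5L, min_contrast = 20,
                          dark_floor = 30, blur_sigma = 1,
                          split_touching = TRUE) {
  med <- stats::median(tile)
  if (med < dark_floor) {
    warning("all-dark tile (median ", round(med, 1), " < floor ",
            dark_floor, "): returning empty mask")
    out <- matrix(FALSE, nrow(tile), ncol(tile))
    attr(out, "all_dark") <- TRUE
    return(out)
  }
  sm <- if (blur_sigma > 0)
    EBImage::imageData(EBImage::gblur(tile, sigma = blur_sigma,
                                      boundary = "replicate")) else tile
  mask <- sm < (med - min_contrast)
  if (!any(mask)) return(mask)
  if (split_touching) {
    ws <- EBImage::imageData(
      EBImage::watershed(EBImage::distmap(mask * 1), tolerance = 1))
    # carve a clean cut along every basin-basin contact
    nr <- nrow(ws); nc <- ncol(ws)
    cut <- matrix(FALSE, nr, nc)
    mark <- function(ia, ja, ib, jb) {
      a <- ws[ia, ja]; b <- ws[ib, jb]
      sel <- a > 0 & b > 0 & a != b
      m <- matrix(FALSE, nr, nc)
      m[ia, ja][sel] <- TRUE
      m[ib, jb][sel] <- TRUE
      m
    }
    cut <- cut | mark(1:(nr - 1), 1:nc, 2:nr, 1:nc)
    cut <- cut | mark(1:nr, 1:(nc - 1), 1:nr, 2:nc)
    mask <- mask & !cut
  }
  if (min_area > 1 && any(mask)) {
    lab <- label8(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_area)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  mask
}

#' Stitch tile masks into a section mask
#'
#' Combines per-tile boolean masks by pixelwise logical OR at their origins;
#' stitching is order-independent and idempotent.
#'
#' @param masks List of logical matrices.
#' @param origins List (or matrix rows) of 0-based `(row, col)` offsets.
#' @param image_dim Integer length-2 size of the output mask.
#' @return Logical matrix of size `image_dim`.
#' @export
stitch_masks <- function(masks, origins, image_dim) {
  stopifnot(length(masks) == length(origins))
  out <- matrix(FALSE, image_dim[1], image_dim[2])
  for (i in seq_along(masks)) {
    o <- origins[[i]]
    dm <- dim(masks[[i]])
    if (any(o < 0) || o[1] + dm[1] > image_dim[1] || o[2] + dm[2] > image_dim[2])
      stop("tile offset (", o[1], ",", o[2], ") outside image")
    rows <- o[1] + seq_len(dm[1]); cols <- o[2] + seq_len(dm[2])
    out[rows, cols] <- out[rows, cols] | masks[[i]]
  }
  out
}

#' Detect nuclei across a whole section
#'
#' Tiles the section, runs the detector on each tile, and stitches the tile
#' masks by logical OR. Detections falling in the padding of an undersized
#' image are clipped.
#'
#' @param image Numeric matrix, grayscale section.
#' @param config A [tile_config()].
#' @param detector Function `(tile, ...) -> logical mask`; defaults to the
#'   reference [detect_nuclei()].
#' @param ... Passed on to `detector`.
#' @return Logical section mask, same size as `image`.
#' @export
detect_section <- function(image, config = tile_config(),
                           detector = detect_nuclei, ...) {
  tiles <- tile_image(image, config)
  masks <- lapply(tiles, function(t) detector(t$tile, ...))
  origins <- lapply(tiles, `[[`, "origin")
  full <- stitch_masks(masks, origins, attr(tiles, "padded_dim"))
  full[seq_len(nrow(image)), seq_len(ncol(image)), drop = FALSE]
}

#' Extract per-cell morphology from a section mask
#'
#' One record per 8-connected component: centroid (pixels), area (pixels),
#' perimeter (pixels), and the circle-equivalent diameter in micrometers,
#' `2 * sqrt(area / pi) * pixel_size`.
#'
#' @param mask Logical section mask.
#' @param section_index 0-based section index recorded on every row.
#' @param optics An [optical_model()] (for the pixel size).
#' @return Data frame with columns `section_index`, `centroid_row`,
#'   `centroid_col`, `area_px`, `perimeter_px`, `equivalent_diameter_um`,
#'   `radius_um`.
#' @export
extract_cells <- function(mask, section_index = 0L,
                          optics = optical_model()) {
  empty <- data.frame(section_index = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_px = numeric(0),
                      perimeter_px = numeric(0),
                      equivalent_diameter_um = numeric(0),
                      radius_um = numeric(0))
  if (!any(mask)) return(empty)
  lab <- label8(mask)
  mom <- EBImage::computeFeatures.moment(lab)
  shp <- EBImage::computeFeatures.shape(lab)
  eq_d <- 2 * sqrt(shp[, "s.area"] / pi) * optics$pixel_size
  out <- data.frame(section_index = as.integer(section_index),
                    centroid_row = mom[, "m.cx"],
                    centroid_col = mom[, "m.cy"],
                    area_px = shp[, "s.area"],
                    perimeter_px = shp[, "s.perimeter"],
                    equivalent_diameter_um = eq_d,
                    radius_um = eq_d / 2)
  rownames(out) <- NULL
  out
}

#' Run detection over a stack of sections
#'
#' @param images List of section image matrices (index 1 = section 0).
#' @param config A [tile_config()].
#' @param optics An [optical_model()].
#' @param detector Detector function, see [detect_section()].
#' @param ... Passed on to the detector.
#' @return List with `cells` (row-bound [extract_cells()] tables) and
#'   `masks` (list of section masks).
#' @export
detect_brain <- function(images, config = tile_config(),
                         optics = optical_model(),
                         detector = detect_nuclei, ...) {
  masks <- vector("list", length(images))
  cells <- vector("list", length(images))
  for (s in seq_along(images)) {
    masks[[s]] <- detect_section(images[[s]], config, detector, ...)
    cells[[s]] <- extract_cells(masks[[s]], section_index = s - 1L, optics)
  }
  list(cells = do.call(rbind, cells), masks = masks)
}
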