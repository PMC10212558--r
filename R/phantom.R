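#' Specify one phantom brain region
#'
#' A region is an axis-aligned 3D primitive (box or ellipsoid) placed in
#' micrometer coordinates, populated by a homogeneous Poisson process of
#' spherical "nuclei" at a given volumetric density. `x` runs left-right
#' across the section (columns), `y` top-bottom (rows), and `z` along the
#' anterior-posterior axis (across sections).
#'
#' @param region_id Unique positive integer label (also used in label
#'   rasters).
#' @param acronym Short region name.
#' @param shape `"box"` or `"ellipsoid"`.
#' @param center Numeric length-3, region center `(x, y, z)` in micrometers.
#' @param half_size Numeric length-3: half edge lengths (box) or semi-axes
#'   (ellipsoid), micrometers.
#' @param density True cell density, cells/mm^3.
#' @param radius_mean,radius_sd Mean and SD of nucleus radii (micrometers);
#'   radii are sampled from a normal truncated at 0.5 um.
#' @param parent_id,level Region-hierarchy bookkeeping.
#' @param density_mult Optional `function(strain, sex, hemisphere)` returning
#'   a multiplicative factor applied to `density` when a phantom brain of
#'   that group is generated (seeded dimorphism / laterality).
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(region_id, acronym = paste0("R", region_id),
                        shape = c("box", "ellipsoid"),
                        center, half_size, density,
                        radius_mean = 4, radius_sd = 0.25,
                        parent_id = 0L, level = 1L, density_mult = NULL) {
  shape <- match.arg(shape)
  stopifnot(length(center) == 3, length(half_size) == 3,
            all(half_size > 0), density >= 0, radius_mean > 0,
            radius_sd >= 0, region_id >= 1)
  structure(list(region_id = as.integer(region_id), acronym = acronym,
                 shape = shape, center = as.numeric(center),
                 half_size = as.numeric(half_size), density = density,
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 parent_id = as.integer(parent_id), level = as.integer(level),
                 density_mult = density_mult),
            class = "region_spec")
}

#' Mirror a region specification across the brain midline
#'
#' Returns a copy of `spec` reflected about the vertical midline plane
#' `x = field_width / 2`, keeping the same `region_id`. Used to build
#' bilaterally symmetric phantoms.
#'
#' @param spec A [region_spec()].
#' @param field_width Width of the phantom field of view along `x`,
#'   micrometers.
#' @return A `region_spec` for the contralateral copy.
#' @export
mirror_spec <- function(spec, field_width) {
  out <- spec
  out$center[1] <- field_width - spec$center[1]
  out
}

# Analytic volume of a region primitive, mm^3.
spec_volume_mm3 <- function(spec) {
  v_um3 <- switch(spec$shape,
    box = prod(2 * spec$half_size),
    ellipsoid = 4 / 3 * pi * prod(spec$half_size))
  v_um3 * 1e-9
}

spec_bbox <- function(spec) {
  rbind(lo = spec$center - spec$half_size, hi = spec$center + spec$half_size)
}

bboxes_overlap <- function(a, b) {
  all(a["lo", ] < b["hi", ] & b["lo", ] < a["hi", ])
}

# In-plane (chord) radius of a sphere of radius r whose center lies dz away
# from the optical plane, given depth of field dof. NA when not visible.
apparent_radius <- function(radius, dz, dof) {
  visible <- abs(dz) <= radius + dof / 2
  eff <- pmax(0, abs(dz) - dof / 2)
  r <- sqrt(pmax(0, radius^2 - eff^2))
  r[!visible] <- NA_real_
  r
}

# Uniform points inside a spec's primitive (rejection sampling for
# ellipsoids).
sample_points_in_spec <- function(spec, n) {
  if (n == 0)
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z"))))
  draw <- function(m) {
    p <- matrix(runif(3 * m, -1, 1), ncol = 3)
    sweep(sweep(p, 2, spec$half_size, "*"), 2, spec$center, "+")
  }
  if (spec$shape == "box") {
    pts <- draw(n)
  } else {
    pts <- matrix(numeric(0), ncol = 3)
    while (nrow(pts) < n) {
      cand <- draw(2 * n)
      u <- sweep(sweep(cand, 2, spec$center, "-"), 2, spec$half_size, "/")
      pts <- rbind(pts, cand[rowSums(u^2) <= 1, , drop = FALSE])
    }
    pts <- pts[seq_len(n), , drop = FALSE]
  }
  colnames(pts) <- c("x", "y", "z")
  pts
}

# Sequential hard-core thinning on lateral (x, y) distance.
thin_min_distance <- function(cells, min_distance) {
  if (min_distance <= 0 || nrow(cells) < 2) return(cells)
  keep <- logical(nrow(cells))
  kx <- ky <- numeric(0)
  for (i in seq_len(nrow(cells))) {
    if (!length(kx) ||
        min((kx - cells$x[i])^2 + (ky - cells$y[i])^2) >= min_distance^2) {
      keep[i] <- TRUE
      kx <- c(kx, cells$x[i]); ky <- c(ky, cells$y[i])
    }
  }
  cells[keep, , drop = FALSE]
}

# Rasterize region labels at one z plane: integer matrix [row, col].
rasterize_labels <- function(specs, plane_z, optics, dim_px) {
  lab <- matrix(0L, dim_px[1], dim_px[2])
  xs <- (seq_len(dim_px[2]) - 0.5) * optics$pixel_size
  ys <- (seq_len(dim_px[1]) - 0.5) * optics$pixel_size
  for (spec in specs) {
    hz <- spec$half_size[3]
    if (abs(plane_z - spec$center[3]) > hz) next
    if (spec$shape == "box") {
      rows <- which(abs(ys - spec$center[2]) <= spec$half_size[2])
      cols <- which(abs(xs - spec$center[1]) <= spec$half_size[1])
      if (length(rows) && length(cols)) lab[rows, cols] <- spec$region_id
    } else {
      uz2 <- ((plane_z - spec$center[3]) / hz)^2
      if (uz2 > 1) next
      uy2 <- ((ys - spec$center[2]) / spec$half_size[2])^2
      ux2 <- ((xs - spec$center[1]) / spec$half_size[1])^2
      inside <- outer(uy2, ux2, "+") <= 1 - uz2
      lab[inside] <- spec$region_id
    }
  }
  lab
}

#' Render one phantom section image
#'
#' Draws every cell whose slab contains the plane: a sphere of radius `r`
#' centred `dz` from the optical plane is visible iff
#' `|dz| <= r + depth_of_field / 2`, and is rendered as a dark disk of
#' apparent (chord) radius `sqrt(r^2 - max(0, |dz| - d/2)^2)`. Intensities
#' are `background_level` outside cells and `nucleus_level` inside, with
#' optional additive Gaussian noise (clamped to 0--255 and rounded).
#'
#' @param cells Data frame with columns `x`, `y`, `z` (micrometers) and
#'   `radius` (micrometers). An empty data frame gives a uniform background.
#' @param plane_z Axial position of the optical plane, micrometers.
#' @param optics An [optical_model()].
#' @param dim_px Integer length-2, image size `(rows, cols)`.
#' @param noise Add Gaussian pixel noise of sd `optics$noise_sd`?
#' @return Numeric matrix of integers in 0--255.
#' @export
render_section <- function(cells, plane_z, optics, dim_px, noise = TRUE) {
  img <- matrix(optics$background_level, dim_px[1], dim_px[2])
  if (nrow(cells)) {
    r_app <- apparent_radius(cells$radius, cells$z - plane_z,
                             optics$depth_of_field)
    vis <- which(!is.na(r_app) & r_app > 0)
    ps <- optics$pixel_size
    for (i in vis) {
      # pixel centres are at ((row - 0.5) ps, (col - 0.5) ps)
      rc <- cells$y[i] / ps + 0.5
      cc <- cells$x[i] / ps + 0.5
      rad <- r_app[i] / ps
      rows <- max(1, floor(rc - rad)):min(dim_px[1], ceiling(rc + rad))
      cols <- max(1, floor(cc - rad)):min(dim_px[2], ceiling(cc + rad))
      if (!length(rows) || !length(cols)) next
      d2 <- outer((rows - rc)^2, (cols - cc)^2, "+")
      img[rows, cols][d2 <= rad^2] <- optics$nucleus_level
    }
  }
  if (noise && optics$noise_sd > 0) {
    img <- img + matrix(rnorm(length(img), 0, optics$noise_sd),
                        nrow(img), ncol(img))
  }
  matrix(pmin(255, pmax(0, round(img))), nrow(img), ncol(img))
}

#' Project ground-truth cells onto section planes
#'
#' For every section plane, lists the cells visible in that section (slab
#' rule `|dz| <= r + d/2`) with their apparent in-plane radius and pixel
#' coordinates. This is the ground-truth counterpart of the detection stage
#' and lets the quantification estimator be tested with detection bypassed.
#'
#' @param cells Data frame with `cell_id`, `region_id`, `x`, `y`, `z`,
#'   `radius` (micrometers).
#' @param z_planes Numeric vector of section plane positions, micrometers.
#' @param optics An [optical_model()].
#' @return Data frame with one row per visible (cell, section) pair:
#'   `section_index` (0-based), `cell_id`, `region_id`, `centroid_row`,
#'   `centroid_col` (pixels), `radius_um` (apparent), `radius_true_um`,
#'   `equivalent_diameter_um`.
#' @export
project_cells_to_sections <- function(cells, z_planes, optics) {
  out <- vector("list", length(z_planes))
  for (s in seq_along(z_planes)) {
    r_app <- apparent_radius(cells$radius, cells$z - z_planes[s],
                             optics$depth_of_field)
    vis <- which(!is.na(r_app))
    out[[s]] <- data.frame(
      section_index = s - 1L,
      cell_id = cells$cell_id[vis],
      region_id = cells$region_id[vis],
      centroid_row = cells$y[vis] / optics$pixel_size + 0.5,
      centroid_col = cells$x[vis] / optics$pixel_size + 0.5,
      radius_um = r_app[vis],
      radius_true_um = cells$radius[vis],
      equivalent_diameter_um = 2 * r_app[vis])
  }
  do.call(rbind, out)
}

#' Generate a phantom brain with full ground truth
#'
#' Places cells in each region by a homogeneous Poisson process at the
#' group-adjusted density, then renders coronal sections every
#' `optics$section_gap` micrometers (planes at `z = 0, gap, 2*gap, ...` up to
#' the field depth) together with pixel-aligned integer label rasters.
#'
#' @param specs List of [region_spec()] objects. Regions with different ids
#'   must not overlap (bounding boxes are checked).
#' @param optics An [optical_model()].
#' @param field_um Numeric length-3 `(x, y, z)` extent of the imaged field in
#'   micrometers. Defaults to the tight bounding box of all regions.
#' @param strain,sex,batch Cohort tags passed to each region's
#'   `density_mult`.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param render Render grayscale section images? Label rasters and ground
#'   truth are produced either way; skipping rendering is useful when only
#'   the geometry and true cells are needed.
#' @param noise Add pixel noise when rendering.
#' @param min_distance Optional hard-core lateral (x, y) distance between
#'   retained cells, micrometers: cells closer than this to an earlier kept
#'   cell are thinned. Used to build benchmark sections whose disks do not
#'   overlap; 0 (default) keeps the pure Poisson process.
#' @return An object of class `phantom_brain`: list with `images` (NULL if
#'   `render = FALSE`), `labels`, `z_um`, `truth` (`$regions`, `$cells`),
#'   `hierarchy`, `optics`, and `meta`.
#' @export
generate_phantom_brain <- function(specs, optics = optical_model(),
                                   field_um = NULL,
                                   strain = "C57BL/6J", sex = "M",
                                   batch = 1L, seed = 1L,
                                   render = TRUE, noise = TRUE,
                                   min_distance = 0) {
  if (inherits(specs, "region_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1)
  bbs <- lapply(specs, spec_bbox)
  n <- length(specs)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (bboxes_overlap(bbs[[i]], bbs[[j]]))
        stop("region shapes overlap (ambiguous labels): ids ",
             specs[[i]]$region_id, " and ", specs[[j]]$region_id)
    }
  }
  if (is.null(field_um)) {
    hi <- apply(do.call(rbind, lapply(bbs, function(b) b["hi", ])), 2, max)
    field_um <- hi
  }
  stopifnot(length(field_um) == 3, all(field_um > 0))
  dim_px <- c(ceiling(field_um[2] / optics$pixel_size),
              ceiling(field_um[1] / optics$pixel_size))
  z_planes <- seq(0, field_um[3], by = optics$section_gap)
  midline_x <- field_um[1] / 2

  with_seed(seed, {
    cell_list <- vector("list", n)
    reg_rows <- vector("list", n)
    for (i in seq_len(n)) {
      sp <- specs[[i]]
      hemi <- if (sp$center[1] < midline_x) "left" else "right"
      mult <- if (is.null(sp$density_mult)) 1
              else sp$density_mult(strain, sex, hemi)
      v_mm3 <- spec_volume_mm3(sp)
      lambda <- sp$density * mult * v_mm3
      ncell <- if (lambda > 0) rpois(1, lambda) else 0L
      pts <- sample_points_in_spec(sp, ncell)
      radii <- if (ncell > 0)
        pmax(0.5, rnorm(ncell, sp$radius_mean, sp$radius_sd)) else numeric(0)
      cell_list[[i]] <- data.frame(region_id = rep(sp$region_id, ncell),
                                   x = pts[, "x"], y = pts[, "y"],
                                   z = pts[, "z"], radius = radii)
      # expected in-plane covered fraction for an interior section
      slab_um <- 2 * sp$radius_mean + optics$depth_of_field
      cover <- sp$density * mult * 1e-9 * slab_um * pi * sp$radius_mean^2
      if (cover > 0.5)
        warning("region ", sp$acronym, ": expected disk coverage ",
                round(100 * cover), "% of section area; ",
                "overlapping disks will dominate")
      reg_rows[[i]] <- data.frame(
        region_id = sp$region_id, acronym = sp$acronym,
        hemisphere = hemi, volume_mm3 = v_mm3,
        density_seeded = sp$density * mult, stringsAsFactors = FALSE)
    }
    cells <- do.call(rbind, cell_list)
    cells <- thin_min_distance(cells, min_distance)
    cells$cell_id <- seq_len(nrow(cells))

    labels <- lapply(z_planes, function(z)
      rasterize_labels(specs, z, optics, dim_px))
    images <- NULL
    if (render) {
      images <- lapply(z_planes, function(z)
        render_section(cells, z, optics, dim_px, noise = noise))
    }

    regions <- do.call(rbind, reg_rows)
    agg <- if (nrow(cells))
      stats::aggregate(list(count = cells$region_id),
                       by = list(region_id = cells$region_id), length)
    else data.frame(region_id = integer(0), count = integer(0))
    # bilateral (mirrored) specs share a region_id: collapse to one row
    regions <- do.call(rbind, lapply(split(regions, regions$region_id),
      function(d) data.frame(region_id = d$region_id[1],
                             acronym = d$acronym[1],
                             volume_mm3 = sum(d$volume_mm3),
                             density_seeded = mean(d$density_seeded),
                             stringsAsFactors = FALSE)))
    regions$count <- agg$count[match(regions$region_id, agg$region_id)]
    regions$count[is.na(regions$count)] <- 0L
    regions$density_true <- regions$count / regions$volume_mm3

    hier_rows <- lapply(specs, function(sp)
      data.frame(region_id = sp$region_id, parent_id = sp$parent_id,
                 acronym = sp$acronym, level = sp$level))
    hierarchy <- unique(do.call(rbind, hier_rows))

    structure(list(images = images, labels = labels, z_um = z_planes,
                   truth = list(regions = regions, cells = cells),
                   hierarchy = hierarchy, optics = optics,
                   meta = list(strain = strain, sex = sex,
                               batch = as.integer(batch), seed = seed,
                               field_um = field_um, dim_px = dim_px,
                               midline_x = midline_x)),
              class = "phantom_brain")
  })
}

#' @export
print.phantom_brain <- function(x, ...) {
  cat("phantom_brain:", length(x$z_um), "sections of",
      paste(x$meta$dim_px, collapse = " x "), "px,",
      nrow(x$truth$cells), "cells in",
      nrow(x$truth$regions), "regions\n")
  invisible(x)
}
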