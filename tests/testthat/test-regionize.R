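test_that("cells are assigned by raster lookup with a right-tie midline", {
  lab <- matrix(0L, 20, 20)
  lab[5:15, 3:9] <- 101L     # left-side region
  lab[5:15, 12:18] <- 102L   # right-side region
  cells <- data.frame(section_index = 0L,
                      centroid_row = c(10, 10, 10, 10.5, 2),
                      centroid_col = c(5, 15, 10.5, 10.5, 2),
                      radius_um = 2)
  out <- assign_cells_to_regions(cells, lab)
  # raster lookup
  expect_equal(out$region_id[out$centroid_col == 5], 101L)
  expect_equal(out$region_id[out$centroid_col == 15], 102L)
  # cell exactly on the midline column (ncol 20 -> mid 10.5): right
  expect_true(all(out$hemisphere[out$centroid_col == 10.5] == "right"))
  expect_equal(out$hemisphere[out$centroid_col == 5], "left")
  # unannotated cell dropped, conservation audit kept
  expect_equal(nrow(out) + attr(out, "n_dropped"), nrow(cells))
  expect_equal(attr(out, "n_dropped"),
               2L + sum(cells$centroid_col == 10.5 &
                          cells$centroid_row == 10))  # midline col label 0
})

test_that("phantom cells away from borders are assigned to their true region", {
  left <- region_spec(7, "L7", "box", center = c(60, 60, 60),
                      half_size = c(40, 40, 66), density = 2e5)
  specs <- list(left, mirror_spec(left, 240))
  opt <- optical_model(pixel_size = 1)
  ph <- generate_phantom_brain(specs, opt, field_um = c(240, 120, 120),
                               seed = 2, render = FALSE)
  proj <- project_cells_to_sections(ph$truth$cells, ph$z_um, opt)
  out <- assign_cells_to_regions(proj, ph$labels)
  # drop cells within 2 px of the region border in-plane
  interior <- with(out, abs(centroid_col - 60) < 38 / opt$pixel_size |
                        abs(centroid_col - 180) < 38 / opt$pixel_size)
  interior <- interior & abs(out$centroid_row - 60) < 38 / opt$pixel_size
  expect_true(all(out$region_id[interior] == 7L))
  # hemisphere agrees with the generating side
  expect_true(all(out$hemisphere[interior & out$centroid_col < 120] == "left"))
})

test_that("raster/image shape mismatch is an error", {
  cells <- data.frame(section_index = 1L, centroid_row = 5, centroid_col = 5,
                      radius_um = 2)
  expect_error(assign_cells_to_regions(cells, matrix(0L, 10, 10)),
               "section_index")
})

test_that("coverage counts mask pixels in a clipped window", {
  cfg <- coverage_config(window_px = 64)
  empty <- matrix(FALSE, 200, 200)
  expect_equal(coverage(empty, cbind(100, 100), cfg), 0L)
  # saturated mask, interior centroid: the full window
  full <- matrix(TRUE, 200, 200)
  expect_equal(coverage(full, cbind(100, 100), cfg), 64L^2)
  # border centroid: clipped, not rescaled
  expect_lt(coverage(full, cbind(1, 100), cfg), 64L^2)
  # a single 80-px cell well inside its own window counts exactly 80
  m <- matrix(FALSE, 200, 200); m[96:105, 96:103] <- TRUE  # 10 x 8 = 80 px
  expect_equal(coverage(m, cbind(100, 100), cfg), 80L)
  # agreement with a direct double-loop count on a random mask
  set.seed(4)
  rm <- matrix(runif(100 * 100) < 0.2, 100, 100)
  pts <- cbind(sample(100, 20), sample(100, 20))
  direct <- vapply(seq_len(20), function(i) {
    r <- pts[i, 1]; c2 <- pts[i, 2]
    sum(rm[max(1, r - 32):min(100, r + 31), max(1, c2 - 32):min(100, c2 + 31)])
  }, numeric(1))
  expect_equal(coverage(rm, pts, cfg), as.integer(direct))
})

test_that("1D 2-means split matches the optimal threshold partition", {
  cov1 <- c(10, 12, 11, 300, 310, 305)
  split <- split_dense_sparse(cov1)
  expect_equal(as.character(split),
               c("sparse", "sparse", "sparse", "dense", "dense", "dense"))
  expect_identical(split, bf_threshold_split(cov1))
  # property: k-means equals brute-force threshold partition on random data
  set.seed(7)
  for (i in 1:20) {
    x <- round(c(rnorm(30, 50, 15), rnorm(30, 200, 30)))
    expect_identical(split_dense_sparse(x, seed = i), bf_threshold_split(x))
  }
  # dense cluster always has the higher mean coverage
  x <- runif(50, 0, 1000)
  sp <- split_dense_sparse(x)
  expect_gt(mean(x[sp == "dense"]), mean(x[sp == "sparse"]))
})

test_that("degenerate coverage values produce no split", {
  expect_warning(sp <- split_dense_sparse(c(5, 5, 5)), "identical")
  expect_true(all(sp == "sparse"))
})

test_that("a dense band inside a sparse region is recovered by the split", {
  # CA1-like composite: a dense pyramidal-like band (6e5 cells/mm^3)
  # embedded on all in-plane sides in sparse strata (1e5), so coverage
  # windows are filled with tissue as they are in real sections.
  opt <- optical_model(pixel_size = 2, noise_sd = 0)
  specs <- list(
    region_spec(2, "SP", "box", center = c(300, 375, 30),
                half_size = c(150, 125, 36), density = 6e5),
    region_spec(1, "SOt", "box", center = c(300, 125, 30),
                half_size = c(300, 125, 36), density = 1e5),
    region_spec(3, "SOb", "box", center = c(300, 625, 30),
                half_size = c(300, 125, 36), density = 1e5),
    region_spec(4, "SOl", "box", center = c(75, 375, 30),
                half_size = c(75, 125, 36), density = 1e5),
    region_spec(5, "SOr", "box", center = c(525, 375, 30),
                half_size = c(75, 125, 36), density = 1e5))
  ph <- generate_phantom_brain(specs, opt, field_um = c(600, 750, 60),
                               seed = 2, render = TRUE, noise = FALSE)
  mask <- ph$images[[1]] < 80
  proj <- project_cells_to_sections(ph$truth$cells, ph$z_um, opt)
  proj <- proj[proj$section_index == 0, ]
  cov <- coverage(mask, cbind(proj$centroid_row, proj$centroid_col),
                  coverage_config())
  cl <- split_dense_sparse(cov)
  band <- proj$region_id == 2
  expect_gte(mean(cl[band] == "dense"), 0.9)
  expect_lte(mean(cl[proj$region_id != 2] == "dense"), 0.05)
})

test_that("subregion masks merge near cells and drop outliers", {
  cfg <- coverage_config(min_subregion_area = 5, closing_radius = 3)
  # two cells 1 px apart close into one component
  pts <- rbind(c(50, 50), c(50, 52), c(50, 54), c(52, 51), c(48, 52))
  masks <- subregion_masks(pts, rep("dense", 5), c(100, 100), cfg)
  expect_equal(max(cytoarch:::label8(masks$dense)), 1)
  # one far outlier cell removed by the size filter
  pts2 <- rbind(pts, c(5, 5))
  masks2 <- subregion_masks(pts2, rep("dense", 6), c(100, 100), cfg)
  expect_false(masks2$dense[5, 5])
  expect_equal(max(cytoarch:::label8(masks2$dense)), 1)
})
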