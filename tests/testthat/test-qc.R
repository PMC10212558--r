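test_that("gray-matter brightness is a pooled median over sections", {
  img1 <- matrix(120, 10, 10); img2 <- matrix(20, 10, 10)
  mask <- matrix(TRUE, 10, 10)
  expect_equal(median_gray_brightness(list(img1), list(mask)), 120)
  # half pixels 20, half 30: even-n median is the middle-pair mean
  img3 <- matrix(c(rep(20, 50), rep(30, 50)), 10, 10)
  expect_equal(median_gray_brightness(list(img3), list(mask)), 25)
  # pooled across sections
  expect_equal(median_gray_brightness(list(img1, img2), list(mask, mask)), 70)
  # label rasters work as masks; empty mask errors
  expect_equal(median_gray_brightness(list(img1), list(matrix(1L, 10, 10))),
               120)
  expect_error(median_gray_brightness(list(img1),
                                      list(matrix(FALSE, 10, 10))), "empty")
  expect_error(median_gray_brightness(list(img1), list(matrix(TRUE, 5, 5))),
               "mismatch")
})

test_that("phantom background brightness passes the dark-brain rule", {
  sp <- region_spec(1, "B", "box", center = c(50, 50, 50),
                    half_size = c(45, 45, 56), density = 1e5)
  ph <- generate_phantom_brain(sp, optical_model(pixel_size = 1),
                               field_um = c(100, 100, 100), seed = 8)
  b <- median_gray_brightness(ph$images, ph$labels)
  expect_lt(abs(b - 120), 2)
  expect_true(filter_dark_brains(b))
})

test_that("the dark-brain threshold is a strict inequality at 25", {
  keep <- filter_dark_brains(c(a = 24.9, b = 25, c = 20, d = 120))
  expect_identical(unname(keep), c(FALSE, TRUE, FALSE, TRUE))
})

test_that("robust outlier flags use MAD-scaled SDs, one-sided", {
  # zero-MAD region: degenerate, warned, no flags
  counts <- matrix(100, 4, 1, dimnames = list(letters[1:4], "r1"))
  expect_warning(fl <- robust_outlier_regions(counts), "zero MAD")
  expect_false(any(fl))
  # hand computation: median 10.5, MAD 1.0, robust SD 1.4826,
  # threshold 10.5 + 3 * 1.4826 = 14.95: only the 50 is flagged
  x <- c(10, 11, 9, 12, 10, 50)
  counts2 <- matrix(x, 6, 1, dimnames = list(letters[1:6], "r1"))
  fl2 <- robust_outlier_regions(counts2)
  expect_identical(unname(fl2[, 1]), x > 14.948)
  # one-sided: a low outlier is never flagged
  counts3 <- matrix(c(10, 11, 9, 12, 10, 0.1), 6, 1)
  expect_false(any(robust_outlier_regions(counts3)))
})

test_that("MAD * 1.4826 is a consistent estimator of the normal SD", {
  set.seed(99)
  x <- rnorm(2e5)
  expect_lt(abs(mad(x, constant = 1.4826) / sd(x) - 1), 0.01)
})

test_that("brains are discarded only beyond three outlier regions", {
  fl <- matrix(FALSE, 2, 10, dimnames = list(c("keep3", "drop4"), NULL))
  fl["keep3", 1:3] <- TRUE
  fl["drop4", 1:4] <- TRUE
  keep <- discard_artifact_brains(fl)
  expect_true(keep["keep3"])
  expect_false(keep["drop4"])
})

test_that("a seeded count-inflation artifact leads to brain discard", {
  sim <- simulate_cohort(n_regions = 40,
                         design = data.frame(strain = "C57BL/6J",
                                             sex = c("F", "M"), n = c(10, 10)),
                         artifact_brains = 1, artifact_regions = 5,
                         artifact_scale = 3, seed = 12)
  counts <- tapply(sim$cohort$N, list(sim$cohort$brain_id,
                                      sim$cohort$region_id), mean)
  keep <- discard_artifact_brains(robust_outlier_regions(counts))
  bad <- unique(sim$truth$artifact$brain_id)
  expect_false(keep[bad])
  expect_true(all(keep[setdiff(names(keep), bad)]))
})

test_that("region filters trigger the documented reasons", {
  mk <- function(V, N, NL, NR, brain = sprintf("b%d", seq_along(V)))
    data.frame(brain_id = brain, region_id = 1L, V_mm3 = V, N = N,
               N_left = NL, N_right = NR)
  cfg <- qc_config()
  # small volume
  m1 <- mk(rep(0.2, 5), rep(1000, 5), rep(500, 5), rep(500, 5))
  expect_match(filter_regions(m1, config = cfg)$reasons, "small_volume")
  # low count (median across per-brain totals when no section counts given)
  m2 <- mk(rep(1, 5), rep(400, 5), rep(200, 5), rep(200, 5))
  expect_match(filter_regions(m2, config = cfg)$reasons, "low_count")
  # hemispheric imbalance: 600 vs 400 -> 0.2 > 0.155
  m3 <- mk(rep(1, 5), rep(1000, 5), rep(600, 5), rep(400, 5))
  expect_match(filter_regions(m3, config = cfg)$reasons, "lr_imbalance")
  # clean region kept
  m4 <- mk(rep(1, 5), rep(1000, 5), rep(510, 5), rep(490, 5))
  expect_true(filter_regions(m4, config = cfg)$keep)
  # section-median count rule
  sc <- data.frame(region_id = 1L, n = rep(450, 20))
  expect_match(filter_regions(m4, section_counts = sc,
                              config = cfg)$reasons, "low_count")
})

test_that("brightness-correlated counts are excluded, independent ones kept", {
  set.seed(5)
  n <- 40
  bright <- setNames(runif(n, 60, 180), sprintf("b%d", 1:n))
  # region 1: counts track brightness; region 2: independent
  m <- rbind(
    data.frame(brain_id = names(bright), region_id = 1L, V_mm3 = 1,
               N = 1000 + 10 * bright + rnorm(n, 0, 50),
               N_left = 500, N_right = 500),
    data.frame(brain_id = names(bright), region_id = 2L, V_mm3 = 1,
               N = rnorm(n, 2000, 100), N_left = 500, N_right = 500))
  m$N_left <- m$N / 2; m$N_right <- m$N / 2
  res <- filter_regions(m, brightness = bright)
  expect_match(res$reasons[res$region_id == 1], "brightness_correlated")
  expect_true(res$keep[res$region_id == 2])
})

test_that("batch correction brings every batch median exactly to target", {
  # hand arithmetic: batch volumes {350, 360, 370} -> factor 380/360
  bc <- batch_correct_volumes(c(350, 360, 370), rep(1, 3))
  expect_equal(unname(bc$factors), 380 / 360)
  expect_equal(median(bc$corrected), 380)
  # a batch already at the target is untouched
  bc2 <- batch_correct_volumes(c(370, 380, 390), rep(1, 3))
  expect_equal(unname(bc2$factors), 1)
  expect_equal(bc2$corrected, c(370, 380, 390))
  # two batches with distinct medians both land on 380
  v <- c(340, 350, 360, 395, 400, 405)
  b <- c(1, 1, 1, 2, 2, 2)
  bc3 <- batch_correct_volumes(v, b)
  expect_equal(as.numeric(tapply(bc3$corrected, b, median)), c(380, 380))
})

test_that("batch correction rescales densities but never counts", {
  sim <- simulate_cohort(n_regions = 20,
                         design = data.frame(strain = "C57BL/6J",
                                             sex = c("F", "M"), n = c(6, 6)),
                         seed = 2)
  cohort <- sim$cohort
  out <- apply_batch_correction(cohort, sim$brains)
  expect_identical(out$metrics$N, cohort$N)
  expect_identical(out$metrics$N_left, cohort$N_left)
  # every batch's median total volume is exactly on target
  tot <- tapply(out$metrics$V, out$metrics$brain_id, sum)
  batch <- sim$brains$batch[match(names(tot), sim$brains$brain_id)]
  expect_equal(as.numeric(tapply(tot, batch, median)), rep(380, 3))
  # D = N / V after correction
  expect_equal(out$metrics$D, out$metrics$N / out$metrics$V)
})

test_that("QC decisions are invariant to brain order", {
  sim <- simulate_cohort(n_regions = 25,
                         design = data.frame(strain = "C57BL/6J",
                                             sex = c("F", "M"), n = c(8, 8)),
                         dark_brains = 2, artifact_brains = 1, seed = 17)
  res1 <- apply_qc(sim$cohort, sim$brains)
  perm <- sample(nrow(sim$cohort))
  res2 <- apply_qc(sim$cohort[perm, ], sim$brains[sample(nrow(sim$brains)), ])
  expect_setequal(res1$kept_brains, res2$kept_brains)
  expect_setequal(res1$kept_regions, res2$kept_regions)
  # dark brains were discarded
  expect_false(any(sim$brains$brain_id[1:2] %in% res1$kept_brains))
})

test_that("null phantom cohorts rarely trigger the outlier rule", {
  # one-sided 3-robust-SD rule: normal tail ~ 0.13%, allow Monte-Carlo slack
  rates <- sapply(1:5, function(s) {
    sim <- simulate_cohort(n_regions = 50,
                           design = data.frame(strain = "C57BL/6J",
                                               sex = c("F", "M"),
                                               n = c(15, 15)), seed = s)
    counts <- tapply(sim$cohort$N, list(sim$cohort$brain_id,
                                        sim$cohort$region_id), mean)
    mean(robust_outlier_regions(counts))
  })
  expect_lt(mean(rates), 0.01)
})
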