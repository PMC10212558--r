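test_that("rank-sum test matches exact enumeration of the U distribution", {
  # identical groups: p ~ 1, zero effect
  rs <- ranksum_test(c(1, 2, 3), c(1, 2, 3))
  expect_gt(rs$p_value, 0.99)
  expect_equal(rs$effect_pct, 0)
  # complete separation, m = n = 10: exact p for the extreme U
  rs2 <- ranksum_test(1:10, 11:20)
  expect_equal(rs2$p_value, bf_ranksum_p(1:10, 11:20), tolerance = 1e-9)
  expect_equal(rs2$p_value, 2 / choose(20, 10), tolerance = 1e-9)
  # random no-tie samples, m, n <= 10: exact agreement with enumeration
  set.seed(10)
  for (i in 1:10) {
    m <- sample(2:7, 1); n <- sample(2:7, 1)
    a <- rnorm(m); b <- rnorm(n, 0.5)
    expect_equal(ranksum_test(a, b)$p_value, bf_ranksum_p(a, b),
                 tolerance = 1e-9)
  }
  # effect sign and magnitude from medians
  expect_equal(ranksum_test(c(90, 100, 110), c(100, 110, 120))$effect_pct, 10)
  expect_error(ranksum_test(numeric(0), 1:3), "empty")
})

test_that("BH adjustment matches a first-principles implementation", {
  expect_equal(bh_adjust(0.03), 0.03)
  # hand computation: p = {.01, .02, .03, .04} -> all q = .04
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(bh_adjust(p), bf_bh(p), tolerance = 1e-12)
  }
  # q-values are monotone in p rank
  p <- runif(30)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("dimorphism screen recovers seeded effects and controls the null", {
  sim <- simulate_cohort(n_regions = 100,
                         design = data.frame(strain = "C57BL/6J",
                                             sex = c("F", "M"),
                                             n = c(40, 40)),
                         sex_density_regions = 1:5,
                         sex_density_effect = 0.15, seed = 3)
  volc <- dimorphism_screen(sim$cohort, "sex", "D")
  expect_true(all(volc$significant[volc$region_id %in% 1:5]))
  expect_equal(sum(volc$significant), 5)
  # effects are medians in percent, male relative to female
  expect_true(all(volc$effect_pct[1:5] > 5))
  # null cohort: at most 5% of regions reach q < 0.05
  sim0 <- simulate_cohort(n_regions = 100,
                          design = data.frame(strain = "C57BL/6J",
                                              sex = c("F", "M"),
                                              n = c(40, 40)), seed = 4)
  v0 <- dimorphism_screen(sim0$cohort, "sex", "D")
  expect_lte(sum(v0$q < 0.05, na.rm = TRUE), 5)
  # zero median difference gives zero effect regardless of spread
  g <- data.frame(region_id = 1, acronym = "r",
                  sex = rep(c("F", "M"), each = 5),
                  D = c(370, 375, 380, 385, 390, 300, 379, 380, 381, 460))
  expect_equal(dimorphism_screen(g, "sex", "D")$effect_pct, 0)
})

test_that("strain screen uses its own FDR threshold and reference level", {
  sim <- simulate_cohort(n_regions = 40,
                         design = data.frame(
                           strain = c("C57BL/6J", "C57BL/6J",
                                      "FVB.CD1", "FVB.CD1"),
                           sex = c("F", "M", "F", "M"),
                           n = c(15, 15, 15, 15)),
                         strain_density_regions = c(4, 9),
                         strain_density_effect = 0.2, seed = 8)
  volc <- dimorphism_screen(sim$cohort, "strain", "D")
  expect_true(all(volc$significant[volc$region_id %in% c(4, 9)]))
  expect_equal(attr(volc, "comparison")[["ref"]], "C57BL/6J")
})

test_that("laterality screen recovers a seeded left bias", {
  # hand arithmetic of the symmetric bias: (110 - 100) / 105 * 100
  g <- data.frame(region_id = 1, acronym = "r", V = 1,
                  D_left = 110, D_right = 100)
  lat1 <- laterality_screen(rbind(g, g), "D")
  expect_equal(lat1$median_bias_pct, 100 * 10 / 105)
  expect_equal(lat1$side, "left")
  sim <- simulate_cohort(n_regions = 30,
                         design = data.frame(strain = "C57BL/6J",
                                             sex = c("F", "M"),
                                             n = c(20, 20)),
                         lateral_regions = 7, lateral_effect = 0.10,
                         seed = 5)
  lat <- laterality_screen(sim$cohort, "D")
  r7 <- lat[lat$region_id == 7, ]
  expect_gt(r7$median_bias_pct, 5)
  expect_lt(r7$median_bias_pct, 15)
  expect_gt(r7$frac_left, 0.8)
  # unbiased regions: symmetric within noise
  expect_lt(max(abs(lat$median_bias_pct[lat$region_id != 7])), 5)
  expect_gt(min(lat$frac_left[lat$region_id != 7]), 0.2)
  expect_lt(max(lat$frac_left[lat$region_id != 7]), 0.8)
})

test_that("laterality screen applies volume and layer-acronym filters", {
  base <- data.frame(region_id = 1:3,
                     acronym = c("MOs1", "VISC2/3", "AUDv6b"),
                     V = c(1, 1, 1), D_left = 110, D_right = 100)
  cohort <- rbind(base, base)
  out <- laterality_screen(cohort, "D")
  expect_equal(out$acronym, "VISC2/3")   # layer 1 and 6b excluded
  cohort$V <- 0.01                       # all below the volume floor
  expect_equal(nrow(laterality_screen(cohort, "D")), 0)
})

test_that("SVM classifier ranks seeded dimorphic regions first", {
  sim <- simulate_cohort(n_regions = 30,
                         design = data.frame(strain = "C57BL/6J",
                                             sex = c("F", "M"),
                                             n = c(40, 40)),
                         sex_volume_regions = c(3, 17),
                         sex_volume_effect = 0.20, seed = 6)
  X <- tapply(sim$cohort$V, list(sim$cohort$brain_id, sim$cohort$acronym),
              mean)
  X <- matrix(X, nrow(X), dimnames = dimnames(X))
  y <- sim$brains$sex[match(rownames(X), sim$brains$brain_id)]
  fit <- svm_sex_classifier(X, y, stats_config(svm_repeats = 25), seed = 1)
  expect_setequal(fit$ranking$region[1:2], c("R003", "R017"))
  expect_gt(fit$accuracy_mean, 0.8)
  # duplicated rows leave the ranking order unchanged
  fit2 <- svm_sex_classifier(rbind(X, X), c(y, y),
                             stats_config(svm_repeats = 25), seed = 1)
  expect_equal(fit2$ranking$region[1:2], fit$ranking$region[1:2])
})

test_that("SVM accuracy is at chance for shuffled labels", {
  sim <- simulate_cohort(n_regions = 30,
                         design = data.frame(strain = "C57BL/6J",
                                             sex = c("F", "M"),
                                             n = c(40, 40)), seed = 9)
  X <- tapply(sim$cohort$V, list(sim$cohort$brain_id, sim$cohort$acronym),
              mean)
  X <- matrix(X, nrow(X), dimnames = dimnames(X))
  set.seed(10)
  y <- sample(rep(c("F", "M"), each = 40))
  fit <- svm_sex_classifier(X, y, stats_config(svm_repeats = 50), seed = 2)
  expect_lt(abs(fit$accuracy_mean - 0.5), 0.1)
})

test_that("the incremental feature curve rises from a separating feature", {
  set.seed(13)
  n <- 60
  X <- cbind(sep = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
             noise1 = rnorm(n), noise2 = rnorm(n))
  y <- rep(c("F", "M"), each = n / 2)
  curve <- incremental_feature_curve(X, y, c("sep", "noise1", "noise2"))
  expect_equal(curve$accuracy[1], 1)        # perfectly separating feature
  expect_equal(nrow(curve), 3)              # truncated at feature count
  # null features fluctuate near chance
  curve0 <- incremental_feature_curve(X[, 2:3], y, c("noise1", "noise2"))
  expect_lt(max(curve0$accuracy), 0.85)
})

test_that("volume-density correlation separates the two expansion regimes", {
  set.seed(14)
  n <- 80
  V <- rlnorm(n, log(1), 0.2)
  # fixed cell count: D = N0 / V -> strongly negative correlation
  fixedN <- data.frame(region_id = 1, acronym = "fixN", V = V, D = 2e5 / V)
  # fixed density: D independent of V -> near-zero correlation
  fixedD <- data.frame(region_id = 2, acronym = "fixD", V = V,
                       D = rlnorm(n, log(2e5), 0.2))
  vd <- volume_density_correlation(rbind(fixedN, fixedD))
  expect_lt(vd$r[vd$region_id == 1], -0.5)
  expect_lt(abs(vd$r[vd$region_id == 2]), 0.2)
  # perfectly linear relation: r = 1
  lin <- data.frame(region_id = 3, acronym = "lin", V = 1:10, D = 2 * (1:10))
  expect_equal(volume_density_correlation(lin)$r, 1)
})

test_that("the |r| = 0.14 significance boundary matches its q-level at n = 204", {
  # self-consistency of the correlation threshold via the t transform
  r <- 0.14; n <- 204
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(t), n - 2)
  expect_lt(p, 0.05)
  expect_gt(p, 0.04)
})

test_that("region similarity has exact invariants and block structure", {
  set.seed(15)
  brains <- 40
  latent1 <- rnorm(brains); latent2 <- rnorm(brains)
  M <- rbind(
    t(replicate(5, 2 + latent1 + rnorm(brains, 0, 0.4))),
    t(replicate(5, 5 + latent2 + rnorm(brains, 0, 0.4))))
  rownames(M) <- paste0("R", 1:10)
  sim <- region_similarity(M, top_n = 3)
  C <- sim$correlation
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, 10))
  within <- c(C[1:5, 1:5][upper.tri(diag(5))], C[6:10, 6:10][upper.tri(diag(5))])
  between <- as.vector(C[1:5, 6:10])
  expect_gt(mean(within), mean(between))
  # identical region vectors are mutual top neighbours with r = 1
  M2 <- rbind(M, R11 = M[1, ])
  sim2 <- region_similarity(M2, top_n = 1)
  nb <- sim2$neighbors
  expect_equal(nb$neighbor[nb$region == "R11"], "R1")
  expect_equal(nb$r[nb$region == "R11"], 1)
  expect_equal(dim(sim2$embedding), c(11, 2))
})
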