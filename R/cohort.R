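#' Simulate a cohort of per-brain regional metrics
#'
#' Draws a population table of per-brain, per-region volume (V, mm^3),
#' density (D, cells/mm^3), count (N = V * D) and left/right splits, with
#' the statistical structure the population analyses assume: lognormal
#' inter-individual variability, batch-level volume offsets, and optional
#' seeded sex, strain, and lateral effects in designated regions. This is
#' the desk-scale stand-in for running the full imaging pipeline over
#' hundreds of brains, and every seeded effect is returned as ground truth.
#'
#' Noise model per brain b and region r (all multiplicative, lognormal with
#' the requested coefficients of variation):
#' `V = V_r * batch_mult * sex/strain volume multipliers * e_V`,
#' `D_hemi = D_r * sex/strain density multipliers * (1 +/- lateral/2) * e_D * e_hemi`,
#' with `e_D` shared by both hemispheres (brain-level biology) and `e_hemi`
#' hemisphere-specific (technical noise). `N_hemi = D_hemi * V / 2`,
#' `N = N_L + N_R`, `D = N / V`.
#'
#' @param n_regions Number of regions.
#' @param design Data frame with columns `strain`, `sex`, `n`: one row per
#'   cohort group. The default is a two-strain, two-sex cohort of 40 brains
#'   per C57BL/6J sex and 20 per FVB.CD1 sex.
#' @param batch_volume_mult Multiplicative volume offsets of the acquisition
#'   batches (brains are assigned to batches cyclically). The defaults are
#'   the reciprocals of correction factors of about 1.064, 1.032, and 1.008.
#' @param volume_range,density_range Ranges (log-uniform for volume, uniform
#'   for density) from which the per-region base values are drawn, in mm^3
#'   and cells/mm^3.
#' @param sex_volume_regions,sex_volume_effect Regions whose volume is
#'   multiplied by `1 + effect` in males.
#' @param sex_density_regions,sex_density_effect As above, for density.
#' @param strain_density_regions,strain_density_effect Regions whose density
#'   is multiplied by `1 + effect` in the non-reference strain (second strain
#'   level of `design`).
#' @param lateral_regions,lateral_effect Regions with a left-hemisphere
#'   density excess: left gets `1 + effect/2`, right `1 - effect/2`.
#' @param cv_volume,cv_density Inter-individual coefficients of variation of
#'   per-region volume and density. The volume default matches the
#'   whole-gray-matter dispersion of real STPT cohorts (about 4.5%); the
#'   density default (8%) is the per-region residual dispersion at which a
#'   rank-sum screen at n = 40 per group reliably detects 15% effects at
#'   q < 0.01 -- the sensitivity regime this generator is designed to
#'   emulate. Real cohorts show larger whole-brain density dispersion
#'   (about 14%), so power on real data is lower at equal n.
#' @param cv_hemi Hemisphere-specific (technical) coefficient of variation.
#' @param target_volume Median whole-brain gray volume, mm^3; per-region base
#'   volumes are rescaled so that their sum equals this.
#' @param brightness_mean,brightness_sd Per-brain median gray brightness.
#' @param dark_brains Number of brains (taken from the start of the roster)
#'   whose brightness is forced to 20 (below the QC threshold).
#' @param artifact_brains Number of brains given a count-inflation artifact.
#' @param artifact_regions Number of regions inflated in each artifact brain.
#' @param artifact_scale Multiplicative count inflation of the artifact.
#' @param seed Integer seed.
#' @return List with `cohort` (long data frame: brain_id, strain, sex, batch,
#'   body_weight, brightness, region_id, acronym, V, D, N, V_left, V_right,
#'   N_left, N_right, D_left, D_right), `brains`, `regions`, and `truth`
#'   (the seeded effect regions and artifact assignments).
#' @export
simulate_cohort <- function(n_regions = 100,
                            design = data.frame(
                              strain = c("C57BL/6J", "C57BL/6J",
                                         "FVB.CD1", "FVB.CD1"),
                              sex = c("F", "M", "F", "M"),
                              n = c(40, 40, 20, 20)),
                            batch_volume_mult = c(1 / 1.064, 1 / 1.032,
                                                  1 / 1.008),
                            volume_range = c(0.1, 3),
                            density_range = c(1e5, 6e5),
                            sex_volume_regions = integer(0),
                            sex_volume_effect = 0.15,
                            sex_density_regions = integer(0),
                            sex_density_effect = 0.15,
                            strain_density_regions = integer(0),
                            strain_density_effect = 0.10,
                            lateral_regions = integer(0),
                            lateral_effect = 0.10,
                            cv_volume = 0.05, cv_density = 0.08,
                            cv_hemi = 0.03,
                            target_volume = 380,
                            brightness_mean = 120, brightness_sd = 5,
                            dark_brains = 0L, artifact_brains = 0L,
                            artifact_regions = 5L, artifact_scale = 3,
                            seed = 1L) {
  stopifnot(n_regions >= 1, all(design$n >= 1))
  with_seed(seed, {
    regions <- data.frame(
      region_id = seq_len(n_regions),
      acronym = sprintf("R%03d", seq_len(n_regions)),
      V_base = exp(runif(n_regions, log(volume_range[1]),
                         log(volume_range[2]))),
      D_base = runif(n_regions, density_range[1], density_range[2]))
    regions$V_base <- regions$V_base * target_volume / sum(regions$V_base)

    n_brains <- sum(design$n)
    brains <- data.frame(
      brain_id = sprintf("brain%03d", seq_len(n_brains)),
      strain = rep(design$strain, design$n),
      sex = rep(design$sex, design$n),
      batch = rep_len(seq_along(batch_volume_mult), n_brains))
    ref_strain <- design$strain[1]
    base_weight <- ifelse(brains$sex == "M", 26, 20) *
      ifelse(brains$strain == ref_strain, 1, 1.4)
    brains$body_weight <- round(base_weight * exp(rnorm(n_brains, 0, 0.08)), 1)
    brains$brightness <- round(rnorm(n_brains, brightness_mean,
                                     brightness_sd), 1)
    if (dark_brains > 0)
      brains$brightness[seq_len(dark_brains)] <- 20

    artifact <- NULL
    if (artifact_brains > 0) {
      ab <- sample(seq_len(n_brains), artifact_brains)
      artifact <- data.frame(
        brain_id = rep(brains$brain_id[ab], each = artifact_regions),
        region_id = as.integer(replicate(artifact_brains,
          sample(n_regions, artifact_regions))))
    }

    sdlog_v <- sqrt(log(1 + cv_volume^2))
    sdlog_d <- sqrt(log(1 + cv_density^2))
    sdlog_h <- sqrt(log(1 + cv_hemi^2))

    rows <- vector("list", n_brains)
    for (b in seq_len(n_brains)) {
      male <- brains$sex[b] == "M"
      alt_strain <- brains$strain[b] != ref_strain
      v_mult <- rep(1, n_regions)
      if (male) v_mult[sex_volume_regions] <-
        v_mult[sex_volume_regions] * (1 + sex_volume_effect)
      d_mult <- rep(1, n_regions)
      if (male) d_mult[sex_density_regions] <-
        d_mult[sex_density_regions] * (1 + sex_density_effect)
      if (alt_strain) d_mult[strain_density_regions] <-
        d_mult[strain_density_regions] * (1 + strain_density_effect)
      lat <- rep(0, n_regions)
      lat[lateral_regions] <- lateral_effect

      V <- regions$V_base * batch_volume_mult[brains$batch[b]] * v_mult *
        exp(rnorm(n_regions, 0, sdlog_v))
      D_core <- regions$D_base * d_mult * exp(rnorm(n_regions, 0, sdlog_d))
      D_L <- D_core * (1 + lat / 2) * exp(rnorm(n_regions, 0, sdlog_h))
      D_R <- D_core * (1 - lat / 2) * exp(rnorm(n_regions, 0, sdlog_h))
      N_L <- D_L * V / 2
      N_R <- D_R * V / 2
      rows[[b]] <- data.frame(
        brain_id = brains$brain_id[b], strain = brains$strain[b],
        sex = brains$sex[b], batch = brains$batch[b],
        body_weight = brains$body_weight[b],
        brightness = brains$brightness[b],
        region_id = regions$region_id, acronym = regions$acronym,
        V = V, N_left = N_L, N_right = N_R,
        V_left = V / 2, V_right = V / 2,
        D_left = D_L, D_right = D_R)
    }
    cohort <- do.call(rbind, rows)
    cohort$N <- cohort$N_left + cohort$N_right
    cohort$D <- cohort$N / cohort$V
    if (!is.null(artifact)) {
      key <- paste(cohort$brain_id, cohort$region_id)
      hit <- key %in% paste(artifact$brain_id, artifact$region_id)
      for (col in c("N", "N_left", "N_right", "D", "D_left", "D_right"))
        cohort[[col]][hit] <- cohort[[col]][hit] * artifact_scale
    }
    rownames(cohort) <- NULL
    list(cohort = cohort, brains = brains, regions = regions,
         truth = list(sex_volume_regions = sex_volume_regions,
                      sex_density_regions = sex_density_regions,
                      strain_density_regions = strain_density_regions,
                      lateral_regions = lateral_regions,
                      artifact = artifact))
  })
}
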