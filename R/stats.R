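#' Rank-sum comparison of two groups with a median effect size
#'
#' Two-sided Wilcoxon rank-sum test (exact when sample sizes permit and there
#' are no ties, normal approximation otherwise) plus the median percent
#' difference of group B relative to group A:
#' `100 * (median(B) - median(A)) / median(A)`.
#'
#' @param a,b Numeric observations of the two groups (each of length >= 2).
#' @return List with `p_value`, `effect_pct`, and the rank-sum `statistic`.
#' @export
ranksum_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty group in rank-sum test")
  stopifnot(length(a) >= 2, length(b) >= 2)
  w <- suppressWarnings(stats::wilcox.test(b, a))
  list(p_value = w$p.value,
       effect_pct = 100 * (stats::median(b) - stats::median(a)) /
         stats::median(a),
       statistic = unname(w$statistic))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment ("q-values"); order-preserving with monotonicity
#' enforcement.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Regional dimorphism screen (volcano table)
#'
#' For each region, compares the two qualifier groups (sex or strain) on one
#' variable (volume, density, or count) with a rank-sum test, adjusts the
#' p-values across regions by Benjamini-Hochberg, and flags regions whose
#' absolute median effect exceeds `effect_threshold` percent at
#' `q < q_threshold` (0.01 for sex, 0.05 for strain, by default).
#'
#' @param cohort Long cohort table with `region_id`, `acronym`, the qualifier
#'   column, and the variable column.
#' @param qualifier `"sex"` or `"strain"`.
#' @param variable `"V"`, `"D"`, or `"N"` (a column of `cohort`).
#' @param config A [stats_config()].
#' @param ref_level Reference group A (effect is B relative to A); defaults
#'   to `"F"` for sex and `"C57BL/6J"` (when present, else the first level)
#'   for strain.
#' @return Data frame: `region_id`, `acronym`, `n_a`, `n_b`, `effect_pct`,
#'   `p`, `q`, `significant`, `note`.
#' @export
dimorphism_screen <- function(cohort, qualifier = c("sex", "strain"),
                              variable = c("D", "V", "N"),
                              config = stats_config(), ref_level = NULL) {
  qualifier <- match.arg(qualifier)
  variable <- match.arg(variable)
  groups <- as.character(cohort[[qualifier]])
  lev <- unique(groups)
  if (length(lev) < 2) stop("both qualifier groups must be represented")
  if (is.null(ref_level)) {
    ref_level <- if (qualifier == "sex" && "F" %in% lev) "F"
                 else if ("C57BL/6J" %in% lev) "C57BL/6J" else lev[1]
  }
  other <- setdiff(lev, ref_level)[1]
  q_thr <- if (qualifier == "sex") config$q_threshold_dimorphism
           else config$q_threshold_strain
  out <- lapply(split(cohort, cohort$region_id), function(g) {
    a <- g[[variable]][g[[qualifier]] == ref_level]
    b <- g[[variable]][g[[qualifier]] == other]
    row <- data.frame(region_id = g$region_id[1], acronym = g$acronym[1],
                      n_a = length(a), n_b = length(b),
                      effect_pct = NA_real_, p = NA_real_, note = "")
    if (length(a) < 2 || length(b) < 2) {
      row$note <- "group_too_small"
      return(row)
    }
    rs <- ranksum_test(a, b)
    row$effect_pct <- rs$effect_pct
    row$p <- rs$p_value
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_adjust(out$p[ok])
  out$significant <- ok & abs(out$effect_pct) > config$effect_threshold &
    out$q < q_thr
  attr(out, "comparison") <- c(ref = ref_level, alt = other,
                               variable = variable)
  out
}

#' Regional laterality screen
#'
#' Per brain and region, the hemispheric bias is the symmetric percent
#' difference `100 * (left - right) / ((left + right) / 2)`; a region's
#' summary is the median bias across brains and the fraction of brains with
#' left > right. Regions whose median volume is at or below
#' `laterality_min_volume`, or whose acronym matches the exclusion pattern
#' (cortical layer 1 / 6b by default), are omitted; so are brains missing a
#' hemisphere value for the region.
#'
#' @param cohort Long cohort table with `V`, and `D_left`/`D_right` (or
#'   `V_left`/`V_right` when `variable = "V"`).
#' @param variable `"D"` (density, default) or `"V"` (volume).
#' @param config A [stats_config()].
#' @return Data frame: `region_id`, `acronym`, `n_brains`,
#'   `median_bias_pct`, `frac_left`, `side`.
#' @export
laterality_screen <- function(cohort, variable = c("D", "V"),
                              config = stats_config()) {
  variable <- match.arg(variable)
  lcol <- paste0(variable, "_left"); rcol <- paste0(variable, "_right")
  stopifnot(all(c(lcol, rcol) %in% names(cohort)))
  out <- lapply(split(cohort, cohort$region_id), function(g) {
    if (stats::median(g$V) <= config$laterality_min_volume) return(NULL)
    if (grepl(config$laterality_exclude_pattern, g$acronym[1], perl = TRUE))
      return(NULL)
    l <- g[[lcol]]; r <- g[[rcol]]
    ok <- !is.na(l) & !is.na(r)
    if (!any(ok)) return(NULL)
    bias <- 100 * (l[ok] - r[ok]) / ((l[ok] + r[ok]) / 2)
    data.frame(region_id = g$region_id[1], acronym = g$acronym[1],
               n_brains = sum(ok),
               median_bias_pct = stats::median(bias),
               frac_left = mean(l[ok] > r[ok]))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(region_id = integer(0), acronym = character(0),
                      n_brains = integer(0), median_bias_pct = numeric(0),
                      frac_left = numeric(0), side = character(0)))
  rownames(out) <- NULL
  out$side <- ifelse(out$median_bias_pct > 0, "left",
                     ifelse(out$median_bias_pct < 0, "right", "none"))
  out
}

# Stratified train indices: train_frac of each class.
stratified_split <- function(y, train_frac) {
  idx <- unlist(lapply(split(seq_along(y), y), function(i)
    sample(i, max(1, round(length(i) * train_frac)))))
  sort(idx)
}

# Hyperplane weights of a fitted linear SVM.
svm_weights <- function(fit) {
  drop(crossprod(fit$coefs, fit$SV))
}

#' Sex prediction from regional features with a linear SVM
#'
#' Trains a linear soft-margin SVM (`C` as configured, default 100) on
#' repeated random stratified train/test splits (default 2/3 train, 100
#' repeats), reporting held-out accuracy (mean and SD) and a feature ranking
#' by the mean absolute hyperplane weight of each region across repeats.
#' Features are z-scored per region before fitting so the weights are
#' comparable; constant regions are dropped with a note.
#'
#' @param X Numeric matrix, brains x regions, column names = regions.
#' @param y Two-level factor (or coercible), one label per brain.
#' @param config A [stats_config()].
#' @param seed Seed governing all splits.
#' @param standardize Z-score each column first (recommended; weights are
#'   otherwise not comparable across regions).
#' @return List: `accuracy_mean`, `accuracy_sd`, `accuracies` (per repeat),
#'   `ranking` (data frame `region`, `mean_abs_weight`, `rank`),
#'   `dropped_constant`.
#' @export
svm_sex_classifier <- function(X, y, config = stats_config(), seed = 1L,
                               standardize = TRUE) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2) stop("exactly two classes required")
  if (is.null(colnames(X))) colnames(X) <- paste0("R", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  X <- X[, sds > 0, drop = FALSE]
  if (standardize) X <- scale(X)
  n_rep <- config$svm_repeats
  acc <- numeric(n_rep)
  absw <- matrix(0, n_rep, ncol(X), dimnames = list(NULL, colnames(X)))
  with_seed(seed, {
    for (r in seq_len(n_rep)) {
      tr <- stratified_split(y, config$svm_train_frac)
      fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "linear",
                        cost = config$svm_C, scale = FALSE)
      pred <- stats::predict(fit, X[-tr, , drop = FALSE])
      acc[r] <- mean(pred == y[-tr])
      absw[r, ] <- abs(svm_weights(fit))
    }
  })
  mw <- colMeans(absw)
  ranking <- data.frame(region = colnames(X), mean_abs_weight = mw)
  ranking <- ranking[order(-ranking$mean_abs_weight), ]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  list(accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
       accuracies = acc, ranking = ranking, dropped_constant = dropped)
}

#' Training accuracy while adding top-ranked regions one at a time
#'
#' Starting from the top of a feature ranking, trains an SVM on the whole
#' dataset (no train/test split) on the top-k regions for k = 1..`k_max` and
#' reports the training accuracy curve. The curve typically rises but is not
#' guaranteed monotone and is reported as-is.
#'
#' @param X,y As in [svm_sex_classifier()].
#' @param ranking Ranking data frame from [svm_sex_classifier()], or a
#'   character vector of region names in rank order.
#' @param k_max Largest number of top regions (truncated to the feature
#'   count).
#' @param config A [stats_config()].
#' @param standardize Z-score columns first.
#' @return Data frame: `k`, `region_added`, `accuracy`.
#' @export
incremental_feature_curve <- function(X, y, ranking, k_max = 10L,
                                      config = stats_config(),
                                      standardize = TRUE) {
  X <- as.matrix(X)
  y <- factor(y)
  order_regions <- if (is.data.frame(ranking)) ranking$region else ranking
  order_regions <- intersect(order_regions, colnames(X))
  k_max <- min(k_max, length(order_regions))
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    X <- scale(X[, sds > 0, drop = FALSE])
    order_regions <- intersect(order_regions, colnames(X))
    k_max <- min(k_max, length(order_regions))
  }
  out <- data.frame(k = seq_len(k_max),
                    region_added = order_regions[seq_len(k_max)],
                    accuracy = NA_real_)
  for (k in seq_len(k_max)) {
    sel <- order_regions[seq_len(k)]
    fit <- e1071::svm(X[, sel, drop = FALSE], y, kernel = "linear",
                      cost = config$svm_C, scale = FALSE)
    out$accuracy[k] <- mean(stats::predict(fit, X[, sel, drop = FALSE]) == y)
  }
  out
}

#' Per-region correlation between volume and density
#'
#' Pearson correlation of (V, D) pairs across brains, per region, with a
#' two-sided p-value from the t transform and BH-adjusted q-values. Regions
#' observed in fewer than 3 brains or with zero variance in either variable
#' are omitted.
#'
#' @param cohort Long cohort table with `V` and `D`.
#' @param config A [stats_config()] (for the `corr_sig_abs` flag).
#' @return Data frame: `region_id`, `acronym`, `n`, `r`, `p`, `q`,
#'   `significant` (|r| above the configured threshold).
#' @export
volume_density_correlation <- function(cohort, config = stats_config()) {
  out <- lapply(split(cohort, cohort$region_id), function(g) {
    n <- nrow(g)
    if (n < 3 || stats::sd(g$V) == 0 || stats::sd(g$D) == 0) return(NULL)
    r <- stats::cor(g$V, g$D)
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    data.frame(region_id = g$region_id[1], acronym = g$acronym[1],
               n = n, r = r, p = 2 * stats::pt(-abs(t), n - 2))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(region_id = integer(0), acronym = character(0),
                      n = integer(0), r = numeric(0), p = numeric(0),
                      q = numeric(0), significant = logical(0)))
  rownames(out) <- NULL
  out$q <- bh_adjust(out$p)
  out$significant <- abs(out$r) > config$corr_sig_abs
  out
}

#' Region-to-region similarity across the population
#'
#' Pairwise Pearson correlations between regions over brains, each region's
#' ten most correlated neighbours, and a deterministic 2D embedding (classical
#' multidimensional scaling of the `1 - correlation` distances) for
#' visualization. Constant region vectors are excluded with a note.
#'
#' @param M Numeric matrix, regions x brains (row names = regions).
#' @param top_n Number of nearest neighbours to report per region.
#' @return List: `correlation` (symmetric, unit diagonal), `neighbors`
#'   (data frame `region`, `rank`, `neighbor`, `r`), `embedding` (regions x 2
#'   coordinates), `excluded_constant`.
#' @export
region_similarity <- function(M, top_n = 10L) {
  M <- as.matrix(M)
  if (is.null(rownames(M))) rownames(M) <- paste0("R", seq_len(nrow(M)))
  if (ncol(M) < 3) stop("at least 3 brains required")
  sds <- apply(M, 1, stats::sd)
  excluded <- rownames(M)[sds == 0]
  M <- M[sds > 0, , drop = FALSE]
  C <- stats::cor(t(M))
  diag(C) <- 1
  top_n <- min(top_n, nrow(C) - 1L)
  neigh <- lapply(rownames(C), function(rg) {
    r <- C[rg, ]; r <- r[names(r) != rg]
    o <- order(-r)[seq_len(top_n)]
    data.frame(region = rg, rank = seq_len(top_n),
               neighbor = names(r)[o], r = unname(r[o]))
  })
  emb <- stats::cmdscale(stats::as.dist(1 - C), k = 2)
  colnames(emb) <- c("dim1", "dim2")
  list(correlation = C, neighbors = do.call(rbind, neigh),
       embedding = emb, excluded_constant = excluded)
}
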