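# Independent brute-force oracles used to freeze expected values.

# Exact two-sided rank-sum p-value by full enumeration of group assignments
# (feasible for m + n <= 12 via combn).
bf_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(b)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[(length(a) + 1):length(pooled)])
  combos <- utils::combn(length(pooled), n)
  w_all <- apply(combos, 2, function(idx) sum(ranks[idx]))
  mu <- mean(w_all)
  # two-sided: as extreme or more in either direction around the mean
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Step-up Benjamini-Hochberg from first principles.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Optimal single-threshold 2-partition of 1D data by within-cluster sum of
# squares (equivalent to 1D 2-means).
bf_threshold_split <- function(x) {
  xs <- sort(unique(x))
  best <- NULL; best_ss <- Inf
  for (t in xs[-length(xs)]) {
    lo <- x[x <= t]; hi <- x[x > t]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best_ss) { best_ss <- ss; best <- t }
  }
  factor(ifelse(x > best, "dense", "sparse"), levels = c("dense", "sparse"))
}

# Draw a disk into a matrix (used for crafted detection fixtures).
draw_disk <- function(img, row, col, radius_px, value) {
  rows <- max(1, floor(row - radius_px)):min(nrow(img), ceiling(row + radius_px))
  cols <- max(1, floor(col - radius_px)):min(ncol(img), ceiling(col + radius_px))
  d2 <- outer((rows - row)^2, (cols - col)^2, "+")
  img[rows, cols][d2 <= radius_px^2] <- value
  img
}

# Match detections to ground-truth cells within a tolerance (um), returning
# recall over truths with apparent radius >= min_radius_um and the
# false-positive rate over all truths.
match_detections <- function(truth, detections, pixel_size, tol_um = 5,
                             min_radius_um = 0) {
  tol2 <- (tol_um / pixel_size)^2
  hits <- 0L; big <- 0L; fp <- 0L
  for (s in unique(truth$section_index)) {
    tr <- truth[truth$section_index == s, ]
    de <- detections[detections$section_index == s, ]
    if (!nrow(tr)) { fp <- fp + nrow(de); next }
    if (!nrow(de)) { big <- big + sum(tr$radius_um >= min_radius_um); next }
    d2 <- outer(tr$centroid_row, de$centroid_row, "-")^2 +
      outer(tr$centroid_col, de$centroid_col, "-")^2
    sel <- tr$radius_um >= min_radius_um
    big <- big + sum(sel)
    hits <- hits + sum(apply(d2[sel, , drop = FALSE], 1,
                             function(r) any(r <= tol2)))
    fp <- fp + sum(!apply(d2, 2, function(r) any(r <= tol2)))
  }
  list(recall = hits / big, fp_rate = fp / nrow(truth))
}

# Standard two-region bilateral phantom layout for pipeline-level tests.
two_region_specs <- function(densities = c(1.5e5, 3e5), field = c(360, 220, 420)) {
  specs <- list()
  h <- (field[2] - 30) / 2
  w <- field[1] / 2 - 20
  for (i in 1:2) {
    cy <- 10 * i + h * (i - 0.5)
    left <- region_spec(i, sprintf("PH%02d", i), "box",
                        center = c(10 + w / 2, cy, field[3] / 2),
                        half_size = c(w / 2, h / 2, field[3] / 2 + 6),
                        density = densities[i])
    specs[[2 * i - 1]] <- left
    specs[[2 * i]] <- mirror_spec(left, field[1])
  }
  specs
}
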