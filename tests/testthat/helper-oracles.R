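# Independent oracles used to cross-check the implementation. These are
# deliberately naive (exhaustive scans, flood fill, direct arithmetic) and
# share no code with the package internals.

# Exhaustive-scan Otsu: try all 256-bin cut points, maximize between-class
# variance (equivalently minimize intra-class variance). When the maximum
# is a plateau (empty bins between well-separated modes), the midpoint of
# the plateau is returned.
oracle_otsu <- function(z, levels = 256) {
  z <- as.vector(unclass(z))
  counts <- tabulate(pmin(floor(z * levels) + 1, levels), nbins = levels)
  p <- counts / sum(counts)
  mids <- (seq_len(levels) - 0.5) / levels
  bc <- rep(NA_real_, levels - 1)
  for (k in seq_len(levels - 1)) {
    w1 <- sum(p[1:k]); w2 <- 1 - w1
    if (w1 == 0 || w2 == 0) next
    m1 <- sum(p[1:k] * mids[1:k]) / w1
    m2 <- sum(p[(k + 1):levels] * mids[(k + 1):levels]) / w2
    bc[k] <- w1 * w2 * (m1 - m2)^2
  }
  plateau <- which(bc >= max(bc, na.rm = TRUE) - 1e-12)
  mean(range(plateau)) / levels
}

# Brute-force flood-fill connected-component count/labelling.
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 8)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  n <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || lab[i, j] != 0) next
    n <- n + 1L
    queue <- list(c(i, j)); lab[i, j] <- n
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbr))) {
        qi <- p[1] + nbr[k, 1]; qj <- p[2] + nbr[k, 2]
        if (qi >= 1 && qi <= nr && qj >= 1 && qj <= nc &&
            mask[qi, qj] && lab[qi, qj] == 0) {
          lab[qi, qj] <- n
          queue[[length(queue) + 1]] <- c(qi, qj)
        }
      }
    }
  }
  list(n = n, label = lab)
}

# Per-pixel scan for marker positivity: nucleus i positive iff any of its
# pixels has marker intensity strictly above t.
oracle_positive_ids <- function(z, label_map, t) {
  z <- unclass(z)
  n <- max(label_map)
  ids <- integer()
  for (i in seq_len(n))
    if (any(z[label_map == i] > t)) ids <- c(ids, i)
  ids
}

# Direct reimplementation of the concordance percentage: distance of the
# algorithm point to the rater centroid, strictly below the max rater
# distance, averaged over images.
oracle_concordance <- function(sets) {
  within <- vapply(sets, function(s) {
    pts <- as.matrix(s$raters[, c("dapi", "marker")])
    cen <- c(mean(pts[, 1]), mean(pts[, 2]))
    d_r <- apply(pts, 1, function(p) sqrt(sum((p - cen)^2)))
    d_a <- sqrt(sum((as.numeric(s$algorithm) - cen)^2))
    d_a < max(d_r)
  }, logical(1))
  100 * mean(within)
}

# A small noiseless piecewise-constant field with two disks, by hand.
make_two_disk_image <- function(h = 64, w = 64, centers = rbind(c(20, 20), c(44, 44)),
                                radius = 8, fg = 0.8, bg = 0.1) {
  z <- matrix(bg, h, w)
  for (r in seq_len(nrow(centers)))
    for (i in 1:h) for (j in 1:w)
      if ((i - centers[r, 1])^2 + (j - centers[r, 2])^2 <= radius^2)
        z[i, j] <- fg
  z
}

# Random synthetic rater sets: raters = truth + integer noise, algorithm =
# truth (used for concordance oracle comparisons).
make_rater_sets <- function(n_images = 10, n_raters = 5, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n_images), function(i) {
    truth <- c(round(runif(1, 30, 80)), round(runif(1, 2, 25)))
    raters <- data.frame(
      rater_id = paste0("R", seq_len(n_raters)),
      dapi = pmax(0, truth[1] + round(rnorm(n_raters))),
      marker = pmax(0, truth[2] + round(rnorm(n_raters))))
    rater_count_set(paste0("img", i), raters, algorithm = truth)
  })
}
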