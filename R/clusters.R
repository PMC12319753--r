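#' Calinski-Harabasz index
#'
#' Ratio of between-cluster to within-cluster dispersion,
#' `[B / (k - 1)] / [W / (n - k)]`.
#'
#' @param X n x p matrix of observations.
#' @param labels Integer cluster labels (1..k).
#' @return The index value (`NaN` for k = 1 or degenerate input).
#' @export
calinski_harabasz <- function(X, labels) {
  X <- as.matrix(X)
  k <- length(unique(labels))
  n <- nrow(X)
  grand <- colMeans(X)
  B <- 0; W <- 0
  for (g in unique(labels)) {
    Xi <- X[labels == g, , drop = FALSE]
    ci <- colMeans(Xi)
    B <- B + nrow(Xi) * sum((ci - grand)^2)
    W <- W + sum(sweep(Xi, 2, ci)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

# seeded k-means with multi-restart, squared Euclidean distance
run_kmeans <- function(X, k, seed = 1L, nstart = 20L) {
  with_seed(seed, stats::kmeans(X, centers = k, nstart = nstart,
                                iter.max = 100L))
}

#' Select the number of clusters by the Calinski-Harabasz criterion
#'
#' Runs k-means for each candidate k and returns the k maximizing the index.
#' A selection whose best index is less than `confidence_ratio` times the
#' runner-up is flagged low-confidence.
#'
#' @param curves Voxels x conditions matrix of (z-scored) tuning curves.
#' @param k_range Candidate cluster counts.
#' @param seed Integer seed.
#' @param nstart k-means restarts.
#' @param confidence_ratio Best/second-best ratio below which the selection
#'   is flagged.
#' @return List: `k`, `ch` (named index values), `low_confidence`.
#' @export
select_k_calinski_harabasz <- function(curves, k_range = 2:6, seed = 1L,
                                       nstart = 20L, confidence_ratio = 1.2) {
  curves <- as.matrix(curves)
  k_max_ok <- nrow(curves) - 1L
  if (max(k_range) > k_max_ok) {
    warning("fewer voxels than k_max; shrinking the k range")
    k_range <- k_range[k_range <= k_max_ok]
    if (!length(k_range)) stop("too few voxels to cluster")
  }
  ch <- vapply(k_range, function(k) {
    km <- run_kmeans(curves, k, seed = derive_seed(seed, k), nstart = nstart)
    calinski_harabasz(curves, km$cluster)
  }, numeric(1))
  names(ch) <- k_range
  best <- order(ch, decreasing = TRUE)
  low_conf <- length(ch) > 1L && ch[best[1]] < confidence_ratio * ch[best[2]]
  list(k = k_range[best[1]], ch = ch, low_confidence = low_conf)
}

#' Synthetic tuning curves from two planted archetypes
#'
#' Generates 4-point (SC, C, D, SD) tuning curves from a graded-linear
#' archetype (strictly increasing) and a step archetype (SC low, C = D = SD
#' high), adds Gaussian noise, and z-scores each curve — the representation
#' the clustering stage operates on. Used by the cluster-count recovery
#' check.
#'
#' @param n_per Voxels per archetype.
#' @param noise_sd Gaussian noise SD added to the (z-scored) archetype.
#' @param seed Integer seed.
#' @return List: `curves` ((2 * n_per) x 4 z-scored matrix), `archetype`
#'   (1 = graded, 2 = step).
#' @export
synthetic_archetype_curves <- function(n_per = 200L, noise_sd = 0.2,
                                       seed = 1L) {
  stopifnot(n_per >= 1L, noise_sd >= 0)
  graded <- as.numeric(scale(c(1, 2, 3, 4)))
  step <- as.numeric(scale(c(0, 1, 1, 1)))
  base <- rbind(matrix(graded, n_per, 4L, byrow = TRUE),
                matrix(step, n_per, 4L, byrow = TRUE))
  noisy <- with_seed(seed, base + matrix(stats::rnorm(length(base), 0,
                                                      noise_sd),
                                         nrow(base), 4L))
  list(curves = zscore_rows(noisy),
       archetype = rep(1:2, each = n_per))
}

# z-score each row (curve) across its columns; flat rows become zeros
zscore_rows <- function(M) {
  mu <- rowMeans(M)
  s <- apply(M, 1, stats::sd)
  out <- (M - mu) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  out
}

# best permutation of labels mapping centroids `C` onto reference `ref`
match_centroids <- function(C, ref) {
  k <- nrow(ref)
  perms <- all_perms(k)
  costs <- vapply(perms, function(p) sum((C[p, , drop = FALSE] - ref)^2),
                  numeric(1))
  perms[[which.min(costs)]]
}

all_perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1L)) for (pos in seq_len(k))
    out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  out
}

#' Leave-one-out k-means clustering of release-mask tuning curves
#'
#' For each fold (one subject held out), averages the deviant betas of the
#' retained subjects per voxel, z-scores each voxel's 4-condition curve,
#' k-means-clusters the curves, aligns cluster labels to the first fold's
#' centroids (minimal summed squared distance over label permutations), and
#' extracts the held-out subject's mean curve within each fold cluster ROI.
#' Clusters are ordered by decreasing centroid slope, so cluster 1 is the
#' steepest.
#'
#' @param beta_array Subjects x voxels x 4 array of deviant betas for the
#'   release-mask voxels (condition order SC, C, D, SD).
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param nstart k-means restarts.
#' @return A `loo_clusters` list: `folds` (per fold: `labels`, `centroids`,
#'   `held_out`, `held_out_curves` (k x 4)), `k`, `n_folds`.
#' @export
loo_cluster_rois <- function(beta_array, k = 2L, seed = 1L, nstart = 20L) {
  stopifnot(length(dim(beta_array)) == 3L, dim(beta_array)[3] == 4L)
  n_sub <- dim(beta_array)[1]
  n_vox <- dim(beta_array)[2]
  if (k > n_vox) stop("more clusters than voxels")
  ref <- NULL
  folds <- lapply(seq_len(n_sub), function(s) {
    keep <- setdiff(seq_len(n_sub), s)
    avg <- apply(beta_array[keep, , , drop = FALSE], c(2, 3), mean)
    Z <- zscore_rows(avg)
    km <- run_kmeans(Z, k, seed = derive_seed(seed, s), nstart = nstart)
    labels <- km$cluster
    cent <- km$centers
    if (is.null(ref)) {
      # order reference clusters by decreasing slope of their centroid
      slopes <- apply(cent, 1, function(v) curve_slope(v))
      ord <- order(slopes, decreasing = TRUE)
      relab <- match(seq_len(k), ord)
      ref <<- cent[ord, , drop = FALSE]
      labels <- relab[labels]
      cent <- ref
    } else {
      p <- match_centroids(cent, ref)
      relab <- match(seq_len(k), p)
      labels <- relab[labels]
      cent <- cent[p, , drop = FALSE]
    }
    held_curves <- t(vapply(seq_len(k), function(c_) {
      sel <- labels == c_
      if (!any(sel)) rep(NA_real_, 4L) else
        colMeans(matrix(beta_array[s, sel, ], ncol = 4L))
    }, numeric(4)))
    list(labels = labels, centroids = cent, held_out = s,
         held_out_curves = held_curves)
  })
  structure(list(folds = folds, k = k, n_folds = n_sub, n_vox = n_vox),
            class = "loo_clusters")
}

curve_slope <- function(v, x = seq_along(v)) {
  xc <- x - mean(x)
  sum(xc * v) / sum(xc^2)
}

# paired t-test that tolerates exactly-constant differences (possible with
# synthetic input): zero mean and zero spread gives t = 0, nonzero mean with
# zero spread gives t = +/-Inf
paired_t <- function(x, y, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  d <- x - y
  n <- length(d)
  m <- mean(d)
  sd_d <- stats::sd(d)
  t <- if (sd_d == 0) {
    if (m == 0) 0 else sign(m) * Inf
  } else {
    m / (sd_d / sqrt(n))
  }
  df <- n - 1L
  p <- if (alternative == "greater") {
    stats::pt(t, df, lower.tail = FALSE)
  } else {
    2 * stats::pt(-abs(t), df)
  }
  list(t = t, df = df, p = p, mean_diff = m)
}

#' Consensus cluster masks across leave-one-out folds
#'
#' A voxel belongs to a cluster's consensus region iff it was assigned to
#' that cluster in at least `ceiling(threshold * n_folds)` folds.
#'
#' @param loo A `loo_clusters` object.
#' @param threshold Fraction of folds required (default 0.75).
#' @return Voxels x k logical matrix of consensus membership.
#' @export
consensus_mask <- function(loo, threshold = 0.75) {
  stopifnot(inherits(loo, "loo_clusters"), threshold > 0, threshold <= 1)
  need <- ceiling(threshold * loo$n_folds)
  counts <- matrix(0L, loo$n_vox, loo$k)
  for (f in loo$folds)
    for (c_ in seq_len(loo$k))
      counts[, c_] <- counts[, c_] + (f$labels == c_)
  counts >= need
}

#' Compare tuning curves and slopes between consensus clusters
#'
#' Per subject and cluster, the mean deviant curve over the cluster's
#' consensus voxels is z-scored across the concatenated comparison set (all
#' clusters x 4 conditions per subject) and summarized by its slope over
#' similarity rank. Reports the paired one-tailed t-test (cluster 1 steeper
#' than cluster 2) and Wilcoxon signed-rank test on the slopes, and per
#' cluster the six pairwise deviant comparisons (two-tailed paired t,
#' Bonferroni). Subjects whose grand-mean beta exceeds the group mean by
#' more than `outlier_sd` SDs are excluded and reported.
#'
#' @param beta_array Subjects x voxels x 4 deviant-beta array (release-mask
#'   voxels, order SC, C, D, SD).
#' @param consensus Voxels x k logical matrix from [consensus_mask()].
#' @param outlier_sd Exclusion threshold in group SD units.
#' @param alpha Significance level.
#' @return List: `curves` (subject x cluster x condition, z-scored),
#'   `slopes` (subject x cluster), `slope_t` (paired one-tailed),
#'   `slope_wilcoxon`, `deviant_pairs` (per-cluster pairwise table),
#'   `excluded` (subject indices), `cluster_summary`.
#' @export
compare_clusters <- function(beta_array, consensus, outlier_sd = 3,
                             alpha = 0.05) {
  stopifnot(length(dim(beta_array)) == 3L,
            nrow(consensus) == dim(beta_array)[2])
  k <- ncol(consensus)
  if (any(colSums(consensus) == 0)) stop("empty consensus cluster")
  n_sub <- dim(beta_array)[1]
  raw <- array(NA_real_, c(n_sub, k, 4L))
  for (s in seq_len(n_sub)) for (c_ in seq_len(k))
    raw[s, c_, ] <- colMeans(matrix(beta_array[s, consensus[, c_], ], ncol = 4L))
  grand <- apply(raw, 1, mean)
  excl <- which(grand > mean(grand) + outlier_sd * stats::sd(grand))
  keep <- setdiff(seq_len(n_sub), excl)
  if (length(keep) < 3L) stop("fewer than 3 subjects remain after outlier exclusion")
  raw_k <- raw[keep, , , drop = FALSE]
  # z-score per subject across the concatenated (cluster x condition) set
  curves <- raw_k
  for (s in seq_along(keep)) {
    v <- as.vector(raw_k[s, , ])
    curves[s, , ] <- (raw_k[s, , ] - mean(v)) / stats::sd(v)
  }
  slopes <- apply(curves, c(1, 2), curve_slope)
  slope_t <- slope_wilcoxon <- NULL
  if (k >= 2L) {
    d <- slopes[, 1] - slopes[, 2]
    slope_t <- paired_t(slopes[, 1], slopes[, 2], alternative = "greater")
    if (all(d == 0)) {
      slope_wilcoxon <- list(V = 0, p = 1)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(slopes[, 1], slopes[, 2],
                                                paired = TRUE,
                                                alternative = "greater"))
      slope_wilcoxon <- list(V = unname(wt$statistic), p = wt$p.value)
    }
  }
  pairs <- utils::combn(4L, 2L)
  deviant_pairs <- do.call(rbind, lapply(seq_len(k), function(c_) {
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      x <- curves[, c_, i1]; y <- curves[, c_, i2]
      tt <- paired_t(x, y)
      p_adj <- min(1, ncol(pairs) * tt$p)
      data.frame(cluster = c_,
                 pair = paste(DEVIANT_BINS[i1], DEVIANT_BINS[i2], sep = "-"),
                 t = tt$t, df = tt$df,
                 p_raw = tt$p, p_adj = p_adj,
                 significant = p_adj < alpha)
    }))
  }))
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  cluster_summary <- do.call(rbind, lapply(seq_len(k), function(c_)
    data.frame(cluster = c_, condition = DEVIANT_BINS,
               mean = apply(curves[, c_, , drop = FALSE], 3, mean),
               sem = apply(curves[, c_, , drop = FALSE], 3, sem),
               slope_mean = mean(slopes[, c_]),
               slope_sem = sem(slopes[, c_]), row.names = NULL)))
  list(curves = curves, slopes = slopes, slope_t = slope_t,
       slope_wilcoxon = slope_wilcoxon, deviant_pairs = deviant_pairs,
       excluded = excl, cluster_summary = cluster_summary)
}
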