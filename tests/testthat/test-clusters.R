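test_that("Calinski-Harabasz index matches hand and brute-force computations", {
  # 6-point 1-D toy: {0,1,2} vs {10,11,12}
  X <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  lab <- c(1, 1, 1, 2, 2, 2)
  # by hand: grand mean 6, B = 3*(1-6)^2 + 3*(11-6)^2 = 150,
  # W = 2 + 2 = 4 -> CH = (150/1)/(4/(6-2)) = 150
  expect_equal(calinski_harabasz(X, lab), 150, tolerance = 1e-12)
  Xr <- with_seed(4L, matrix(rnorm(40), 10, 4))
  labr <- rep(1:2, 5)
  expect_equal(calinski_harabasz(Xr, labr), ch_bf(Xr, labr),
               tolerance = 1e-12)
})

test_that("k selection recovers separated archetypes and flags weak structure", {
  syn <- synthetic_archetype_curves(n_per = 100L, noise_sd = 0.1, seed = 3L)
  sel <- select_k_calinski_harabasz(syn$curves, seed = 1L)
  expect_equal(sel$k, 2L)
  expect_false(sel$low_confidence)
  # single isotropic blob: whatever k wins, confidence is low
  blob <- with_seed(5L, matrix(rnorm(200 * 4), 200, 4))
  sel1 <- select_k_calinski_harabasz(blob, seed = 1L)
  expect_true(sel1$low_confidence)
  # range shrinks with warning when voxels are scarce
  tiny <- with_seed(6L, matrix(rnorm(5 * 4), 5, 4))
  expect_warning(sel2 <- select_k_calinski_harabasz(tiny, k_range = 2:6,
                                                    seed = 1L), "shrink")
  expect_lte(sel2$k, 4L)
})

test_that("z-scoring preserves curve ordering and handles flat rows", {
  M <- rbind(c(1, 3, 2, 4), c(5, 5, 5, 5))
  Z <- adaptune:::zscore_rows(M)
  expect_equal(order(Z[1, ]), order(M[1, ]))
  expect_equal(Z[2, ], rep(0, 4))
  expect_equal(mean(Z[1, ]), 0, tolerance = 1e-12)
  expect_equal(sd(Z[1, ]), 1, tolerance = 1e-12)
})

test_that("centroid matching maps permuted labels back consistently", {
  ref <- rbind(c(0, 0, 0, 0), c(5, 5, 5, 5), c(-5, -5, -5, -5))
  for (p in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    perm <- adaptune:::match_centroids(ref[p, ], ref)
    expect_equal(ref[p, ][perm, ], ref)
  }
})

test_that("leave-one-out clustering recovers planted structure noise-free", {
  # 12 subjects x 60 voxels x 4 conditions; voxels 1:30 graded, 31:60 step
  graded <- c(-1.2, -0.4, 0.4, 1.2)
  step <- c(-1.5, 0.5, 0.5, 0.5)
  n_sub <- 12L
  ba <- array(NA_real_, c(n_sub, 60L, 4L))
  for (s in seq_len(n_sub)) {
    ba[s, 1:30, ] <- matrix(graded, 30, 4, byrow = TRUE)
    ba[s, 31:60, ] <- matrix(step, 30, 4, byrow = TRUE)
  }
  loo <- loo_cluster_rois(ba, k = 2L, seed = 1L)
  expect_equal(loo$n_folds, n_sub)
  # identical partitions in every fold, cluster 1 = steeper (graded)
  for (f in loo$folds) {
    expect_equal(f$labels, rep(c(1L, 2L), each = 30))
    expect_equal(f$held_out_curves[1, ], graded, tolerance = 1e-12)
    expect_equal(f$held_out_curves[2, ], step, tolerance = 1e-12)
  }
  cons <- consensus_mask(loo)
  expect_equal(unname(colSums(cons)), c(30L, 30L))
  expect_error(loo_cluster_rois(ba[, 1:1, , drop = FALSE], k = 2L),
               "more clusters")
})

test_that("held-out extraction excludes the held-out subject from the fold ROIs", {
  # give one subject aberrant curves; fold partitions must not change
  graded <- c(-1.2, -0.4, 0.4, 1.2); step <- c(-1.5, 0.5, 0.5, 0.5)
  ba <- array(NA_real_, c(6L, 20L, 4L))
  for (s in 1:6) {
    ba[s, 1:10, ] <- matrix(graded, 10, 4, byrow = TRUE)
    ba[s, 11:20, ] <- matrix(step, 10, 4, byrow = TRUE)
  }
  ba[3, , ] <- 100  # held-out subject's own data can't leak into fold 3's ROIs
  loo <- loo_cluster_rois(ba, k = 2L, seed = 2L)
  expect_equal(loo$folds[[3]]$labels, rep(c(1L, 2L), each = 10))
  expect_equal(loo$folds[[3]]$held_out_curves[1, ], rep(100, 4))
})

test_that("consensus threshold arithmetic matches the 75% rule", {
  # synthetic loo object: 20 folds -> need ceiling(0.75 * 20) = 15 folds;
  # voxel 1 hits cluster 1 in 15 folds (kept, boundary), voxel 2 in 14 (dropped)
  folds <- lapply(1:20, function(f) {
    lab <- c(if (f <= 15) 1L else 2L, if (f <= 14) 1L else 2L)
    list(labels = lab)
  })
  loo <- structure(list(folds = folds, k = 2L, n_folds = 20L, n_vox = 2L),
                   class = "loo_clusters")
  cons <- consensus_mask(loo, threshold = 0.75)
  expect_true(cons[1, 1])        # exactly 15/20 = 75% kept
  expect_false(cons[2, 1])       # 14/20 dropped
  # threshold 1.0 = intersection of all folds
  cons1 <- consensus_mask(loo, threshold = 1.0)
  expect_false(any(cons1[, 1]))
})

test_that("compare_clusters: slopes, tests, and the Wilcoxon oracle", {
  graded <- c(-1.2, -0.4, 0.4, 1.2); step <- c(-1.5, 0.5, 0.5, 0.5)
  n_sub <- 10L
  ba <- array(NA_real_, c(n_sub, 40L, 4L))
  for (s in seq_len(n_sub)) {
    jit <- with_seed(100L + s, rnorm(4, 0, 0.05))
    ba[s, 1:20, ] <- matrix(graded + jit, 20, 4, byrow = TRUE)
    ba[s, 21:40, ] <- matrix(step + jit, 20, 4, byrow = TRUE)
  }
  cons <- cbind(c(rep(TRUE, 20), rep(FALSE, 20)),
                c(rep(FALSE, 20), rep(TRUE, 20)))
  cmp <- compare_clusters(ba, cons)
  expect_equal(dim(cmp$curves), c(n_sub, 2L, 4L))
  expect_true(all(cmp$slopes[, 1] > cmp$slopes[, 2]))
  expect_lt(cmp$slope_t$p, 0.01)
  expect_equal(cmp$slope_t$df, n_sub - 1L)
  # Wilcoxon V against the by-hand signed-rank sum
  V_hand <- wilcoxon_bf(cmp$slopes[, 1], cmp$slopes[, 2])
  expect_equal(unname(cmp$slope_wilcoxon$V), V_hand)
  expect_equal(nrow(cmp$deviant_pairs), 12L)  # 6 pairs x 2 clusters
  expect_true(all(cmp$deviant_pairs$p_adj >= cmp$deviant_pairs$p_raw))
  expect_length(cmp$excluded, 0L)
})

test_that("identical clusters give slope t = 0 and one-tailed p = 0.5", {
  graded <- c(-1.2, -0.4, 0.4, 1.2)
  ba <- array(NA_real_, c(6L, 20L, 4L))
  for (s in 1:6) {
    jit <- with_seed(s, rnorm(1, 0, 0.1))
    ba[s, , ] <- matrix(graded + jit, 20, 4, byrow = TRUE)
  }
  cons <- cbind(rep(c(TRUE, FALSE), 10), rep(c(FALSE, TRUE), 10))
  cmp <- compare_clusters(ba, cons)
  expect_equal(cmp$slope_t$t, 0, tolerance = 1e-10)
  expect_equal(cmp$slope_t$p, 0.5, tolerance = 1e-10)
})

test_that("subjects more than 3 SD above the group mean are excluded", {
  graded <- c(-1.2, -0.4, 0.4, 1.2)
  ba <- array(NA_real_, c(12L, 20L, 4L))
  for (s in 1:12) ba[s, , ] <- matrix(graded + with_seed(s, rnorm(1, 0, 0.02)),
                                      20, 4, byrow = TRUE)
  ba[12, , ] <- ba[12, , ] + 50
  cons <- cbind(rep(c(TRUE, FALSE), 10), rep(c(FALSE, TRUE), 10))
  cmp <- compare_clusters(ba, cons)
  expect_equal(cmp$excluded, 12L)
  expect_equal(dim(cmp$curves)[1], 11L)
})

test_that("planted slope difference 0.24 vs 0.12 rejects in most seeds", {
  rejections <- vapply(1:11, function(seed) {
    n_sub <- 20L
    ba <- array(NA_real_, c(n_sub, 40L, 4L))
    with_seed(seed, {
      for (s in seq_len(n_sub)) {
        c1 <- 0.24 * (1:4 - 2.5) + rnorm(4, 0, 0.12)
        c2 <- 0.12 * (1:4 - 2.5) + rnorm(4, 0, 0.12)
        ba[s, 1:20, ] <- matrix(c1, 20, 4, byrow = TRUE) +
          matrix(rnorm(80, 0, 0.05), 20, 4)
        ba[s, 21:40, ] <- matrix(c2, 20, 4, byrow = TRUE) +
          matrix(rnorm(80, 0, 0.05), 20, 4)
      }
    })
    cons <- cbind(c(rep(TRUE, 20), rep(FALSE, 20)),
                  c(rep(FALSE, 20), rep(TRUE, 20)))
    compare_clusters(ba, cons)$slope_t$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.5)
})

test_that("synthetic archetype curves have the advertised structure", {
  syn <- synthetic_archetype_curves(n_per = 50L, noise_sd = 0, seed = 1L)
  expect_equal(dim(syn$curves), c(100L, 4L))
  expect_true(all(diff(syn$curves[1, ]) > 0))            # graded increasing
  expect_equal(syn$curves[51, 2:4], rep(syn$curves[51, 2], 3),
               tolerance = 1e-12)                         # step flat top
  expect_identical(syn$curves,
                   synthetic_archetype_curves(n_per = 50L, noise_sd = 0,
                                              seed = 1L)$curves)
})
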