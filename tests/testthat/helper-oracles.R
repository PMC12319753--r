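# Independent brute-force oracles used across the suite. Deliberately naive
# implementations: plain loops and textbook formulas, sharing no code with
# the package internals they check.

cosine_bf <- function(freq) {
  n <- nrow(freq)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- freq[i, ]; b <- freq[j, ]
    out[i, j] <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  }
  out
}

ols_bf <- function(X, y) solve(t(X) %*% X) %*% t(X) %*% y

# brute-force TFCE: per voxel, per threshold, flood-fill the suprathreshold
# component containing it and accumulate size^E * h^H * dh
tfce_bf <- function(map, H = 2, E = 0.5, dh, connectivity = 26) {
  dims <- dim(map)
  nbr <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nbr <- nbr[rowSums(abs(nbr)) > 0, ]
  if (connectivity == 6) nbr <- nbr[rowSums(abs(nbr)) == 1, ]
  if (connectivity == 18) nbr <- nbr[rowSums(abs(nbr)) <= 2, ]
  comp_size <- function(start, supra) {
    seen <- array(FALSE, dims)
    queue <- list(start)
    seen[start[1], start[2], start[3]] <- TRUE
    size <- 0L
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (r in seq_len(nrow(nbr))) {
        u <- v + as.integer(nbr[r, ])
        if (any(u < 1) || any(u > dims)) next
        if (supra[u[1], u[2], u[3]] && !seen[u[1], u[2], u[3]]) {
          seen[u[1], u[2], u[3]] <- TRUE
          queue[[length(queue) + 1L]] <- u
        }
      }
    }
    size
  }
  hmax <- max(map, 0)
  out <- array(0, dims)
  if (hmax <= 0) return(out)
  hs <- dh * seq_len(floor(hmax / dh + 1e-9))
  for (h in hs) {
    supra <- map >= h - 1e-9 * dh
    for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
      for (z in seq_len(dims[3])) {
        if (!supra[x, y, z]) next
        e <- comp_size(c(x, y, z), supra)
        out[x, y, z] <- out[x, y, z] + e^E * h^H * dh
      }
  }
  out
}

ch_bf <- function(X, labels) {
  n <- nrow(X); k <- length(unique(labels))
  grand <- colMeans(X)
  B <- 0; W <- 0
  for (g in unique(labels)) {
    rows <- which(labels == g)
    cent <- colMeans(X[rows, , drop = FALSE])
    B <- B + length(rows) * sum((cent - grand)^2)
    for (i in rows) W <- W + sum((X[i, ] - cent)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

# one-sided (greater) Wilcoxon signed-rank V statistic, by-hand ranks
wilcoxon_bf <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  r <- rank(abs(d))
  sum(r[d > 0])
}

# classical two-way (subject x condition) repeated-measures decomposition
rm_anova_bf <- function(M) {
  n <- nrow(M); p <- ncol(M)
  grand <- mean(M)
  ss_cond <- n * sum((colMeans(M) - grand)^2)
  ss_subj <- p * sum((rowMeans(M) - grand)^2)
  ss_tot <- sum((M - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- p - 1; df2 <- (p - 1) * (n - 1)
  F <- (ss_cond / df1) / (ss_err / df2)
  list(F = F, df1 = df1, df2 = df2,
       p = pf(F, df1, df2, lower.tail = FALSE),
       peta2 = ss_cond / (ss_cond + ss_err))
}

# shared small fixtures
demo_norms <- function(seed = 7L) simulate_feature_norms(seed = seed)
demo_binnings <- function(seed = 7L) {
  sim <- cosine_similarity_matrix(demo_norms(seed))
  assign_bins(sim, pick_adaptors(sim, 10L, seed = seed), seed = seed)
}
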