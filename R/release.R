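#' Voxel-wise similarity-tuning (release) regression
#'
#' Inside a mask (typically the adaptation mask), regress each voxel's four
#' deviant betas on the similarity predictor (ordinal rank 1..4 from SC to
#' SD by default, or measured cosine-similarity values). Returns the signed
#' slope and the explained variance R-squared per voxel; a voxel with zero
#' beta variance gets R-squared 0. The Identity condition is excluded by
#' construction and rejected if requested.
#'
#' @param betas A `beta_maps` object from the canonical-HRF fit (regressors
#'   `dev_SC`, `dev_C`, `dev_D`, `dev_SD`).
#' @param mask 3D logical array of voxels to analyze (subset of the fit
#'   mask).
#' @param conditions Condition labels, must be exactly SC, C, D, SD.
#' @param x Similarity predictor, one value per condition (default ranks
#'   1..4).
#' @return A `release_maps` object: `slope`, `r2` (vectors over mask
#'   voxels), `mask`, `x`.
#' @export
voxelwise_release_regression <- function(betas, mask,
                                         conditions = DEVIANT_BINS,
                                         x = seq_along(conditions)) {
  if ("I" %in% conditions)
    stop("the Identity condition is excluded from the release regression")
  if (!setequal(conditions, DEVIANT_BINS))
    stop("release regression needs exactly the four deviant conditions")
  if (!any(mask)) stop("empty release-regression mask")
  if (any(mask & !betas$mask)) stop("mask extends outside the fitted mask")
  sel <- mask[betas$mask]                # mask voxels within the fit's voxels
  B <- betas$coef[paste0("dev_", conditions), sel, drop = FALSE]
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- as.numeric(crossprod(xc, B)) / sxx
  fit_var <- slope^2 * sxx
  sst <- colSums(B^2) - nrow(B) * colMeans(B)^2
  r2 <- ifelse(sst > 0, pmin(1, pmax(0, fit_var / sst)), 0)
  structure(list(slope = slope, r2 = r2, mask = mask, x = x),
            class = "release_maps")
}

#' TFCE parameters
#'
#' Defaults follow the FSL randomise conventions: height exponent `H = 2`,
#' extent exponent `E = 0.5`, 26-connectivity, and a step of `max(map)/100`.
#'
#' @param H,E Height and extent exponents (> 0).
#' @param dh Threshold step; `NULL` selects `max(map)/n_steps` per map.
#' @param connectivity 6, 18 or 26.
#' @param n_steps Number of steps used when `dh` is `NULL`.
#' @export
tfce_params <- function(H = 2, E = 0.5, dh = NULL, connectivity = 26L,
                        n_steps = 100L) {
  stopifnot(H > 0, E > 0, connectivity %in% c(6L, 18L, 26L), n_steps >= 1L)
  if (!is.null(dh) && dh <= 0) stop("dh must be positive")
  structure(list(H = H, E = E, dh = dh, connectivity = as.integer(connectivity),
                 n_steps = as.integer(n_steps)),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement
#'
#' `TFCE(v) = sum_h e(h, v)^E * h^H * dh` over thresholds `h` from `dh` to
#' the map maximum, where `e(h, v)` is the voxel count of the suprathreshold
#' connected component containing `v`. One-sided: non-positive values score
#' zero.
#'
#' @param map 3D numeric array.
#' @param params A [tfce_params()] object.
#' @param mask Optional 3D logical restriction (default: finite voxels).
#' @return 3D array of TFCE scores (0 outside the mask).
#' @export
tfce <- function(map, params = tfce_params(), mask = NULL) {
  stopifnot(inherits(params, "tfce_params"), length(dim(map)) == 3L)
  if (is.null(mask)) mask <- is.finite(map)
  m <- map
  m[!is.finite(m)] <- 0
  out <- tfce_cpp(as.numeric(m), as.integer(dim(map)), as.logical(mask),
                  params$H, params$E, params$dh %||% -1, params$connectivity,
                  params$n_steps)
  array(out, dim(map))
}

#' One-sample sign-flip permutation test with TFCE
#'
#' The observed statistic is the one-sample t map of the subject maps,
#' TFCE-enhanced; the null distribution records the maximum TFCE score under
#' random sign flips of whole subject maps (the exchangeability scheme for a
#' symmetric-about-zero one-sample null). Familywise-corrected p-values are
#' `(1 + #(null max >= TFCE(v))) / (1 + n_perm)`.
#'
#' @param maps Subjects x voxels matrix of in-mask values (e.g. per-subject
#'   R-squared or slope maps).
#' @param mask 3D logical array with `sum(mask) == ncol(maps)`.
#' @param n_perm Number of sign-flip permutations.
#' @param params TFCE parameters.
#' @param alpha Familywise significance level; `n_perm` must be at least
#'   `1/alpha` to resolve it.
#' @param seed Integer seed.
#' @return A `permutation_result`: `t` (3D), `tfce` (3D), `p_fwe` (3D),
#'   `significant` (3D logical), `null_max` (length `n_perm`), `n_perm`,
#'   `alpha`, `seed`.
#' @export
permutation_one_sample <- function(maps, mask, n_perm = 5000L,
                                   params = tfce_params(), alpha = 0.001,
                                   seed = 1L) {
  maps <- as.matrix(maps)
  stopifnot(length(dim(mask)) == 3L, sum(mask) == ncol(maps))
  if (n_perm < 1 / alpha)
    stop("n_perm = ", n_perm, " cannot resolve alpha = ", alpha,
         "; need at least ", ceiling(1 / alpha))
  n <- nrow(maps)
  if (n < 8L) warning("fewer than 8 subjects; permutation p-values are coarse")
  sumsq <- colSums(maps^2)
  t_of <- function(m) {
    v <- (sumsq - n * m^2) / (n - 1)
    v[v < 0] <- 0
    se <- sqrt(v / n)
    ifelse(se > 0, m / se, ifelse(m == 0, 0, sign(m) * Inf))
  }
  t_obs <- t_of(colMeans(maps))
  tfce_of <- function(tv) {
    tv[!is.finite(tv)] <- max(tv[is.finite(tv)], 0)
    tfce(embed_in_mask(tv, mask, fill = 0), params, mask)
  }
  tfce_obs <- tfce_of(t_obs)
  # The p-value formula counts the identity permutation once (the "1 +"
  # terms), so the sampled flips must be distinct non-identity patterns;
  # resampling the identity by chance would make the smallest attainable
  # p-value 2/(1 + n_perm). Falls back to with-replacement draws when the
  # pattern space is too small (or unenumerable) to supply n_perm distinct
  # flips.
  null_max <- with_seed(seed, {
    score_of <- function(s) max(tfce_of(t_of(colMeans(s * maps))))
    if (n <= 30 && n_perm <= 2^n - 1) {
      codes <- sample.int(2^n - 1L, n_perm)
      vapply(codes, function(cd)
        score_of(1 - 2 * as.integer(intToBits(cd)[seq_len(n)])), numeric(1))
    } else {
      vapply(seq_len(n_perm), function(i)
        score_of(sample(c(-1, 1), n, replace = TRUE)), numeric(1))
    }
  })
  obs_in <- tfce_obs[mask]
  p <- vapply(obs_in, function(x) (1 + sum(null_max >= x)) / (1 + n_perm),
              numeric(1))
  p_map <- embed_in_mask(p, mask)
  structure(list(t = embed_in_mask(t_obs, mask), tfce = tfce_obs,
                 p_fwe = p_map,
                 significant = embed_in_mask(p < alpha, mask, fill = FALSE),
                 null_max = null_max, n_perm = n_perm, alpha = alpha,
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation_result:", x$n_perm, "sign-flip permutations, alpha =",
      x$alpha, ";", sum(x$significant), "significant voxels\n")
  invisible(x)
}

#' Positive-slope masking of the significant release voxels
#'
#' @param significant 3D logical array of permutation-significant voxels.
#' @param mean_slope 3D array of the group mean release slope.
#' @return 3D logical: significant voxels whose mean slope is positive.
#' @export
positive_slope_mask <- function(significant, mean_slope) {
  stopifnot(identical(dim(significant), dim(mean_slope)))
  significant & !is.na(mean_slope) & mean_slope > 0
}

#' Release-inference stage
#'
#' Runs the voxel-wise similarity regression per subject inside the
#' adaptation mask, the group sign-flip TFCE permutation test on the chosen
#' statistic (R-squared maps as in the reference analysis, or slope maps),
#' and the positive-slope masking.
#'
#' @param hrf_betas_list Per-subject `beta_maps` from the canonical-HRF fit.
#' @param mask 3D logical adaptation mask.
#' @param stat `"r2"` or `"slope"`.
#' @param n_perm,params,alpha,seed Passed to [permutation_one_sample()].
#' @param x Similarity predictor passed to
#'   [voxelwise_release_regression()].
#' @return List: `release` (per-subject `release_maps`), `perm`
#'   (`permutation_result`), `mean_slope` (3D), `final_mask` (3D logical).
#' @export
run_release <- function(hrf_betas_list, mask, stat = c("r2", "slope"),
                        n_perm = 5000L, params = tfce_params(),
                        alpha = 0.001, seed = 1L, x = 1:4) {
  stat <- match.arg(stat)
  release <- lapply(hrf_betas_list, voxelwise_release_regression,
                    mask = mask, x = x)
  stat_mat <- do.call(rbind, lapply(release, function(r) r[[stat]]))
  slope_mat <- do.call(rbind, lapply(release, function(r) r$slope))
  perm <- permutation_one_sample(stat_mat, mask, n_perm = n_perm,
                                 params = params, alpha = alpha, seed = seed)
  mean_slope <- embed_in_mask(colMeans(slope_mat), mask)
  final_mask <- positive_slope_mask(perm$significant, mean_slope)
  list(release = release, perm = perm, mean_slope = mean_slope,
       final_mask = final_mask)
}
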