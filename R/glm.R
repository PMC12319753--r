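#' Build the FIR (stick) design matrix
#'
#' Fourteen regressors of interest: one unit impulse train per adaptor
#' position 1..9 (an impulse at each volume where an adaptor occupying that
#' position of the sequence is on screen) and one per deviant condition
#' (SC, C, D, SD, I; an impulse at each deviant presentation). Because the
#' positions tile the 1 s stimulus stream, the position betas estimate the
#' peristimulus BOLD level at each second of the adaptation sequence without
#' assuming a response shape. Nuisance columns, an optional polynomial
#' drift, and an intercept are appended.
#'
#' @param events `event_table` with onsets on the `tr` grid.
#' @param n_vols Number of volumes in the run.
#' @param tr Repetition time in seconds.
#' @param nuisance Optional matrix with `n_vols` rows (24 columns expected:
#'   6 motion + 18 physiological; other counts are accepted with a warning).
#' @param drift_order Polynomial drift order (0 = none; default 1, linear).
#' @return A `design_matrix`: list with `values`, `names`,
#'   `interest` (names of the regressors of interest), `tr`, `frame_times`.
#' @export
build_fir_design <- function(events, n_vols, tr = 1.0, nuisance = NULL,
                             drift_order = 1L) {
  idx <- event_volume_index(events, n_vols, tr)
  cols <- list()
  for (k in 1:9) {
    v <- numeric(n_vols)
    sel <- idx[events$stimulus_role == paste0("adaptor_", k)]
    v[sel] <- 1
    cols[[paste0("adaptor_", k)]] <- v
  }
  for (cond in ALL_CONDITIONS) {
    v <- numeric(n_vols)
    sel <- idx[events$stimulus_role == "deviant" & events$condition == cond]
    v[sel] <- 1
    cols[[paste0("deviant_", cond)]] <- v
  }
  assemble_design(cols, n_vols, tr, nuisance, drift_order)
}

#' Build the canonical-HRF design matrix
#'
#' Six regressors of interest — one for all adaptors pooled and one per
#' deviant condition — each an impulse train convolved with the canonical
#' double-gamma HRF and truncated to the run length, plus nuisance, drift
#' and intercept columns.
#'
#' @inheritParams build_fir_design
#' @return A `design_matrix`.
#' @export
build_hrf_design <- function(events, n_vols, tr = 1.0, nuisance = NULL,
                             drift_order = 1L) {
  idx <- event_volume_index(events, n_vols, tr)
  h <- double_gamma_hrf(tr)
  conv_train <- function(sel) {
    v <- numeric(n_vols)
    v[sel] <- 1
    stats::convolve(v, rev(h), type = "open")[seq_len(n_vols)]
  }
  cols <- list(adaptors = conv_train(idx[events$stimulus_role != "deviant"]))
  for (cond in ALL_CONDITIONS)
    cols[[paste0("dev_", cond)]] <-
      conv_train(idx[events$stimulus_role == "deviant" & events$condition == cond])
  assemble_design(cols, n_vols, tr, nuisance, drift_order)
}

event_volume_index <- function(events, n_vols, tr) {
  stopifnot(nrow(events) > 0)
  v <- events$onset / tr
  off <- abs(v - round(v)) > 1e-9
  if (any(off)) stop("event onset off the tr grid at row ", which(off)[1])
  v <- as.integer(round(v)) + 1L
  if (any(v < 1L | v > n_vols)) stop("event outside the run")
  v
}

assemble_design <- function(interest_cols, n_vols, tr, nuisance, drift_order) {
  zero <- vapply(interest_cols, function(v) all(v == 0), logical(1))
  if (any(zero))
    stop("all-zero regressor(s) of interest: ",
         paste(names(interest_cols)[zero], collapse = ", "))
  X <- do.call(cbind, interest_cols)
  interest <- names(interest_cols)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_vols)
      stop("nuisance must have n_vols rows")
    if (ncol(nuisance) != 24L)
      warning("expected 24 nuisance columns, got ", ncol(nuisance))
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuisance_", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  frame_times <- (seq_len(n_vols) - 1) * tr
  if (drift_order >= 1L) {
    dr <- stats::poly(frame_times, degree = drift_order)
    colnames(dr) <- paste0("drift_", seq_len(drift_order))
    X <- cbind(X, dr)
  }
  X <- cbind(X, intercept = 1)
  structure(list(values = X, names = colnames(X), interest = interest,
                 tr = tr, frame_times = frame_times),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("design_matrix:", nrow(x$values), "volumes x", ncol(x$values),
      "regressors (", length(x$interest), "of interest )\n")
  invisible(x)
}

#' Write a design matrix as TSV
#' @param X A `design_matrix`.
#' @param path Output path.
#' @export
write_design_tsv <- function(X, path) {
  utils::write.table(as.data.frame(X$values), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Volumes free of run-boundary transients
#'
#' The stick/FIR model assigns one beta per adaptor position, which is only
#' unbiased once the hemodynamic response has reached its within-run steady
#' state. Two run segments violate that: the initial rise over the first
#' trials after the lead fixation, and the post-stimulation decay during the
#' trailing fixation (unmodeled by impulse regressors at the event volumes).
#' This returns a logical keep-vector that censors (a) volumes from the
#' first stimulus through the end of trial `settle_trials` and (b) volumes
#' after the last event, for use as the `keep` argument of [fit_glm()].
#' Fixation volumes before the first stimulus are retained (they anchor the
#' baseline and carry no transient). The canonical-HRF design models the
#' boundary response explicitly, so censoring is only needed for FIR fits.
#'
#' @param events `event_table` with a `trial_index` column.
#' @param n_vols Number of volumes in the run.
#' @param tr Repetition time in seconds.
#' @param settle_trials Number of initial trials to censor (0 disables the
#'   head censor).
#' @param censor_tail Censor the volumes after the last event.
#' @return Logical vector of length `n_vols`; `TRUE` = keep.
#' @export
censor_volumes <- function(events, n_vols, tr = 1.0, settle_trials = 2L,
                           censor_tail = TRUE) {
  stopifnot(!is.null(events$trial_index), settle_trials >= 0)
  if (settle_trials >= max(events$trial_index))
    stop("settle_trials must leave at least one trial")
  keep <- rep(TRUE, n_vols)
  vol_of <- function(t) as.integer(round(t / tr)) + 1L
  if (settle_trials > 0) {
    from <- vol_of(min(events$onset))
    to <- vol_of(events$onset[match(settle_trials + 1L, events$trial_index)]) - 1L
    keep[from:to] <- FALSE
  }
  if (censor_tail) {
    last <- vol_of(max(events$onset))
    if (last < n_vols) keep[(last + 1L):n_vols] <- FALSE
  }
  keep
}

#' Voxel-wise ordinary least squares GLM fit
#'
#' Fits `y = X b + e` independently at every in-mask voxel via the QR
#' decomposition of the design.
#'
#' @param vol A [volume_series()].
#' @param X A `design_matrix` with as many rows as the series has volumes.
#' @param keep Optional logical vector over volumes; `FALSE` rows are
#'   censored from the fit (see [censor_volumes()]).
#' @return A `beta_maps` object: `coef` (regressor x voxel matrix), `names`,
#'   `interest`, `resvar` (residual variance per voxel), `dof`, `mask`,
#'   `dims`.
#' @export
fit_glm <- function(vol, X, keep = NULL) {
  stopifnot(inherits(vol, "volume_series"), inherits(X, "design_matrix"))
  M <- X$values
  if (nrow(M) != n_volumes(vol))
    stop("design has ", nrow(M), " rows but the series has ", n_volumes(vol), " volumes")
  if (!any(vol$mask)) stop("empty mask")
  if (!is.null(keep)) {
    stopifnot(is.logical(keep), length(keep) == nrow(M))
    if (sum(keep) <= ncol(M)) stop("censoring leaves too few volumes")
  }
  Y <- vol_matrix(vol)
  if (!is.null(keep)) {
    M <- M[keep, , drop = FALSE]
    Y <- Y[keep, , drop = FALSE]
  }
  qx <- qr(M)
  if (qx$rank < ncol(M)) {
    bad <- colnames(M)[qx$pivot[(qx$rank + 1L):ncol(M)]]
    stop("rank-deficient design; collinear column(s): ", paste(bad, collapse = ", "))
  }
  B <- qr.coef(qx, Y)
  res <- Y - M %*% B
  dof <- nrow(M) - qx$rank
  resvar <- colSums(res^2) / dof
  structure(list(coef = B, names = colnames(M), interest = X$interest,
                 resvar = resvar, dof = dof, mask = vol$mask,
                 dims = dim(vol$mask)),
            class = "beta_maps")
}

#' @export
print.beta_maps <- function(x, ...) {
  cat("beta_maps:", nrow(x$coef), "regressors x", ncol(x$coef),
      "voxels, dof =", x$dof, "\n")
  invisible(x)
}

#' Extract one coefficient as a 3D map
#' @param betas A `beta_maps` object.
#' @param name Regressor name.
#' @return 3D array (NA outside the mask).
#' @export
beta_map <- function(betas, name) {
  if (!name %in% rownames(betas$coef)) stop("no regressor named ", name)
  embed_in_mask(betas$coef[name, ], betas$mask)
}

# one-sample t across subjects; rows = subjects, cols = voxels
group_one_sample_t <- function(mat) {
  n <- nrow(mat)
  m <- colMeans(mat)
  v <- (colSums(mat^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  se <- sqrt(v / n)
  t <- ifelse(se > 0, m / se, ifelse(m == 0, 0, sign(m) * Inf))
  list(t = t, mean = m, n = n, dof = n - 1L)
}

#' Group adaptation contrast (FIR bin 4 > bin 7)
#'
#' Per subject, the difference between the FIR betas of two adaptor
#' positions (default 4 minus 7); across subjects, a repeated-measures F on
#' the difference (the squared one-sample t, exactly equivalent for a
#' single-df contrast). The adaptation mask keeps voxels significant at
#' `alpha` whose mean difference is positive (the contrast is directional).
#'
#' @param betas_list List of `beta_maps`, one per subject, all from the same
#'   FIR design and mask.
#' @param alpha Uncorrected voxel-wise threshold.
#' @param bins Integer pair: (higher, lower) adaptor positions contrasted.
#' @return List: `F`, `p`, `mean_d` (3D maps), `mask` (3D logical),
#'   `dof`, `alpha`, `bins`.
#' @export
adaptation_contrast <- function(betas_list, alpha = 0.001, bins = c(4L, 7L)) {
  if (length(betas_list) < 3L) stop("need at least 3 subjects")
  hi <- paste0("adaptor_", bins[1]); lo <- paste0("adaptor_", bins[2])
  D <- do.call(rbind, lapply(betas_list, function(b) {
    if (!all(c(hi, lo) %in% rownames(b$coef)))
      stop("subject betas lack ", hi, " or ", lo)
    b$coef[hi, ] - b$coef[lo, ]
  }))
  g <- group_one_sample_t(D)
  Fv <- g$t^2
  p <- stats::pf(Fv, 1, g$dof, lower.tail = FALSE)
  mask3 <- betas_list[[1]]$mask
  sig <- p < alpha & g$mean > 0
  list(F = embed_in_mask(Fv, mask3), p = embed_in_mask(p, mask3),
       mean_d = embed_in_mask(g$mean, mask3),
       mask = embed_in_mask(sig, mask3, fill = FALSE) & mask3,
       dof = g$dof, alpha = alpha, bins = bins)
}

#' Group deviants-versus-Identity contrast (sanity map)
#'
#' Per subject, the mean of the four deviant HRF betas minus the Identity
#' beta; across subjects, a one-sample t map. Reported as a sanity output,
#' never used as an analysis mask.
#'
#' @param betas_list List of `beta_maps` from the canonical-HRF design.
#' @return List: `t`, `p`, `mean_c` (3D maps), `dof`.
#' @export
deviants_vs_identity <- function(betas_list) {
  dev <- paste0("dev_", DEVIANT_BINS)
  C <- do.call(rbind, lapply(betas_list, function(b) {
    if (!all(c(dev, "dev_I") %in% rownames(b$coef)))
      stop("subject betas lack deviant or Identity regressors")
    colMeans(b$coef[dev, , drop = FALSE]) - b$coef["dev_I", ]
  }))
  g <- group_one_sample_t(C)
  p <- 2 * stats::pt(abs(g$t), g$dof, lower.tail = FALSE)
  mask3 <- betas_list[[1]]$mask
  list(t = embed_in_mask(g$t, mask3), p = embed_in_mask(p, mask3),
       mean_c = embed_in_mask(g$mean, mask3), dof = g$dof)
}
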