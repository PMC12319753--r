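make_vol <- function(Y, dims = NULL) {
  # wrap a time x voxel matrix as a volume_series on a minimal grid
  nv <- ncol(Y)
  if (is.null(dims)) dims <- c(nv, 1L, 1L)
  volume_series(array(t(Y), c(dims, nrow(Y))), tr = 1)
}

test_that("FIR design has 14 interest regressors with correct impulses", {
  ev <- build_fmri_run(demo_binnings(), seed = 1L)
  nv <- attr(ev, "n_vols")
  X <- build_fir_design(ev, nv, 1)
  expect_equal(X$interest,
               c(paste0("adaptor_", 1:9), paste0("deviant_", c(DEVIANT_BINS, "I"))))
  expect_equal(length(X$interest), 14L)
  # each adaptor_4 impulse sits at that event's volume
  col <- X$values[, "adaptor_4"]
  vols <- round(ev$onset[ev$stimulus_role == "adaptor_4"]) + 1L
  expect_equal(which(col == 1), vols)
  expect_true(all(col %in% c(0, 1)))
  # drift + intercept appended
  expect_true(all(c("drift_1", "intercept") %in% colnames(X$values)))
})

test_that("HRF design has 6 interest regressors equal to convolved trains", {
  ev <- build_fmri_run(demo_binnings(), seed = 2L)
  nv <- attr(ev, "n_vols")
  X <- build_hrf_design(ev, nv, 1)
  expect_equal(X$interest, c("adaptors", paste0("dev_", c(DEVIANT_BINS, "I"))))
  h <- double_gamma_hrf(1)
  train <- numeric(nv)
  sel <- round(ev$onset[ev$stimulus_role == "deviant" & ev$condition == "SD"]) + 1L
  train[sel] <- 1
  manual <- stats::convolve(train, rev(h), type = "open")[seq_len(nv)]
  expect_equal(unname(X$values[, "dev_SD"]), manual, tolerance = 1e-10)
})

test_that("design assembly validates inputs", {
  ev <- build_fmri_run(demo_binnings(), seed = 1L)
  nv <- attr(ev, "n_vols")
  ev0 <- ev[ev$condition != "I" | ev$stimulus_role != "deviant", ]
  expect_error(build_fir_design(ev0, nv, 1), "all-zero.*deviant_I")
  expect_error(build_fir_design(ev, nv, 1,
                                nuisance = matrix(0, 10, 24)), "n_vols rows")
  expect_warning(build_fir_design(ev, nv, 1,
                                  nuisance = matrix(rnorm(nv * 3), nv, 3)),
                 "24 nuisance")
  evx <- ev; evx$onset[2] <- evx$onset[2] + 0.5
  expect_error(build_fir_design(evx, nv, 1), "off the tr grid")
})

test_that("fit_glm reproduces exact coefficients and matches a generic solver", {
  # y exactly 2 x column j -> beta_j = 2, residuals 0
  ev <- build_fmri_run(demo_binnings(), seed = 3L)
  nv <- attr(ev, "n_vols")
  X <- build_fir_design(ev, nv, 1)
  y <- 2 * X$values[, "adaptor_4"]
  fit <- fit_glm(make_vol(cbind(y), dims = c(1L, 1L, 1L)), X)
  expect_equal(unname(fit$coef["adaptor_4", 1]), 2, tolerance = 1e-10)
  expect_equal(max(abs(fit$coef[setdiff(rownames(fit$coef), "adaptor_4"), 1])),
               0, tolerance = 1e-10)
  expect_equal(unname(fit$resvar[1]), 0, tolerance = 1e-12)

  # 50 x 10 toy problem against the normal-equations oracle
  Xt <- with_seed(1L, matrix(rnorm(500), 50, 10))
  colnames(Xt) <- paste0("c", 1:10)
  yt <- with_seed(2L, matrix(rnorm(100), 50, 2))
  Xd <- structure(list(values = Xt, names = colnames(Xt),
                       interest = colnames(Xt), tr = 1,
                       frame_times = 0:49), class = "design_matrix")
  fit2 <- fit_glm(make_vol(yt, dims = c(2L, 1L, 1L)), Xd)
  expect_equal(unname(fit2$coef), unname(ols_bf(Xt, yt)), tolerance = 1e-10)

  # pure-noise y: interest betas average to ~0 over 100 simulations
  bmean <- rowMeans(vapply(1:100, function(s) {
    yn <- with_seed(100 + s, matrix(rnorm(50), 50, 1))
    fit_glm(make_vol(yn, dims = c(1L, 1L, 1L)), Xd)$coef[, 1]
  }, numeric(10)))
  expect_lt(max(abs(bmean)), 0.06)
})

test_that("rank-deficient designs error with the collinear column named", {
  X <- with_seed(3L, matrix(rnorm(40 * 3), 40, 3))
  X <- cbind(X, dup = X[, 1])
  colnames(X)[1:3] <- paste0("c", 1:3)
  Xd <- structure(list(values = X, names = colnames(X), interest = "c1",
                       tr = 1, frame_times = 0:39), class = "design_matrix")
  expect_error(fit_glm(make_vol(matrix(rnorm(40), 40, 1),
                                dims = c(1L, 1L, 1L)), Xd),
               "collinear.*dup")
})

test_that("censor_volumes drops the settle trials and the tail only", {
  ev <- build_fmri_run(demo_binnings(), seed = 4L)
  nv <- attr(ev, "n_vols")
  keep <- censor_volumes(ev, nv, 1, settle_trials = 2L, censor_tail = TRUE)
  expect_length(keep, nv)
  expect_true(all(keep[1:16]))                     # lead fixation retained
  first_stim <- min(ev$onset) + 1
  t3 <- ev$onset[match(3L, ev$trial_index)]        # first kept trial onset
  expect_true(all(!keep[first_stim:t3]))
  expect_true(all(keep[(t3 + 1):(max(ev$onset) + 1)]))
  expect_true(all(!keep[(max(ev$onset) + 2):nv]))  # trailing fixation dropped
  # disabling both censors keeps everything
  expect_true(all(censor_volumes(ev, nv, 1, 0L, FALSE)))
  expect_error(censor_volumes(ev, nv, 1, settle_trials = 50L), "settle")
})

test_that("fit_glm with censoring ignores censored rows entirely", {
  ev <- build_fmri_run(demo_binnings(), seed = 5L)
  nv <- attr(ev, "n_vols")
  X <- build_fir_design(ev, nv, 1)
  keep <- censor_volumes(ev, nv, 1)
  y <- with_seed(6L, rnorm(nv))
  y[!keep] <- 1e6                                  # garbage in censored rows
  fit <- fit_glm(make_vol(cbind(y), dims = c(1L, 1L, 1L)), X, keep = keep)
  yc <- y; yc[!keep] <- 0
  fit2 <- fit_glm(make_vol(cbind(yc), dims = c(1L, 1L, 1L)), X, keep = keep)
  expect_equal(fit$coef, fit2$coef, tolerance = 1e-9)
  expect_equal(fit$dof, sum(keep) - ncol(X$values))
})

test_that("adaptation contrast: null, directionality, and subject checks", {
  mask <- array(TRUE, c(2, 2, 1))
  fake_betas <- function(d4, d7) {
    coef <- matrix(0, 9, 4, dimnames = list(paste0("adaptor_", 1:9), NULL))
    coef["adaptor_4", ] <- d4; coef["adaptor_7", ] <- d7
    structure(list(coef = coef, mask = mask, dims = dim(mask)),
              class = "beta_maps")
  }
  # all-zero differences -> empty mask
  ac0 <- adaptation_contrast(replicate(5, fake_betas(0, 0), simplify = FALSE))
  expect_false(any(ac0$mask))
  # strong positive difference with tiny jitter -> full mask; negative -> empty
  pos <- lapply(1:5, function(s) fake_betas(1 + 0.01 * s, 0))
  acp <- adaptation_contrast(pos)
  expect_true(all(acp$mask))
  expect_equal(acp$dof, 4L)
  neg <- lapply(1:5, function(s) fake_betas(0, 1 + 0.01 * s))
  expect_false(any(adaptation_contrast(neg)$mask))  # directional: mean d > 0
  expect_true(all(adaptation_contrast(neg)$F > 0))  # but F is large
  expect_error(adaptation_contrast(pos[1:2]), "3 subjects")
})

test_that("deviants-vs-identity contrast equals the hand-computed mean difference", {
  mask <- array(TRUE, c(1, 1, 1))
  mk <- function(vals) {
    coef <- matrix(vals, 5, 1,
                   dimnames = list(paste0("dev_", c(DEVIANT_BINS, "I")), NULL))
    structure(list(coef = coef, mask = mask, dims = dim(mask)),
              class = "beta_maps")
  }
  bl <- list(mk(c(2, 3, 4, 5, 1)), mk(c(1, 1, 1, 1, 1)), mk(c(4, 4, 4, 4, 2)))
  dv <- deviants_vs_identity(bl)
  cs <- c(mean(c(2, 3, 4, 5)) - 1, 0, 2)
  expect_equal(dv$mean_c[1, 1, 1], mean(cs), tolerance = 1e-12)
  tt <- stats::t.test(cs)
  expect_equal(dv$t[1, 1, 1], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(dv$p[1, 1, 1], tt$p.value, tolerance = 1e-10)
})

test_that("noise-free graded simulation yields a positive 4>7 contrast", {
  binnings <- demo_binnings()
  co <- simulate_cohort(binnings, n_subjects = 4L, n_runs = 1L,
                        noise = noise_off(), seed = 3L)
  fir <- lapply(co, function(sub) {
    run <- sub$runs[[1]]
    nv <- n_volumes(run$sim$vol)
    fit_glm(run$sim$vol,
            build_fir_design(run$events, nv, 1, run$sim$nuisance),
            keep = censor_volumes(run$events, nv, 1))
  })
  grid <- co[[1]]$runs[[1]]$sim$grid
  d <- vapply(fir, function(f)
    mean(f$coef["adaptor_4", as.vector(grid$graded_mask)[f$mask]] -
           f$coef["adaptor_7", as.vector(grid$graded_mask)[f$mask]]),
    numeric(1))
  expect_true(all(d > 0))
})
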