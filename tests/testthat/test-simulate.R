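test_that("noise-free RT means are exactly the planted condition means", {
  binnings <- demo_binnings()
  design <- build_behavioral_design(binnings, seed = 1L)
  params <- rt_gen_params(trial_sd = 0, subject_sd = 0, similarity_slope = 10,
                          base_rt = 420, miss_base_rate = 0,
                          miss_similarity_boost = 0, n_subjects = 3L)
  rt <- simulate_rt_dataset(design, params)
  means <- tapply(rt$rt_ms, rt$condition, mean)
  expect_equal(as.vector(means[c("SC", "C", "D", "SD")]),
               c(450, 440, 430, 420))
  # slope = 0 -> all condition means equal
  p0 <- rt_gen_params(trial_sd = 0, subject_sd = 0, similarity_slope = 0,
                      miss_base_rate = 0, miss_similarity_boost = 0,
                      n_subjects = 2L)
  m0 <- tapply(simulate_rt_dataset(design, p0)$rt_ms,
               simulate_rt_dataset(design, p0)$condition, mean)
  expect_true(all(abs(m0 - m0[1]) < 1e-12))
  # plateau flattens C and D to their midpoint
  pp <- rt_gen_params(trial_sd = 0, subject_sd = 0, plateau = TRUE,
                      miss_base_rate = 0, miss_similarity_boost = 0,
                      n_subjects = 2L)
  mp <- tapply(simulate_rt_dataset(design, pp)$rt_ms,
               simulate_rt_dataset(design, pp)$condition, mean)
  expect_equal(unname(mp["C"]), unname(mp["D"]))
  expect_equal(unname(mp["C"]), 435)
})

test_that("RT sample mean ordering SC > SD holds in >= 95% of 100 seeds", {
  binnings <- demo_binnings()
  design <- build_behavioral_design(binnings, seed = 1L)
  ok <- vapply(1:100, function(s) {
    rt <- simulate_rt_dataset(design, rt_gen_params(n_subjects = 20L, seed = s))
    m <- tapply(rt$rt_ms, rt$condition, mean, na.rm = TRUE)
    m[["SC"]] > m[["SD"]]
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("RT generator is reproducible and leaves misses as NA", {
  design <- build_behavioral_design(demo_binnings(), seed = 1L)
  p <- rt_gen_params(n_subjects = 4L, seed = 9L)
  r1 <- simulate_rt_dataset(design, p)
  expect_identical(r1, simulate_rt_dataset(design, p))
  expect_true(all(is.na(r1$rt_ms[!r1$responded])))
  expect_true(all(!is.na(r1$rt_ms[r1$responded])))
  expect_setequal(unique(r1$condition), DEVIANT_BINS)  # Identity omitted
})

test_that("voxel tuning models validate their shape constraints", {
  m <- voxel_tuning_model()
  expect_true(all(diff(m$weights) > 0))
  expect_error(voxel_tuning_model(release_profile = "graded_linear",
                                  weights = c(SC = .9, C = .7, D = .85, SD = 1)),
               "strictly increasing")
  expect_error(voxel_tuning_model(release_profile = "step_sc",
                                  weights = c(SC = .5, C = .8, D = .9, SD = .9)),
               "SC < C = D = SD")
  expect_error(voxel_tuning_model(identity_weight = 0.9), "identity_weight")
  expect_error(voxel_tuning_model(adapt_decay = 0))
})

test_that("neural amplitudes follow the decay rule by hand", {
  ev <- build_fmri_run(demo_binnings(), seed = 1L)
  m <- voxel_tuning_model(adapt_decay = 0.8, adapt_floor = 0.3)
  amp <- neural_amplitudes(ev, m)
  a4 <- amp[ev$stimulus_role == "adaptor_4"][1]
  a7 <- amp[ev$stimulus_role == "adaptor_7"][1]
  expect_equal(a4, 0.8^3)              # 0.512
  expect_equal(a7, 0.3)                # floor binds: 0.8^6 = 0.262 < 0.3
  # deviant amplitudes are the profile weights
  expect_equal(unique(amp[ev$stimulus_role == "deviant" & ev$condition == "SC"]),
               unname(m$weights["SC"]))
  expect_equal(unique(amp[ev$stimulus_role == "deviant" & ev$condition == "I"]),
               m$identity_weight)
})

test_that("noise-free clean signal equals a direct convolution", {
  ev <- build_fmri_run(demo_binnings(), seed = 2L)
  grid <- default_tuning_grid()
  sim <- simulate_bold_run(ev, grid = grid, noise = noise_off(), seed = 1L)
  nv <- attr(ev, "n_vols")
  h <- double_gamma_hrf(1)
  amp <- neural_amplitudes(ev, grid$models$graded)
  train <- numeric(nv)
  train[round(ev$onset) + 1L] <- amp
  manual <- numeric(nv)
  for (i in which(train != 0)) {
    span <- i:min(nv, i + length(h) - 1L)
    manual[span] <- manual[span] + train[i] * h[seq_along(span)]
  }
  expect_equal(unname(sim$clean[, "1"]), manual, tolerance = 1e-10)
  # all graded voxels carry the identical noise-free signal; background zero
  vox <- which(grid$graded_mask)[1]
  ix <- arrayInd(vox, grid$dims)
  expect_equal(sim$vol$data[ix[1], ix[2], ix[3], ], manual, tolerance = 1e-10)
  bg <- which(grid$null_mask)[1]
  ib <- arrayInd(bg, grid$dims)
  expect_true(all(sim$vol$data[ib[1], ib[2], ib[3], ] == 0))
})

test_that("flat no-adaptation voxels evoke identical responses per event", {
  ev <- build_fmri_run(demo_binnings(), seed = 3L)
  flat <- voxel_tuning_model(adapt_decay = 1, adapt_floor = 1,
                             release_profile = "flat", identity_weight = 1)
  amp <- neural_amplitudes(ev, flat)
  expect_true(all(amp == amp[1]))
})

test_that("graded voxel deviant-epoch peaks increase SC < C < D < SD", {
  ev <- build_fmri_run(demo_binnings(), seed = 4L)
  grid <- default_tuning_grid()
  sim <- simulate_bold_run(ev, grid = grid, noise = noise_off(), seed = 1L)
  h <- double_gamma_hrf(1)
  # isolate the deviant contribution: signal minus the adaptor-only signal
  amp_all <- neural_amplitudes(ev, grid$models$graded)
  nv <- attr(ev, "n_vols")
  conv <- function(a) {
    train <- numeric(nv); train[round(ev$onset) + 1L] <- a
    stats::convolve(train, rev(h), type = "open")[seq_len(nv)]
  }
  peaks <- vapply(DEVIANT_BINS, function(cc) {
    a <- ifelse(ev$stimulus_role == "deviant" & ev$condition == cc, amp_all, 0)
    max(conv(a))
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("simulated runs are bit-identical under the same seed", {
  ev <- build_fmri_run(demo_binnings(), seed = 5L)
  s1 <- simulate_bold_run(ev, seed = 42L)
  s2 <- simulate_bold_run(ev, seed = 42L)
  expect_identical(s1$vol$data, s2$vol$data)
  expect_identical(s1$nuisance, s2$nuisance)
  s3 <- simulate_bold_run(ev, seed = 43L)
  expect_false(identical(s1$vol$data, s3$vol$data))
})

test_that("off-grid event onsets are rejected", {
  ev <- build_fmri_run(demo_binnings(), seed = 6L)
  ev$onset[5] <- ev$onset[5] + 0.25
  expect_error(simulate_bold_run(ev), "grid")
})

test_that("nuisance matrix has 24 standardized named columns", {
  X <- make_nuisance(200L, seed = 3L)
  expect_equal(dim(X), c(200L, 24L))
  expect_equal(sum(grepl("^motion_", colnames(X))), 6L)
  expect_equal(sum(grepl("^cardiac_|^resp_|^cardresp_", colnames(X))), 18L)
  expect_true(all(abs(colMeans(X)) < 1e-10))
  expect_equal(unname(apply(X, 2, sd)), rep(1, 24L), tolerance = 1e-10)
  expect_identical(X, make_nuisance(200L, seed = 3L))
})

test_that("cohort structure: runs, shared subject scale, reproducibility", {
  binnings <- demo_binnings()
  co <- simulate_cohort(binnings, n_subjects = 2L, n_runs = 2L,
                        noise = noise_off(), seed = 5L)
  expect_length(co, 2L)
  expect_length(co[[1]]$runs, 2L)
  # different orderings across runs and subjects
  expect_false(identical(co[[1]]$runs[[1]]$events$adaptor_object,
                         co[[1]]$runs[[2]]$events$adaptor_object))
  expect_false(identical(co[[1]]$runs[[1]]$events$adaptor_object,
                         co[[2]]$runs[[1]]$events$adaptor_object))
  co2 <- simulate_cohort(binnings, n_subjects = 2L, n_runs = 2L,
                         noise = noise_off(), seed = 5L)
  expect_identical(co, co2)
})
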