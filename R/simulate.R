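#' Reaction-time generator parameters
#'
#' Defaults emulate the behavioral adaptation task: detection of a deviant
#' slows with adaptor-deviant similarity (SC slowest), with subject-level
#' random intercepts, trial noise, and a miss process whose rate is elevated
#' for the most similar deviants.
#'
#' @param base_rt Mean RT (ms) in the easiest (SD) condition.
#' @param similarity_slope RT increase (ms) per similarity step toward SC.
#' @param plateau If `TRUE`, the C and D condition means are flattened to
#'   their midpoint (the mid-similarity plateau seen in detection RTs).
#' @param subject_sd SD (ms) of the subject random intercept.
#' @param trial_sd SD (ms) of trial-level noise.
#' @param miss_base_rate Baseline probability of a miss (no response).
#' @param miss_similarity_boost Extra miss probability in the SC condition.
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @return An `rt_gen_params` list.
#' @export
rt_gen_params <- function(base_rt = 420, similarity_slope = 10, plateau = FALSE,
                          subject_sd = 25, trial_sd = 60,
                          miss_base_rate = 0.08, miss_similarity_boost = 0.03,
                          n_subjects = 22L, seed = 1L) {
  stopifnot(miss_base_rate >= 0, miss_base_rate <= 1,
            miss_similarity_boost >= 0,
            miss_base_rate + miss_similarity_boost <= 1,
            subject_sd >= 0, trial_sd >= 0, n_subjects >= 1L)
  structure(list(base_rt = base_rt, similarity_slope = similarity_slope,
                 plateau = plateau, subject_sd = subject_sd, trial_sd = trial_sd,
                 miss_base_rate = miss_base_rate,
                 miss_similarity_boost = miss_similarity_boost,
                 n_subjects = as.integer(n_subjects), seed = as.integer(seed)),
            class = "rt_gen_params")
}

# similarity steps above base: SD = 0 ... SC = 3 (optionally plateaued)
rt_condition_shift <- function(params) {
  steps <- c(SC = 3, C = 2, D = 1, SD = 0)
  if (isTRUE(params$plateau)) steps[c("C", "D")] <- 1.5
  params$base_rt + params$similarity_slope * steps
}

#' Simulate a behavioral reaction-time dataset
#'
#' Responses are only recorded for deviant-detection trials (SC, C, D, SD);
#' Identity trials require no response and are omitted. RT means decrease
#' from SC to SD by construction whenever `similarity_slope > 0`.
#'
#' @param design Trial data frame from [build_behavioral_design()].
#' @param params An [rt_gen_params()] object.
#' @return Data frame: `subject`, `trial`, `condition`, `rt_ms` (NA for a
#'   miss), `responded`.
#' @export
simulate_rt_dataset <- function(design, params = rt_gen_params()) {
  stopifnot(inherits(params, "rt_gen_params"),
            all(c("trial", "condition") %in% names(design)))
  dv <- design[design$condition %in% DEVIANT_BINS, c("trial", "condition")]
  shifts <- rt_condition_shift(params)
  with_seed(params$seed, {
    out <- lapply(seq_len(params$n_subjects), function(s) {
      intercept <- stats::rnorm(1, 0, params$subject_sd)
      mu <- shifts[dv$condition] + intercept
      rt <- mu + stats::rnorm(nrow(dv), 0, params$trial_sd)
      p_miss <- ifelse(dv$condition == "SC",
                       params$miss_base_rate + params$miss_similarity_boost,
                       params$miss_base_rate)
      missed <- stats::runif(nrow(dv)) < p_miss
      data.frame(subject = s, trial = dv$trial, condition = dv$condition,
                 rt_ms = ifelse(missed, NA_real_, rt),
                 responded = !missed, row.names = NULL)
    })
    do.call(rbind, out)
  })
}

#' Voxel tuning model
#'
#' Generative model of one voxel class: adaptor position `k` evokes neural
#' amplitude `amplitude * max(adapt_floor, adapt_decay^(k-1))`; a deviant of
#' condition `c` evokes `amplitude * weights[c]`. Two archetypes are
#' supported: `graded_linear` (release grows strictly with dissimilarity)
#' and `step_sc` (only the most-similar deviant stays suppressed).
#'
#' @param amplitude Response amplitude (arbitrary units).
#' @param adapt_decay Per-repetition multiplicative decay in (0, 1].
#' @param adapt_floor Floor as a fraction of `amplitude`.
#' @param release_profile `"graded_linear"`, `"step_sc"` or `"flat"`.
#' @param weights Named numeric (SC, C, D, SD) in \[0, 1\]; defaults depend
#'   on the profile.
#' @param identity_weight Weight of the Identity deviant; must not exceed
#'   the smallest deviant weight.
#' @return A `voxel_tuning_model`.
#' @export
voxel_tuning_model <- function(amplitude = 1,
                               adapt_decay = 0.30, adapt_floor = 0.20,
                               release_profile = c("graded_linear", "step_sc", "flat"),
                               weights = NULL, identity_weight = NULL) {
  release_profile <- match.arg(release_profile)
  if (is.null(weights))
    weights <- switch(release_profile,
                      graded_linear = c(SC = 0.55, C = 0.70, D = 0.85, SD = 1.00),
                      step_sc       = c(SC = 0.55, C = 0.90, D = 0.90, SD = 0.90),
                      flat          = c(SC = 1, C = 1, D = 1, SD = 1))
  stopifnot(identical(sort(names(weights)), sort(DEVIANT_BINS)),
            all(weights >= 0 & weights <= 1),
            adapt_decay > 0, adapt_decay <= 1, adapt_floor >= 0, adapt_floor <= 1)
  weights <- weights[DEVIANT_BINS]
  if (release_profile == "graded_linear" &&
      !all(diff(unname(weights)) > 0))
    stop("graded_linear requires strictly increasing weights SC < C < D < SD")
  if (release_profile == "step_sc" &&
      !(weights[["SC"]] < weights[["C"]] &&
        weights[["C"]] == weights[["D"]] && weights[["D"]] == weights[["SD"]]))
    stop("step_sc requires SC < C = D = SD")
  if (is.null(identity_weight)) identity_weight <- min(weights) * 0.9
  if (identity_weight > min(weights) + 1e-12)
    stop("identity_weight must not exceed the smallest deviant weight")
  structure(list(amplitude = amplitude, adapt_decay = adapt_decay,
                 adapt_floor = adapt_floor, release_profile = release_profile,
                 weights = weights, identity_weight = identity_weight),
            class = "voxel_tuning_model")
}

#' Planted neural amplitude of each event
#'
#' @param events An `event_table`.
#' @param model A [voxel_tuning_model()].
#' @return Numeric vector, one amplitude per event row.
#' @export
neural_amplitudes <- function(events, model) {
  stopifnot(inherits(model, "voxel_tuning_model"))
  w_all <- c(model$weights, I = model$identity_weight)
  vapply(seq_len(nrow(events)), function(i) {
    role <- events$stimulus_role[i]
    if (role == "deviant") {
      model$amplitude * w_all[[events$condition[i]]]
    } else {
      k <- as.integer(sub("adaptor_", "", role))
      model$amplitude * max(model$adapt_floor, model$adapt_decay^(k - 1))
    }
  }, numeric(1))
}

#' Default simulation grid with planted tuning regions
#'
#' A small volume with three planted regions: a graded-linear release block,
#' a step-like release block, and non-responsive background.
#'
#' @param dims Spatial dims.
#' @param models Named list with `graded` and `step` tuning models.
#' @return List with `dims`, `regions` (3D integer array: 0 background,
#'   1 graded, 2 step), `models` (list indexed by region code), and logical
#'   region masks `graded_mask`, `step_mask`, `null_mask`.
#' @export
default_tuning_grid <- function(dims = c(12L, 12L, 8L),
                                models = list(
                                  graded = voxel_tuning_model(release_profile = "graded_linear"),
                                  step = voxel_tuning_model(release_profile = "step_sc"))) {
  stopifnot(all(dims >= 8L))
  regions <- array(0L, dims)
  regions[2:5, 2:5, 2:5] <- 1L
  regions[(dims[1] - 4):(dims[1] - 1), (dims[2] - 4):(dims[2] - 1),
          (dims[3] - 4):(dims[3] - 1)] <- 2L
  list(dims = as.integer(dims), regions = regions, models = models,
       graded_mask = regions == 1L, step_mask = regions == 2L,
       null_mask = regions == 0L)
}

#' Simulated nuisance regressors
#'
#' Six motion-like regressors (integrated random walks) and eighteen
#' physiological regressors: six cardiac and eight respiratory harmonics
#' (sines/cosines with frequency jitter) plus four cardio-respiratory
#' interaction terms. All columns are standardized.
#'
#' @param n_vols Number of volumes.
#' @param tr Repetition time in seconds.
#' @param seed Integer seed.
#' @return `n_vols` x 24 matrix with named columns.
#' @export
make_nuisance <- function(n_vols, tr = 1, seed = 1L) {
  with_seed(seed, {
    t <- (seq_len(n_vols) - 1) * tr
    motion <- sapply(1:6, function(i) cumsum(stats::rnorm(n_vols, 0, 0.05)))
    # harmonics whose aliased frequency falls too close to DC degenerate
    # into drift-like columns and make the design rank-deficient; redraw
    # until every harmonic keeps at least 0.02 cycles/volume from an integer
    draw_f <- function(lo, hi, ks) {
      repeat {
        f <- stats::runif(1, lo, hi)
        al <- f * ks * tr
        if (all(abs(al - round(al)) > 0.02)) return(f)
      }
    }
    card_f <- draw_f(0.9, 1.2, 1:3)         # Hz (aliased at typical TR)
    resp_f <- draw_f(0.25, 0.35, 1:4)
    ph <- function(f, k) 2 * pi * f * k * t + stats::runif(1, 0, 2 * pi)
    cardiac <- do.call(cbind, lapply(1:3, function(k) cbind(sin(ph(card_f, k)), cos(ph(card_f, k)))))
    resp <- do.call(cbind, lapply(1:4, function(k) cbind(sin(ph(resp_f, k)), cos(ph(resp_f, k)))))
    inter <- cbind(cardiac[, 1] * resp[, 1], cardiac[, 1] * resp[, 2],
                   cardiac[, 2] * resp[, 1], cardiac[, 2] * resp[, 2])
    X <- cbind(motion, cardiac, resp, inter)
    X <- scale(X)
    X[is.na(X)] <- 0
    colnames(X) <- c(paste0("motion_", 1:6), paste0("cardiac_", 1:6),
                     paste0("resp_", 1:8), paste0("cardresp_", 1:4))
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
    X
  })
}

#' Default noise settings for the BOLD generator
#' @param ar1_phi AR(1) coefficient of the voxel noise.
#' @param sigma Innovation SD of the voxel noise (amplitude units).
#' @param drift_sd SD of the random linear drift amplitude per run.
#' @param nuisance_gain SD of per-voxel loadings on the nuisance regressors.
#' @export
bold_noise <- function(ar1_phi = 0.3, sigma = 0.15, drift_sd = 0.3,
                       nuisance_gain = 0.05) {
  list(ar1_phi = ar1_phi, sigma = sigma, drift_sd = drift_sd,
       nuisance_gain = nuisance_gain)
}

#' Noise-free generator settings
#' @export
noise_off <- function() bold_noise(ar1_phi = 0, sigma = 0, drift_sd = 0,
                                   nuisance_gain = 0)

#' Simulate one BOLD run
#'
#' Plants, per region of the grid, an event amplitude train (adaptation
#' decay along the sequence, similarity-graded release at the deviant),
#' convolves it with the canonical HRF on the acquisition grid, and adds a
#' random linear drift, AR(1) noise, and small linear contributions of 24
#' simulated nuisance regressors (6 motion + 18 physiological).
#'
#' @param events `event_table` from [build_fmri_run()]; onsets must lie on
#'   the `tr` grid.
#' @param grid Planted-region grid from [default_tuning_grid()].
#' @param noise [bold_noise()] settings (use [noise_off()] to disable).
#' @param tr Repetition time in seconds.
#' @param n_vols Number of volumes (default from the events attributes).
#' @param subject_scale Multiplier on all planted amplitudes (between-subject
#'   variation).
#' @param seed Integer seed; identical seeds give bit-identical runs.
#' @return List: `vol` (a [volume_series()]), `nuisance` (n_vols x 24),
#'   `clean` (n_vols x n_region-models matrix of noise-free signals),
#'   `grid`.
#' @export
simulate_bold_run <- function(events, grid = default_tuning_grid(),
                              noise = bold_noise(), tr = 1.0,
                              n_vols = attr(events, "n_vols"),
                              subject_scale = 1, seed = 1L) {
  if (is.null(n_vols)) stop("n_vols not given and not recorded on the events")
  vol_idx <- events$onset / tr
  if (any(abs(vol_idx - round(vol_idx)) > 1e-9))
    stop("event onset off the tr grid at row ",
         which(abs(vol_idx - round(vol_idx)) > 1e-9)[1])
  vol_idx <- as.integer(round(vol_idx)) + 1L   # 1-based volume index
  if (any(vol_idx > n_vols)) stop("event beyond the run length")
  h <- double_gamma_hrf(tr)
  region_codes <- sort(unique(as.vector(grid$regions)))
  region_codes <- region_codes[region_codes > 0L]
  clean <- matrix(0, n_vols, length(region_codes))
  colnames(clean) <- as.character(region_codes)
  for (j in seq_along(region_codes)) {
    model <- grid$models[[region_codes[j]]]
    amp <- neural_amplitudes(events, model) * subject_scale
    train <- numeric(n_vols)
    train[vol_idx] <- train[vol_idx] + amp
    conv <- stats::convolve(train, rev(h), type = "open")[seq_len(n_vols)]
    clean[, j] <- conv
  }
  nv <- prod(grid$dims)
  region_vec <- as.vector(grid$regions)
  with_seed(seed, {
    nuisance <- make_nuisance(n_vols, tr, seed = derive_seed(seed, 1L))
    data <- matrix(0, n_vols, nv)
    for (j in seq_along(region_codes))
      data[, region_vec == region_codes[j]] <- clean[, j]
    if (noise$drift_sd > 0) {
      slope <- stats::rnorm(1, 0, noise$drift_sd)
      data <- data + slope * seq(-0.5, 0.5, length.out = n_vols)
    }
    if (noise$nuisance_gain > 0) {
      load <- matrix(stats::rnorm(ncol(nuisance) * nv, 0, noise$nuisance_gain),
                     ncol(nuisance), nv)
      data <- data + nuisance %*% load
    }
    if (noise$sigma > 0) {
      eps <- matrix(stats::rnorm(n_vols * nv, 0, noise$sigma), n_vols, nv)
      if (noise$ar1_phi != 0)
        eps <- apply(eps, 2, function(e)
          as.numeric(stats::filter(e, noise$ar1_phi, method = "recursive")))
      data <- data + eps
    }
    arr <- array(t(data), dim = c(grid$dims, n_vols))
    list(vol = volume_series(arr, tr = tr),
         nuisance = nuisance, clean = clean, grid = grid)
  })
}

#' Simulate a cohort of subjects
#'
#' Each subject gets `n_runs` runs, each with its own trial ordering and
#' noise stream (seeded), plus a subject-level amplitude scale (log-normal,
#' ~10% SD) shared across that subject's runs.
#'
#' @param binnings Similarity binnings for the adaptors.
#' @param n_subjects Number of subjects.
#' @param n_runs Runs per subject.
#' @param grid Planted-region grid.
#' @param noise Noise settings.
#' @param tr Repetition time.
#' @param seed Base seed; per-subject and per-run seeds are derived from it.
#' @param subject_amp_sd SD of the log-normal amplitude scale.
#' @return List of per-subject lists: `runs` (each a list with `events` and
#'   `sim`, see [simulate_bold_run()]) and `scale`.
#' @export
simulate_cohort <- function(binnings, n_subjects = 12L, n_runs = 3L,
                            grid = default_tuning_grid(),
                            noise = bold_noise(), tr = 1.0, seed = 1L,
                            subject_amp_sd = 0.1) {
  stopifnot(n_subjects >= 1L, n_runs >= 1L)
  lapply(seq_len(n_subjects), function(s) {
    sseed <- derive_seed(seed, s)
    scale <- with_seed(derive_seed(sseed, 997L),
                       exp(stats::rnorm(1, 0, subject_amp_sd)))
    runs <- lapply(seq_len(n_runs), function(r) {
      rseed <- derive_seed(sseed, r)
      events <- build_fmri_run(binnings, tr = tr, seed = rseed)
      sim <- simulate_bold_run(events, grid = grid, noise = noise, tr = tr,
                               subject_scale = scale,
                               seed = derive_seed(rseed, 13L))
      list(events = events, sim = sim)
    })
    list(runs = runs, scale = scale)
  })
}
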