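#' Default pipeline configuration
#'
#' Returns the demo configuration: synthetic feature norms, the standard
#' behavioral and fMRI designs, a simulated cohort on the default planted
#' grid, FIR + HRF GLMs, release inference and tuning-curve clustering.
#' Any entry can be overridden via a (possibly nested) list or a YAML file.
#'
#' @param overrides Named list (or path to a YAML file) merged over the
#'   defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(overrides = NULL) {
  cfg <- list(
    seed = 1L,
    out_dir = "adaptune-out",
    stages = c("norms", "design", "behavior", "simulate_glm", "release",
               "clusters"),
    norms = list(csv = NULL, n_objects = 40L, n_features = 160L),
    design = list(n_adaptors = 10L, lengths = 5:9, reps_per_cell = 2L),
    behavior = list(n_subjects = 22L, similarity_slope = 10, base_rt = 420,
                    plateau = FALSE),
    simulate = list(n_subjects = 12L, n_runs = 3L, tr = 1.0,
                    noise = list(ar1_phi = 0.3, sigma = 0.15, drift_sd = 0.3,
                                 nuisance_gain = 0.05)),
    glm = list(alpha_adapt = 0.001, bins = c(4L, 7L), drift_order = 1L,
               settle_trials = 2L, censor_tail = TRUE),
    release = list(n_perm = 1000L, alpha = 0.001, stat = "r2",
                   tfce = list(H = 2, E = 0.5, connectivity = 26L)),
    clusters = list(k = NULL, k_range = 2:6, consensus = 0.75)
  )
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  if (!is.null(overrides)) cfg <- modify_list_deep(cfg, overrides)
  if (cfg$release$alpha <= 0 || cfg$release$alpha >= 1)
    stop("release alpha must be in (0,1)")
  structure(cfg, class = c("pipeline_config", "list"))
}

modify_list_deep <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- modify_list_deep(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Run the full release-from-adaptation pipeline
#'
#' Executes the requested stages — similarity norms and binning, design
#' generation, behavioral simulation + statistics, BOLD simulation + GLMs,
#' release inference, tuning-curve clustering — writing artifacts and a
#' provenance manifest under `config$out_dir`. Identical configurations
#' produce identical results.
#'
#' @param config A [pipeline_config()] (or overrides accepted by it).
#' @param write Write artifacts to disk (set `FALSE` for in-memory use).
#' @return Invisible list with the stage results (`sim_matrix`, `binnings`,
#'   `behavior`, `adaptation`, `dev_vs_identity`, `release`, `clusters`,
#'   `manifest`, ...).
#' @export
run_pipeline <- function(config = pipeline_config(), write = TRUE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (!is.null(config$norms$csv) && !file.exists(config$norms$csv))
    stop("stage norms: norms CSV not found: ", config$norms$csv)
  out <- list(config = config)
  dir_ <- config$out_dir
  if (write) dir.create(dir_, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  path <- function(...) file.path(dir_, paste0(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    r <- tryCatch(force(expr), error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[adaptune] stage %-12s %6.1f s", name, proc.time()[3] - t0))
    r
  }

  ## norms + similarity + binning
  norms <- stage("norms", {
    if (!is.null(config$norms$csv)) load_feature_norms(config$norms$csv)
    else simulate_feature_norms(config$norms$n_objects,
                                config$norms$n_features,
                                seed = derive_seed(seed, 101L))
  })
  sim <- cosine_similarity_matrix(norms)
  adaptors <- pick_adaptors(sim, config$design$n_adaptors,
                            seed = derive_seed(seed, 102L))
  binnings <- assign_bins(sim, adaptors, seed = derive_seed(seed, 103L))
  out$norms <- norms; out$sim_matrix <- sim; out$binnings <- binnings
  if (write) {
    write_similarity_matrix(sim, path("similarity.csv"))
    write_binnings_tsv(binnings, path("binnings.tsv"))
  }
  if (!"design" %in% config$stages) return(finish_pipeline(out, write))

  ## behavioral design + events for one example fMRI run
  design <- stage("design", build_behavioral_design(
    binnings, config$design$n_adaptors, config$design$lengths,
    config$design$reps_per_cell, seed = derive_seed(seed, 104L)))
  events <- build_fmri_run(binnings, tr = config$simulate$tr,
                           seed = derive_seed(seed, 105L))
  out$design <- design; out$events <- events
  if (write) {
    utils::write.table(design, path("behavioral_design.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_events_tsv(events, path("events_run1.tsv"))
  }

  ## behavioral simulation + stats
  if ("behavior" %in% config$stages) {
    out$behavior <- stage("behavior", {
      params <- rt_gen_params(base_rt = config$behavior$base_rt,
                              similarity_slope = config$behavior$similarity_slope,
                              plateau = config$behavior$plateau,
                              n_subjects = config$behavior$n_subjects,
                              seed = derive_seed(seed, 106L))
      rt <- simulate_rt_dataset(design, params)
      list(rt = rt, stats = analyze_behavior(rt))
    })
    if (write) {
      utils::write.csv(out$behavior$rt, path("rt_trials.csv"), row.names = FALSE)
      jsonlite::write_json(behavior_report(out$behavior$stats),
                           path("behavior_stats.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }
  }
  if (!"simulate_glm" %in% config$stages) return(finish_pipeline(out, write))

  ## cohort simulation + subject GLMs
  grid <- default_tuning_grid()
  noise <- do.call(bold_noise, config$simulate$noise)
  glms <- stage("simulate_glm", {
    cohort <- simulate_cohort(binnings, config$simulate$n_subjects,
                              n_runs = config$simulate$n_runs,
                              grid = grid, noise = noise,
                              tr = config$simulate$tr,
                              seed = derive_seed(seed, 107L))
    fit_cohort_glms(cohort, drift_order = config$glm$drift_order,
                    settle_trials = config$glm$settle_trials,
                    censor_tail = config$glm$censor_tail)
  })
  out$grid <- grid
  out$fir_betas <- glms$fir; out$hrf_betas <- glms$hrf
  adapt <- stage("adaptation", adaptation_contrast(
    glms$fir, alpha = config$glm$alpha_adapt, bins = config$glm$bins))
  out$adaptation <- adapt
  out$dev_vs_identity <- deviants_vs_identity(glms$hrf)
  if (write) {
    aff <- diag(4)
    write_mask_nifti(adapt$mask, aff, path("adaptation_mask.nii.gz"))
    write_mask_nifti(adapt$F, aff, path("adaptation_F.nii.gz"))
    write_mask_nifti(out$dev_vs_identity$t, aff, path("dev_vs_identity_t.nii.gz"))
  }
  if (!"release" %in% config$stages) return(finish_pipeline(out, write))

  ## release inference
  rel <- stage("release", {
    if (!any(adapt$mask)) stop("empty adaptation mask")
    run_release(glms$hrf, adapt$mask, stat = config$release$stat,
                n_perm = config$release$n_perm,
                params = tfce_params(H = config$release$tfce$H,
                                     E = config$release$tfce$E,
                                     connectivity = config$release$tfce$connectivity),
                alpha = config$release$alpha,
                seed = derive_seed(seed, 108L))
  })
  out$release <- rel
  if (write) {
    aff <- diag(4)
    write_mask_nifti(rel$final_mask, aff, path("release_mask.nii.gz"))
    write_mask_nifti(rel$mean_slope, aff, path("mean_slope.nii.gz"))
    utils::write.csv(data.frame(null_max = rel$perm$null_max),
                     path("perm_null_max.csv"), row.names = FALSE)
  }
  if (!"clusters" %in% config$stages) return(finish_pipeline(out, write))

  ## tuning-curve clustering
  out$clusters <- stage("clusters", {
    if (!any(rel$final_mask)) stop("empty release mask")
    ba <- deviant_beta_array(glms$hrf, rel$final_mask)
    group_z <- zscore_rows(apply(ba, c(2, 3), mean))
    ksel <- select_k_calinski_harabasz(group_z, config$clusters$k_range,
                                       seed = derive_seed(seed, 109L))
    k <- config$clusters$k %||% ksel$k
    loo <- loo_cluster_rois(ba, k = k, seed = derive_seed(seed, 110L))
    cons <- consensus_mask(loo, config$clusters$consensus)
    cmp <- compare_clusters(ba, cons)
    list(k_selection = ksel, k = k, loo = loo, consensus = cons,
         comparison = cmp)
  })
  if (write) {
    cl <- out$clusters
    # consensus masks back in volume space
    vox <- which(rel$final_mask)
    for (c_ in seq_len(cl$k)) {
      m <- array(FALSE, dim(rel$final_mask))
      m[vox[cl$consensus[, c_]]] <- TRUE
      write_mask_nifti(m, diag(4), path(sprintf("cluster%d_consensus.nii.gz", c_)))
    }
    utils::write.table(cl$comparison$cluster_summary,
                       path("cluster_curves.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(cluster_report(cl), path("cluster_stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  finish_pipeline(out, write)
}

# Per-subject FIR and HRF fits; with several runs per subject, the run-wise
# beta maps are averaged (classic fixed-effects combination feeding the
# random-effects group stage). Boundary censoring applies to the FIR model
# only — the HRF model represents run-boundary transients by construction.
fit_cohort_glms <- function(cohort, drift_order = 1L, settle_trials = 2L,
                            censor_tail = TRUE) {
  fit_subject <- function(sub, builder, censor) {
    fits <- lapply(sub$runs, function(run) {
      vol <- run$sim$vol
      nv <- n_volumes(vol)
      X <- builder(run$events, nv, vol$tr, run$sim$nuisance, drift_order)
      keep <- if (censor)
        censor_volumes(run$events, nv, vol$tr, settle_trials, censor_tail)
      fit_glm(vol, X, keep = keep)
    })
    average_beta_maps(fits)
  }
  list(fir = lapply(cohort, fit_subject, build_fir_design, censor = TRUE),
       hrf = lapply(cohort, fit_subject, build_hrf_design, censor = FALSE))
}

# average run-wise beta_maps of one subject (matching regressors and mask)
average_beta_maps <- function(fits) {
  if (length(fits) == 1L) return(fits[[1]])
  stopifnot(all(vapply(fits, function(f)
    identical(rownames(f$coef), rownames(fits[[1]]$coef)) &&
      identical(f$mask, fits[[1]]$mask), logical(1))))
  out <- fits[[1]]
  out$coef <- Reduce(`+`, lapply(fits, `[[`, "coef")) / length(fits)
  out$resvar <- Reduce(`+`, lapply(fits, `[[`, "resvar")) / length(fits)
  out$dof <- sum(vapply(fits, `[[`, numeric(1), "dof"))
  out
}

# subjects x voxels x 4 deviant-beta array at the masked voxels
deviant_beta_array <- function(hrf_betas, mask) {
  sel <- mask[hrf_betas[[1]]$mask]
  n_sub <- length(hrf_betas)
  ba <- array(NA_real_, c(n_sub, sum(sel), 4L))
  for (s in seq_len(n_sub))
    ba[s, , ] <- t(hrf_betas[[s]]$coef[paste0("dev_", DEVIANT_BINS), sel,
                                       drop = FALSE])
  ba
}

behavior_report <- function(stats) {
  list(anova_rt = stats$anova_rt, anova_miss = stats$anova_miss,
       pairwise_rt = stats$pairwise_rt, pairwise_miss = stats$pairwise_miss,
       summary = stats$summary)
}

cluster_report <- function(cl) {
  list(k = cl$k, ch_index = as.list(cl$k_selection$ch),
       low_confidence = cl$k_selection$low_confidence,
       slope_t = cl$comparison$slope_t,
       slope_wilcoxon = cl$comparison$slope_wilcoxon,
       deviant_pairs = cl$comparison$deviant_pairs,
       excluded_subjects = cl$comparison$excluded)
}

finish_pipeline <- function(out, write) {
  if (write) {
    cfg <- out$config
    manifest <- list(
      package = "adaptune",
      version = as.character(utils::packageVersion("adaptune")),
      timestamp = format(Sys.time(), tz = "UTC"),
      seed = cfg$seed,
      stages = cfg$stages,
      config = unclass(cfg),
      input_hashes = if (!is.null(cfg$norms$csv))
        as.list(tools::md5sum(cfg$norms$csv)) else NULL,
      artifacts = list.files(cfg$out_dir)
    )
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    out$manifest <- manifest
  }
  invisible(out)
}
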