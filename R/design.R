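#' Build the behavioral adaptation design
#'
#' Fully crossed design: for each adaptor, each adaptation length and each
#' deviant condition appears `reps_per_cell` times (defaults give
#' 10 x 5 x 5 x 2 = 500 trials, so each deviant condition occurs 100 times).
#' Trial order is a seeded shuffle constrained so the same adaptor never
#' occupies two consecutive trials.
#'
#' @param binnings Named list of `similarity_binning` objects (one per
#'   adaptor), e.g. from [assign_bins()].
#' @param n_adaptors Number of adaptors to use (taken from `binnings`).
#' @param lengths Integer vector of adaptation sequence lengths.
#' @param reps_per_cell Trials per (adaptor, length, condition) cell.
#' @param n_deviant_presentations Deviant repetitions per trial (3 in the
#'   behavioral task).
#' @param seed Integer seed for the trial-order shuffle.
#' @return A data frame of trial specs: `trial`, `adaptor_object`,
#'   `adaptation_length`, `condition`, `deviant_object`,
#'   `n_deviant_presentations`.
#' @export
build_behavioral_design <- function(binnings, n_adaptors = 10L, lengths = 5:9,
                                    reps_per_cell = 2L,
                                    n_deviant_presentations = 3L, seed = 1L) {
  stopifnot(all(lengths %in% 5:9), reps_per_cell >= 1L)
  adaptors <- names(binnings)
  if (length(adaptors) < n_adaptors)
    stop("need binnings for ", n_adaptors, " adaptors, got ", length(adaptors))
  adaptors <- adaptors[seq_len(n_adaptors)]
  grid <- expand.grid(adaptor_object = adaptors,
                      adaptation_length = as.integer(lengths),
                      condition = ALL_CONDITIONS,
                      rep = seq_len(reps_per_cell),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$deviant_object <- vapply(seq_len(nrow(grid)), function(i) {
    b <- binnings[[grid$adaptor_object[i]]]
    if (is.null(b)) stop("missing binning for adaptor ", grid$adaptor_object[i])
    if (grid$condition[i] == "I") grid$adaptor_object[i] else
      unname(b$deviants[[grid$condition[i]]])
  }, character(1))
  ord <- with_seed(seed, shuffle_no_repeat(grid$adaptor_object))
  out <- grid[ord, c("adaptor_object", "adaptation_length", "condition",
                     "deviant_object")]
  out$n_deviant_presentations <- as.integer(n_deviant_presentations)
  out <- cbind(trial = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

# Seeded shuffle of indices such that equal keys are never adjacent.
# Draws are uniform among the admissible remaining items; restarts on the
# rare dead end. With a single distinct key the constraint is vacuous and a
# plain shuffle is returned.
shuffle_no_repeat <- function(keys, max_tries = 100L) {
  n <- length(keys)
  if (length(unique(keys)) == 1L) return(sample.int(n))
  for (try in seq_len(max_tries)) {
    remaining <- seq_len(n)
    out <- integer(n)
    prev <- ""
    ok <- TRUE
    for (i in seq_len(n)) {
      cand <- remaining[keys[remaining] != prev]
      if (!length(cand)) { ok <- FALSE; break }
      pick <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
      out[i] <- pick
      prev <- keys[pick]
      remaining <- remaining[remaining != pick]
    }
    if (ok) return(out)
  }
  stop("could not order trials without adjacent repeats of an adaptor")
}

#' Build one fMRI run and its event table
#'
#' One run holds `trials_per_run` trials: every adaptor paired once with
#' every deviant condition (so 10 trials per condition with 10 adaptors),
#' with adaptation lengths assigned per adaptor as a permutation of
#' `lengths` (so 10 trials per length). Each stimulus lasts `stim_dur`
#' seconds followed by a blank of `isi` seconds (one stimulus per second at
#' the defaults, matching a 1 s acquisition grid); the deviant is shown
#' `deviant_reps` times; the run starts and ends with 16 s of fixation.
#'
#' @param binnings Named list of `similarity_binning` objects.
#' @param trials_per_run Number of trials (must equal adaptors x conditions).
#' @param lengths Adaptation lengths (one permutation per adaptor).
#' @param stim_dur,isi Stimulus and blank durations in seconds.
#' @param lead_fix,trail_fix Fixation before the first / after the last
#'   stimulus, seconds.
#' @param deviant_reps Deviant presentations per trial (2 in the scanner).
#' @param tr Acquisition grid in seconds; onsets are snapped to it.
#' @param seed Integer seed (length assignment and trial order).
#' @return An `event_table` data frame: `onset`, `duration`, `trial_type`,
#'   `trial_index`, `stimulus_role`, `condition`, `adaptor_object`,
#'   `deviant_object`; attributes `n_vols`, `tr`, `lead_fix`, `trail_fix`.
#' @export
build_fmri_run <- function(binnings, trials_per_run = 50L, lengths = 5:9,
                           stim_dur = 0.5, isi = 0.5,
                           lead_fix = 16, trail_fix = 16,
                           deviant_reps = 2L, tr = 1.0, seed = 1L) {
  adaptors <- names(binnings)
  n_cond <- length(ALL_CONDITIONS)
  if (trials_per_run != length(adaptors) * n_cond)
    stop("trials_per_run (", trials_per_run, ") must equal adaptors x conditions (",
         length(adaptors) * n_cond, ")")
  if (length(lengths) != n_cond)
    stop("need one adaptation length per condition cell")
  sdur <- stim_dur + isi
  if (abs(sdur %% tr) > 1e-9 && abs(sdur %% tr - tr) > 1e-9)
    stop("stimulus+blank duration must be a multiple of tr")
  with_seed(seed, {
    grid <- do.call(rbind, lapply(adaptors, function(a) {
      data.frame(adaptor_object = a,
                 condition = sample(ALL_CONDITIONS),
                 adaptation_length = as.integer(sample(lengths)),
                 stringsAsFactors = FALSE)
    }))
    ord <- shuffle_no_repeat(grid$adaptor_object)
    grid <- grid[ord, ]
    rows <- vector("list", nrow(grid))
    onset <- lead_fix
    for (i in seq_len(nrow(grid))) {
      a <- grid$adaptor_object[i]
      cond <- grid$condition[i]
      L <- grid$adaptation_length[i]
      dev <- if (cond == "I") a else unname(binnings[[a]]$deviants[[cond]])
      n_ev <- L + deviant_reps
      role <- c(paste0("adaptor_", seq_len(L)), rep("deviant", deviant_reps))
      rows[[i]] <- data.frame(
        onset = onset + sdur * (seq_len(n_ev) - 1L),
        duration = stim_dur,
        trial_type = c(paste0("adaptor_", seq_len(L)),
                       rep(paste0("deviant_", cond), deviant_reps)),
        trial_index = i,
        stimulus_role = role,
        condition = cond,
        adaptor_object = a,
        deviant_object = dev,
        stringsAsFactors = FALSE)
      onset <- onset + sdur * n_ev
    }
    ev <- do.call(rbind, rows)
    rownames(ev) <- NULL
    run_dur <- onset + trail_fix
    structure(ev, class = c("event_table", "data.frame"),
              tr = tr, n_vols = as.integer(ceiling(run_dur / tr)),
              lead_fix = lead_fix, trail_fix = trail_fix)
  })
}

validate_events <- function(events) {
  need <- c("onset", "duration", "trial_type")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("event table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(events)) {
    if (any(diff(events$onset) <= 0)) stop("event onsets must be strictly increasing")
    if (any(events$duration <= 0)) stop("event durations must be positive")
    ends <- events$onset + events$duration
    if (any(ends[-length(ends)] > events$onset[-1] + 1e-9))
      stop("events overlap")
  }
  invisible(events)
}

#' Write / read an events table as BIDS-style TSV
#'
#' Columns `onset`, `duration`, `trial_type` come first; any extra columns
#' are preserved. Writing refuses invalid tables; reading re-validates
#' (non-monotone onsets are an error).
#'
#' @param events An `event_table` (or compatible data frame).
#' @param path TSV path.
#' @return `write_events_tsv` returns the path invisibly; `read_events_tsv`
#'   returns an `event_table`.
#' @export
write_events_tsv <- function(events, path) {
  validate_events(events)
  first <- c("onset", "duration", "trial_type")
  df <- as.data.frame(events)[, c(first, setdiff(names(events), first)), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_events(df)
  structure(df, class = c("event_table", "data.frame"))
}
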