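#' Load feature-production norms from CSV
#'
#' Reads a table of feature-production frequencies: one row per object, the
#' first column holding the object label and the remaining columns holding
#' non-negative integer counts (the number of participants who produced each
#' feature for that object). Empty cells are treated as zero.
#'
#' @param path Path to a UTF-8 CSV file with a header row of feature labels.
#' @return A `feature_norms` object: list with `object_ids`, `feature_ids`
#'   and `freq` (integer matrix, objects x features).
#' @export
load_feature_norms <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("norms CSV needs an object column plus at least one feature column")
  object_ids <- as.character(raw[[1L]])
  if (anyDuplicated(object_ids))
    stop("duplicate object labels in norms CSV: ",
         paste(unique(object_ids[duplicated(object_ids)]), collapse = ", "))
  freq <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(freq) <- "double"
  freq[is.na(freq)] <- 0
  if (any(freq < 0)) stop("negative production frequencies in norms CSV")
  if (any(freq != round(freq)))
    warning("non-integer production frequencies; rounding")
  freq <- round(freq)
  storage.mode(freq) <- "integer"
  feature_norms(object_ids, colnames(freq), freq)
}

#' Construct a feature-norms table
#'
#' @param object_ids Character vector of unique object labels.
#' @param feature_ids Character vector of feature labels.
#' @param freq Non-negative integer matrix (objects x features) of
#'   production-frequency counts.
#' @return A `feature_norms` object.
#' @export
feature_norms <- function(object_ids, feature_ids, freq) {
  freq <- as.matrix(freq)
  stopifnot(length(object_ids) == nrow(freq), length(feature_ids) == ncol(freq))
  if (anyDuplicated(object_ids)) stop("object_ids must be unique")
  if (any(freq < 0)) stop("production frequencies must be non-negative")
  dimnames(freq) <- list(object_ids, feature_ids)
  structure(list(object_ids = as.character(object_ids),
                 feature_ids = as.character(feature_ids),
                 freq = freq),
            class = "feature_norms")
}

#' @export
print.feature_norms <- function(x, ...) {
  cat("Feature-production norms:", length(x$object_ids), "objects x",
      length(x$feature_ids), "features\n")
  invisible(x)
}

#' Write feature norms to CSV
#' @param norms A `feature_norms` object.
#' @param path Output CSV path.
#' @export
write_feature_norms <- function(norms, path) {
  df <- data.frame(object = norms$object_ids, norms$freq,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Cosine similarity between objects from production frequencies
#'
#' Similarity between two objects is the cosine of the angle between their
#' feature-frequency vectors: `dot(f_i, f_j) / (||f_i|| * ||f_j||)`. With
#' non-negative counts this lies in `[0, 1]`; 1 means proportional feature
#' profiles, 0 means disjoint feature sets.
#'
#' @param norms A `feature_norms` object; every object must have at least one
#'   positive count.
#' @return A `similarity_matrix` object: symmetric matrix with unit diagonal
#'   plus the object labels.
#' @export
cosine_similarity_matrix <- function(norms) {
  stopifnot(inherits(norms, "feature_norms"))
  f <- norms$freq
  storage.mode(f) <- "double"
  nrm <- sqrt(rowSums(f^2))
  if (any(nrm == 0))
    stop("object(s) with all-zero feature vector: ",
         paste(norms$object_ids[nrm == 0], collapse = ", "))
  s <- tcrossprod(f / nrm)
  s <- pmin(pmax(s, 0), 1)             # clip fp jitter at the boundaries
  diag(s) <- 1
  s <- (s + t(s)) / 2
  dimnames(s) <- list(norms$object_ids, norms$object_ids)
  structure(list(values = s, object_ids = norms$object_ids),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  off <- x$values[lower.tri(x$values)]
  cat("Cosine similarity matrix:", length(x$object_ids), "objects; off-diagonal range [",
      round(min(off), 3), ",", round(max(off), 3), "]\n")
  invisible(x)
}

#' Write a similarity matrix to CSV
#' @param sim A `similarity_matrix`.
#' @param path Output CSV path.
#' @export
write_similarity_matrix <- function(sim, path) {
  df <- data.frame(object = sim$object_ids, sim$values,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Default similarity bin edges
#'
#' Quartile cut points of the off-diagonal similarity distribution, yielding
#' four half-open intervals (closed on the low side) for the SD, D, C and SC
#' bins in increasing similarity.
#'
#' @param sim A `similarity_matrix`.
#' @return Numeric vector of 5 increasing edges; interval `i` is
#'   `[edges[i], edges[i+1])` (the top interval is closed above).
#' @export
default_bin_edges <- function(sim) {
  off <- sim$values[lower.tri(sim$values)]
  e <- stats::quantile(off, probs = c(0, .25, .5, .75, 1), names = FALSE)
  if (any(diff(e) <= 0)) stop("degenerate similarity distribution; supply bin_edges explicitly")
  e
}

bin_of <- function(x, edges) {
  # half-open [lo, hi), ties at an edge go to the lower-similarity bin;
  # the top interval is closed above so the maximum is binnable
  b <- findInterval(x, edges, rightmost.closed = TRUE)
  b[b < 1L | b > 4L] <- NA_integer_
  b
}

#' Assign deviants to similarity bins for each adaptor
#'
#' For every adaptor, picks one deviant object per similarity bin
#' (SC = most similar ... SD = least similar), sampled uniformly among the
#' candidates whose similarity to the adaptor falls inside the bin's
#' interval. The chosen deviants necessarily satisfy the strict ordering
#' sim(SC) > sim(C) > sim(D) > sim(SD).
#'
#' @param sim A `similarity_matrix`.
#' @param adaptors Character vector of adaptor object ids.
#' @param bin_edges Numeric vector of 5 increasing edges (see
#'   [default_bin_edges()]); interval 4 (highest similarity) is the SC bin.
#' @param seed Integer seed controlling the candidate sampling.
#' @return A named list of `similarity_binning` objects, one per adaptor,
#'   each with `adaptor_id`, `deviants` (named SC/C/D/SD), `similarities`
#'   and `bin_edges`.
#' @export
assign_bins <- function(sim, adaptors, bin_edges = default_bin_edges(sim), seed = 1L) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (length(bin_edges) != 5L || any(diff(bin_edges) <= 0))
    stop("bin_edges must be 5 strictly increasing values")
  missing <- setdiff(adaptors, sim$object_ids)
  if (length(missing)) stop("unknown adaptor(s): ", paste(missing, collapse = ", "))
  bins_hi_to_lo <- c(SC = 4L, C = 3L, D = 2L, SD = 1L)
  with_seed(seed, {
    out <- lapply(adaptors, function(a) {
      s <- sim$values[a, ]
      s <- s[names(s) != a]
      b <- bin_of(s, bin_edges)
      deviants <- similarities <- stats::setNames(vector("list", 4L), names(bins_hi_to_lo))
      for (lab in names(bins_hi_to_lo)) {
        cand <- names(s)[!is.na(b) & b == bins_hi_to_lo[[lab]]]
        if (!length(cand))
          stop("no candidate deviant for adaptor '", a, "' in bin ", lab)
        pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
        deviants[[lab]] <- pick
        similarities[[lab]] <- unname(s[pick])
      }
      structure(list(adaptor_id = a,
                     deviants = unlist(deviants),
                     similarities = unlist(similarities),
                     bin_edges = bin_edges),
                class = "similarity_binning")
    })
    names(out) <- adaptors
    out
  })
}

#' @export
print.similarity_binning <- function(x, ...) {
  cat("Adaptor", x$adaptor_id, ":",
      paste(sprintf("%s=%s (%.3f)", names(x$deviants), x$deviants, x$similarities),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a set of similarity binnings as TSV
#' @param binnings List of `similarity_binning` objects from [assign_bins()].
#' @param path Output TSV path (columns: adaptor, bin, deviant, similarity).
#' @export
write_binnings_tsv <- function(binnings, path) {
  rows <- do.call(rbind, lapply(binnings, function(b)
    data.frame(adaptor = b$adaptor_id, bin = names(b$deviants),
               deviant = unname(b$deviants),
               similarity = unname(b$similarities))))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate feature-production norms (synthetic)
#'
#' Generates a synthetic norms table with graded between-object structure so
#' that every similarity bin is populated: objects carry a shared base
#' feature profile, a semantic-neighborhood profile (neighborhoods overlap
#' in a chain so intermediate similarities exist), and object-specific
#' features; counts are Poisson draws.
#'
#' @param n_objects Number of objects.
#' @param n_features Number of features.
#' @param n_groups Number of overlapping semantic neighborhoods.
#' @param seed Integer seed.
#' @return A `feature_norms` object.
#' @export
simulate_feature_norms <- function(n_objects = 40L, n_features = 160L,
                                   n_groups = 8L, seed = 1L) {
  stopifnot(n_objects >= 8L, n_features >= 4L * n_groups)
  with_seed(seed, {
    base <- rexp_rate(n_features, 0.15)           # shared profile
    group_block <- floor(n_features / n_groups)
    lam <- matrix(0, n_objects, n_features)
    grp <- rep_len(seq_len(n_groups), n_objects)
    for (i in seq_len(n_objects)) {
      g <- grp[i]
      prof <- base
      # own neighborhood, strongly loaded; adjacent neighborhood, weakly --
      # the chain overlap creates the mid-similarity pairs
      idx <- ((g - 1L) * group_block + 1L):(g * group_block)
      prof[idx] <- prof[idx] + rexp_rate(group_block, 1.2)
      nxt <- (g %% n_groups) * group_block + seq_len(group_block)
      prof[nxt] <- prof[nxt] + rexp_rate(group_block, 0.5)
      # object-specific idiosyncrasy
      own <- sample.int(n_features, 6L)
      prof[own] <- prof[own] + rexp_rate(6L, 2.0)
      lam[i, ] <- prof
    }
    freq <- matrix(stats::rpois(length(lam), lam * 4), n_objects, n_features)
    # guarantee no all-zero row
    zero <- rowSums(freq) == 0
    freq[zero, 1L] <- 1L
    feature_norms(sprintf("obj%02d", seq_len(n_objects)),
                  sprintf("feat%03d", seq_len(n_features)),
                  freq)
  })
}

rexp_rate <- function(n, mean) stats::rexp(n, rate = 1 / mean)

#' Select adaptors with candidates in every similarity bin
#'
#' @param sim A `similarity_matrix`.
#' @param n_adaptors Number of adaptors wanted.
#' @param bin_edges Bin edges as in [assign_bins()].
#' @param seed Seed for sampling among eligible objects.
#' @return Character vector of adaptor ids.
#' @export
pick_adaptors <- function(sim, n_adaptors = 10L,
                          bin_edges = default_bin_edges(sim), seed = 1L) {
  eligible <- Filter(function(a) {
    s <- sim$values[a, ]; s <- s[names(s) != a]
    b <- bin_of(s, bin_edges)
    all(tabulate(b[!is.na(b)], 4L) > 0L)
  }, sim$object_ids)
  if (length(eligible) < n_adaptors)
    stop("only ", length(eligible), " objects have candidates in all four bins")
  with_seed(seed, sort(sample(eligible, n_adaptors)))
}
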