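#' RT validity window
#'
#' Responses between `lower_ms` and `upper_ms` (inclusive at both bounds)
#' count as valid; anything else, including absent responses, is a miss.
#'
#' @param lower_ms,upper_ms Window bounds in milliseconds.
#' @export
rt_validity_rule <- function(lower_ms = 100, upper_ms = 800) {
  stopifnot(lower_ms < upper_ms)
  structure(list(lower_ms = lower_ms, upper_ms = upper_ms),
            class = "rt_validity_rule")
}

#' Filter valid reaction times and tabulate misses
#'
#' A trial is a miss iff there was no response or the RT falls outside the
#' validity window; the bounds themselves are valid.
#'
#' @param rt_table Data frame with `subject`, `condition`, `rt_ms`
#'   (NA = no response) and optionally `responded`.
#' @param rule An [rt_validity_rule()].
#' @return List: `valid` (the valid trials), `miss` (subject x condition
#'   matrix of miss percentages), `n_total` (matching trial-count matrix).
#' @export
filter_valid <- function(rt_table, rule = rt_validity_rule()) {
  stopifnot(all(c("subject", "condition", "rt_ms") %in% names(rt_table)))
  bad_cond <- setdiff(unique(rt_table$condition), DEVIANT_BINS)
  if (length(bad_cond))
    stop("unknown condition label(s): ", paste(bad_cond, collapse = ", "))
  responded <- if ("responded" %in% names(rt_table)) rt_table$responded else !is.na(rt_table$rt_ms)
  ok <- responded & !is.na(rt_table$rt_ms) &
    rt_table$rt_ms >= rule$lower_ms & rt_table$rt_ms <= rule$upper_ms
  subj <- sort(unique(rt_table$subject))
  miss_pct <- n_total <- matrix(0, length(subj), length(DEVIANT_BINS),
                                dimnames = list(subj, DEVIANT_BINS))
  for (i in seq_along(subj)) for (j in seq_along(DEVIANT_BINS)) {
    sel <- rt_table$subject == subj[i] & rt_table$condition == DEVIANT_BINS[j]
    n_total[i, j] <- sum(sel)
    miss_pct[i, j] <- if (n_total[i, j]) 100 * sum(sel & !ok) / sum(sel) else NA_real_
  }
  list(valid = rt_table[ok, , drop = FALSE], miss = miss_pct, n_total = n_total)
}

#' Per-subject condition means of valid RTs
#'
#' @param valid Valid-trial data frame from [filter_valid()].
#' @return Subjects x 4 (SC, C, D, SD) matrix of mean RTs. Errors if any
#'   cell is empty.
#' @export
condition_means <- function(valid) {
  subj <- sort(unique(valid$subject))
  m <- matrix(NA_real_, length(subj), 4L, dimnames = list(subj, DEVIANT_BINS))
  for (i in seq_along(subj)) for (j in seq_along(DEVIANT_BINS)) {
    x <- valid$rt_ms[valid$subject == subj[i] & valid$condition == DEVIANT_BINS[j]]
    if (!length(x)) stop("subject ", subj[i], " has no valid trials in ", DEVIANT_BINS[j])
    m[i, j] <- mean(x)
  }
  m
}

#' Within-subject one-way repeated-measures ANOVA
#'
#' Classical decomposition on a complete subjects x conditions matrix:
#' `F = MS_condition / MS_(condition x subject)` with `df1 = p - 1` and
#' `df2 = (p - 1)(n - 1)`; partial eta squared is
#' `SS_condition / (SS_condition + SS_error)`.
#'
#' @param means Subjects x conditions matrix (no missing cells).
#' @return List: `F`, `df1`, `df2`, `p`, `partial_eta_sq`.
#' @export
rm_anova_oneway <- function(means) {
  means <- as.matrix(means)
  n <- nrow(means); p <- ncol(means)
  if (n < 2L) stop("repeated-measures ANOVA needs at least 2 subjects")
  if (anyNA(means)) stop("missing cells in the condition-means matrix")
  grand <- mean(means)
  ss_cond <- n * sum((colMeans(means) - grand)^2)
  ss_subj <- p * sum((rowMeans(means) - grand)^2)
  ss_tot <- sum((means - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- p - 1L
  df2 <- (p - 1L) * (n - 1L)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  F <- if (ms_err > 0) ms_cond / ms_err else if (ms_cond > 0) Inf else 0
  pval <- stats::pf(F, df1, df2, lower.tail = FALSE)
  list(F = F, df1 = df1, df2 = df2, p = pval,
       partial_eta_sq = if (ss_cond + ss_err > 0) ss_cond / (ss_cond + ss_err) else 0)
}

#' Planned pairwise comparisons with Bonferroni correction
#'
#' Paired t-tests for every condition pair; adjusted p is `min(1, m * p)`.
#'
#' @param means Subjects x conditions matrix.
#' @param m Family size for the correction (default: the number of pairs;
#'   raised with a warning if smaller than the number of tests).
#' @param alpha Significance level applied to the adjusted p.
#' @return Data frame: `pair`, `mean_diff`, `t`, `df`, `p_raw`, `p_adj`,
#'   `significant`.
#' @export
planned_pairwise <- function(means, m = NULL, alpha = 0.05) {
  means <- as.matrix(means)
  conds <- colnames(means) %||% paste0("cond", seq_len(ncol(means)))
  pairs <- utils::combn(seq_len(ncol(means)), 2L)
  n_tests <- ncol(pairs)
  if (is.null(m)) m <- n_tests
  if (m < n_tests) {
    warning("family size m < number of tests; raising m to ", n_tests)
    m <- n_tests
  }
  res <- lapply(seq_len(n_tests), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    d <- means[, i] - means[, j]
    n <- length(d)
    sd_d <- stats::sd(d)
    t_stat <- if (sd_d > 0) mean(d) / (sd_d / sqrt(n)) else
      if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p_raw <- 2 * stats::pt(abs(t_stat), n - 1L, lower.tail = FALSE)
    data.frame(pair = paste(conds[i], conds[j], sep = "-"),
               mean_diff = mean(d), t = t_stat, df = n - 1L,
               p_raw = p_raw, p_adj = min(1, m * p_raw))
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_adj < alpha
  out
}

#' Full behavioral analysis stage
#'
#' Validity filtering, miss percentages, within-subject one-way ANOVAs on
#' RTs and miss rates, and Bonferroni-corrected planned comparisons.
#'
#' @param rt_table Trial-level RT data (see [filter_valid()]).
#' @param rule Validity window.
#' @return List with `rt_means`, `miss_pct`, `anova_rt`, `anova_miss`,
#'   `pairwise_rt`, `pairwise_miss`, `summary` (condition-level means/SEM).
#' @export
analyze_behavior <- function(rt_table, rule = rt_validity_rule()) {
  f <- filter_valid(rt_table, rule)
  rt_means <- condition_means(f$valid)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  summary <- data.frame(
    condition = DEVIANT_BINS,
    rt_mean = colMeans(rt_means), rt_sem = apply(rt_means, 2, sem),
    miss_mean = colMeans(f$miss), miss_sem = apply(f$miss, 2, sem),
    row.names = NULL)
  list(rt_means = rt_means, miss_pct = f$miss,
       anova_rt = rm_anova_oneway(rt_means),
       anova_miss = rm_anova_oneway(f$miss),
       pairwise_rt = planned_pairwise(rt_means),
       pairwise_miss = planned_pairwise(f$miss),
       summary = summary)
}
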