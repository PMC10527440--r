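# The CCHP core: within-class channel-channel correlations, channel-class
# relevance, subset merit, per-subject greedy search, and cross-subject
# occurrence ranking.

#' Within-class channel-channel correlation matrix
#'
#' For one class, the correlation between channels S and K aggregates the
#' three Hjorth parameters: the entry is
#' `(cov(A_S,A_K) + cov(M_S,M_K) + cov(C_S,C_K)) /
#'  (sd(A_S)sd(A_K) + sd(M_S)sd(M_K) + sd(C_S)sd(C_K))`
#' with covariances and standard deviations taken across the class's trials
#' (N-1 denominators). The matrix is symmetric with unit diagonal.
#'
#' @param tab a normalised `cchp_hjorth` table (see [zscore_table()]).
#' @param class_label `"stress"` or `"calm"`.
#' @return channel x channel numeric matrix.
#' @export
pair_channel_corr <- function(tab, class_label) {
  stopifnot(inherits(tab, "cchp_hjorth"))
  if (!tab$normalized)
    abort_validation("pair_channel_corr expects a z-scored table")
  idx <- tab$labels == class_label
  if (sum(idx) < 2)
    abort_validation("class '%s' has fewer than 2 trials", class_label)
  nch <- dim(tab$values)[2]
  # per-parameter trial x channel slices within the class
  sl <- lapply(1:3, function(p) matrix(tab$values[idx, , p], ncol = nch))
  covs <- lapply(sl, stats::cov)          # channel x channel, N-1
  sds <- lapply(sl, function(m) apply(m, 2, sd))
  num <- covs[[1]] + covs[[2]] + covs[[3]]
  den <- outer(sds[[1]], sds[[1]]) + outer(sds[[2]], sds[[2]]) +
    outer(sds[[3]], sds[[3]])
  bad <- which(den <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    abort_degenerate("zero denominator for channel pair (%s, %s)",
                     tab$channel_names[bad[1, 1]], tab$channel_names[bad[1, 2]])
  out <- num / den
  dimnames(out) <- list(tab$channel_names, tab$channel_names)
  (out + t(out)) / 2                      # enforce exact symmetry
}

#' Pool the stress and calm channel-channel matrices
#'
#' Elementwise mean of the two within-class matrices.
#'
#' @param p_s stress-class matrix from [pair_channel_corr()].
#' @param p_c calm-class matrix, same shape.
#' @return pooled channel x channel matrix.
#' @export
pooled_pair_corr <- function(p_s, p_c) {
  if (!all(dim(p_s) == dim(p_c)))
    abort_validation("matrix shapes differ: %s vs %s",
                     paste(dim(p_s), collapse = "x"),
                     paste(dim(p_c), collapse = "x"))
  (p_s + p_c) / 2
}

#' Channel-class relevance scores
#'
#' Default (`mode = "pointbiserial"`): for each channel and each Hjorth
#' parameter, the Pearson correlation between the parameter's value across
#' all labelled trials and the binary stress indicator; the channel score
#' is the mean of the three absolute correlations, so anti-correlated
#' channels count as relevant. `mode = "paired"` is the literal
#' sum-of-covariances reading: stress and calm trials are paired by sorted
#' rank, truncated to the smaller class, and
#' `cov(T_s, T_c) / (sd(T_s) * sd(T_c))` is averaged (absolute values) over
#' the three parameters; exposed for reproduction experiments.
#'
#' @param tab a normalised `cchp_hjorth` table.
#' @param mode `"pointbiserial"` (default) or `"paired"`.
#' @return named numeric vector of per-channel scores.
#' @export
channel_class_corr <- function(tab, mode = c("pointbiserial", "paired")) {
  stopifnot(inherits(tab, "cchp_hjorth"))
  mode <- match.arg(mode)
  if (!tab$normalized)
    abort_validation("channel_class_corr expects a z-scored table")
  ls <- sum(tab$labels == "stress"); lc <- sum(tab$labels == "calm")
  if (ls < 2 || lc < 2)
    abort_validation("each class needs >= 2 trials (stress %d, calm %d)", ls, lc)
  nch <- dim(tab$values)[2]
  y <- as.numeric(tab$labels == "stress")
  scores <- numeric(nch)
  for (ch in seq_len(nch)) {
    rs <- vapply(1:3, function(p) {
      x <- tab$values[, ch, p]
      if (sd(x) <= 0)
        abort_degenerate("zero feature variance: channel %s", tab$channel_names[ch])
      if (mode == "pointbiserial") {
        cor(x, y)
      } else {
        a <- sort(x[tab$labels == "stress"]); b <- sort(x[tab$labels == "calm"])
        m <- min(length(a), length(b))
        a <- a[seq_len(m)]; b <- b[seq_len(m)]
        sa <- sd(a); sb <- sd(b)
        if (sa <= 0 || sb <= 0)
          abort_degenerate("zero within-class variance: channel %s",
                           tab$channel_names[ch])
        stats::cov(a, b) / (sa * sb)
      }
    }, 0)
    scores[ch] <- mean(abs(rs))
  }
  names(scores) <- tab$channel_names
  scores
}

#' Subset merit score
#'
#' Scores a k-channel subset from its mean channel-class relevance `r_cf`
#' and mean absolute inter-channel (pooled) correlation `r_ff`. The default
#' `"literal"` mode is `k * r_cf / (k + k*(k+1)*k * r_ff)`; the `"cfs"`
#' mode is the classical correlation-feature-selection merit
#' `k * r_cf / sqrt(k + k*(k-1) * r_ff)`. For k = 1 there are no pairs and
#' `r_ff` is taken as 0, so both modes reduce to `r_cf`.
#'
#' @param r_cf mean channel-class score over the subset.
#' @param r_ff mean absolute pooled pair correlation over subset pairs.
#' @param k subset size, >= 1.
#' @param mode `"literal"` (default) or `"cfs"`.
#' @return the merit, a finite scalar.
#' @export
merit_score <- function(r_cf, r_ff, k, mode = c("literal", "cfs")) {
  mode <- match.arg(mode)
  if (!is.finite(r_cf) || !is.finite(r_ff) || k < 1)
    abort_validation("merit_score: non-finite inputs or k < 1")
  if (k == 1) r_ff <- 0
  out <- if (mode == "literal") k * r_cf / (k + k * (k + 1) * k * r_ff)
  else k * r_cf / sqrt(k + k * (k - 1) * r_ff)
  if (!is.finite(out)) abort_validation("merit_score: non-finite result")
  out
}

subset_merit <- function(subset_idx, class_scores, pooled, mode) {
  k <- length(subset_idx)
  r_cf <- mean(class_scores[subset_idx])
  r_ff <- if (k < 2) 0 else {
    m <- abs(pooled[subset_idx, subset_idx])
    mean(m[upper.tri(m)])
  }
  merit_score(r_cf, r_ff, k, mode)
}

#' Select one subject's significant channels
#'
#' `strategy = "bestfirst"` (default) runs a greedy forward search: start
#' from the empty set, repeatedly add the channel that maximises the merit
#' of the augmented subset, and stop as soon as no addition improves the
#' merit (patience 0). `strategy = "topk"` simply returns the `k` channels
#' with the highest channel-class scores. Both are deterministic; merit
#' ties during the search are broken by higher channel-class score, then
#' channel-name lexicographic order.
#'
#' @param tab a normalised `cchp_hjorth` table with both classes present.
#' @param strategy `"bestfirst"` or `"topk"`.
#' @param k subset size for `"topk"`.
#' @param mode channel-class mode passed to [channel_class_corr()].
#' @param merit merit mode passed to [merit_score()].
#' @return object of class `cchp_subject_selection`: list with
#'   `subject_id`, `channels` (in insertion order), `merit`,
#'   `channel_scores` (all channels' class scores).
#' @export
select_subject_channels <- function(tab, strategy = c("bestfirst", "topk"),
                                    k = NULL,
                                    mode = c("pointbiserial", "paired"),
                                    merit = c("literal", "cfs")) {
  strategy <- match.arg(strategy); mode <- match.arg(mode)
  merit <- match.arg(merit)
  scores <- channel_class_corr(tab, mode)
  nch <- length(scores)
  p_s <- pair_channel_corr(tab, "stress")
  p_c <- pair_channel_corr(tab, "calm")
  pooled <- pooled_pair_corr(p_s, p_c)

  if (strategy == "topk") {
    if (is.null(k)) abort_validation("strategy 'topk' requires k")
    k <- min(k, nch)
    ord <- order(-scores, tab$channel_names)
    sel <- ord[seq_len(k)]
  } else {
    sel <- integer(0)
    remaining <- seq_len(nch)
    best_merit <- -Inf
    repeat {
      if (length(remaining) == 0) break
      cand_merit <- vapply(remaining, function(ci)
        subset_merit(c(sel, ci), scores, pooled, merit), 0)
      # tie-break: merit, then class score, then name
      o <- order(-cand_merit, -scores[remaining],
                 tab$channel_names[remaining])[1]
      if (cand_merit[o] <= best_merit) break
      best_merit <- cand_merit[o]
      sel <- c(sel, remaining[o])
      remaining <- setdiff(remaining, remaining[o])
    }
  }
  structure(list(subject_id = tab$subject_id,
                 channels = tab$channel_names[sel],
                 merit = subset_merit(sel, scores, pooled, merit),
                 channel_scores = scores),
            class = "cchp_subject_selection")
}

#' Count channel occurrences across subjects
#'
#' @param selections list of `cchp_subject_selection` objects.
#' @return named integer vector: for every channel seen in any subject's
#'   table, the number of subjects whose significant set contains it.
#' @export
aggregate_occurrences <- function(selections) {
  if (length(selections) == 0) abort_validation("no selections to aggregate")
  all_ch <- unique(unlist(lapply(selections, function(s) names(s$channel_scores))))
  counts <- setNames(integer(length(all_ch)), all_ch)
  for (s in selections) counts[s$channels] <- counts[s$channels] + 1L
  counts
}

#' Rank occurrences and apply the commonality threshold
#'
#' Channels occurring in at least `f_thr` subjects' significant sets are
#' ranked by descending occurrence count; ties are broken by descending
#' `tie_break_scores` (mean channel-class relevance across subjects), then
#' channel name. If `n_max` is given the list is truncated to that length.
#' An empty result under the threshold is a warning, not an error.
#'
#' @param occurrence named counts from [aggregate_occurrences()].
#' @param f_thr minimum occurrence count, >= 1.
#' @param n_max optional cap on the list length.
#' @param tie_break_scores named per-channel scores used to break count
#'   ties (defaults to 0 for all channels).
#' @return character vector of channel names, best first.
#' @export
rank_and_threshold <- function(occurrence, f_thr, n_max = NULL,
                               tie_break_scores = NULL) {
  if (f_thr < 1) abort_validation("f_thr must be >= 1")
  if (is.null(tie_break_scores))
    tie_break_scores <- setNames(numeric(length(occurrence)), names(occurrence))
  tb <- tie_break_scores[names(occurrence)]
  tb[is.na(tb)] <- 0
  keep <- occurrence >= f_thr
  if (!any(keep)) {
    warning("no channel reaches the occurrence threshold f_thr = ", f_thr)
    return(character(0))
  }
  nm <- names(occurrence)[keep]
  ord <- order(-occurrence[keep], -tb[keep], nm)
  out <- nm[ord]
  if (!is.null(n_max)) out <- head(out, n_max)
  out
}

#' Cross-subject CCHP channel selection
#'
#' Runs the full selection stage: z-scores each subject's Hjorth table,
#' selects that subject's significant channels, aggregates occurrences
#' across subjects, and returns the occurrence-ranked list together with
#' the thresholded general optimal set.
#'
#' @param trialsets list of `cchp_trialset` objects (subjects lacking a
#'   class are excluded via [filter_subjects()] and reported).
#' @param f_thr occurrence threshold; default `ceiling(0.5 * n_subjects)`.
#' @param n_max cap on the general optimal set size (default 8).
#' @param strategy,k,mode,merit passed to [select_subject_channels()].
#' @param use_segments if `TRUE`, Hjorth tables are computed on fixed
#'   segments (pseudo-trials) rather than whole trials; requires
#'   `n_parts`.
#' @param n_parts segments per trial when `use_segments = TRUE`.
#' @param seed recorded in the report (the stage itself is deterministic).
#' @return object of class `cchp_selection`: list with `subjects`
#'   (per-subject id/channels/merit/scores), `occurrence`, `ranked`
#'   (full occurrence ranking at threshold 1), `g_optimal` (thresholded,
#'   capped list), `tie_break_scores`, `excluded_ids` and `params`.
#' @export
cchp_select <- function(trialsets, f_thr = NULL, n_max = 8,
                        strategy = "bestfirst", k = NULL,
                        mode = "pointbiserial", merit = "literal",
                        use_segments = FALSE, n_parts = 16, seed = NULL) {
  flt <- filter_subjects(trialsets)
  if (length(flt$retained) == 0)
    abort_validation("no subject has both stress and calm trials")
  if (is.null(f_thr)) f_thr <- ceiling(0.5 * length(flt$retained))
  sels <- lapply(flt$retained, function(ts) {
    if (use_segments) ts <- segment_trials(ts, n_parts)
    tab <- zscore_table(hjorth_table(ts))
    select_subject_channels(tab, strategy = strategy, k = k,
                            mode = mode, merit = merit)
  })
  occurrence <- aggregate_occurrences(sels)
  score_mat <- do.call(rbind, lapply(sels, function(s)
    s$channel_scores[names(occurrence)]))
  tie_break <- colMeans(score_mat)
  ranked <- rank_and_threshold(occurrence, 1, NULL, tie_break)
  g_optimal <- suppressWarnings(
    rank_and_threshold(occurrence, f_thr, n_max, tie_break))
  structure(list(
    subjects = lapply(sels, function(s)
      list(subject_id = s$subject_id, channels = s$channels,
           merit = s$merit, channel_scores = as.list(s$channel_scores))),
    occurrence = as.list(occurrence),
    ranked = ranked,
    g_optimal = g_optimal,
    tie_break_scores = as.list(tie_break),
    excluded_ids = as.character(flt$excluded_ids),
    params = list(f_thr = f_thr, n_max = n_max, strategy = strategy,
                  k = k, mode = mode, merit = merit,
                  use_segments = use_segments, n_parts = n_parts,
                  seed = seed,
                  package_version = as.character(packageVersion("cchp")))),
    class = "cchp_selection")
}

#' @export
print.cchp_selection <- function(x, ...) {
  cat(sprintf("<cchp_selection> %d subjects (%d excluded)\n",
              length(x$subjects), length(x$excluded_ids)))
  cat("  general optimal channels:", paste(x$g_optimal, collapse = ", "), "\n")
  invisible(x)
}
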