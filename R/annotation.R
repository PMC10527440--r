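# Trial labelling from valence/arousal self-ratings, subject exclusion,
# pretrial trimming and fixed-length segmentation.

#' Map valence/arousal ratings to stress/calm labels
#'
#' A trial is labelled `stress` when valence < 3 and arousal > 5, `calm`
#' when 4 < valence < 6 and arousal < 4, and `unlabeled` otherwise. The
#' boundaries are strict: ratings falling exactly on a bound (e.g. valence
#' 3, arousal 5) satisfy neither conjunction and come out `unlabeled` --
#' the gap between the two regions is intentional. Vectorised.
#'
#' @param valence numeric in `[1, 9]`.
#' @param arousal numeric in `[1, 9]`, same length.
#' @return character vector in `{"stress", "calm", "unlabeled"}`.
#' @export
label_trial <- function(valence, arousal) {
  if (length(valence) != length(arousal))
    abort_validation("valence and arousal must have equal length")
  if (any(!is.finite(valence)) || any(!is.finite(arousal)))
    abort_validation("non-finite rating")
  if (any(valence < 1 | valence > 9) || any(arousal < 1 | arousal > 9))
    abort_validation("ratings must lie in [1, 9]")
  out <- rep("unlabeled", length(valence))
  out[valence < 3 & arousal > 5] <- "stress"
  out[valence > 4 & valence < 6 & arousal < 4] <- "calm"
  out
}

#' Build a labelled trial set from a recording and its ratings
#'
#' The recording's sample axis is interpreted as that subject's trials laid
#' out back to back, one per rating row (ordered by 0-based `trial` index);
#' the column count must divide evenly. Each trial is optionally trimmed of
#' its pretrial baseline, labelled via [label_trial()], and unlabeled trials
#' are dropped.
#'
#' @param rec a [recording()].
#' @param ratings data.frame from [read_ratings()] (rows for this subject
#'   are selected by `rec$subject_id`; if no subject matches, all rows are
#'   used as-is).
#' @param pretrial_s seconds of pretrial baseline to remove from the start
#'   of every trial (default 0).
#' @return object of class `cchp_trialset`: list with `subject_id`,
#'   `trials` (list of channels x samples matrices), `labels`,
#'   `trial_index` (0-based original indices), `fs`, `channel_names`.
#' @export
annotate_trials <- function(rec, ratings, pretrial_s = 0) {
  stopifnot(inherits(rec, "cchp_recording"))
  r <- ratings[ratings$subject == rec$subject_id, , drop = FALSE]
  if (nrow(r) == 0) r <- ratings
  if (nrow(r) == 0) abort_validation("no ratings for subject %s", rec$subject_id)
  r <- r[order(r$trial), , drop = FALSE]
  n_trials <- nrow(r)
  if (ncol(rec$signal) %% n_trials != 0)
    abort_validation("sample count %d not divisible by %d trials",
                     ncol(rec$signal), n_trials)
  len <- ncol(rec$signal) / n_trials
  labels <- label_trial(r$valence, r$arousal)
  keep <- labels != "unlabeled"
  trials <- lapply(which(keep), function(i) {
    tr <- rec$signal[, ((i - 1) * len + 1):(i * len), drop = FALSE]
    trim_pretrial(tr, rec$fs, pretrial_s)
  })
  structure(list(subject_id = rec$subject_id, trials = trials,
                 labels = labels[keep], trial_index = r$trial[keep],
                 fs = rec$fs, channel_names = rec$channel_names),
            class = "cchp_trialset")
}

#' @export
print.cchp_trialset <- function(x, ...) {
  cat(sprintf("<cchp_trialset> subject %s: %d trials (%d stress, %d calm), %d channels\n",
              x$subject_id, length(x$trials), sum(x$labels == "stress"),
              sum(x$labels == "calm"), length(x$channel_names)))
  invisible(x)
}

#' Retain only subjects with both stress and calm trials
#'
#' Subjects whose labelled data contain only one of the two states cannot
#' support within-subject class contrasts and are excluded.
#'
#' @param trialsets list of `cchp_trialset` objects.
#' @return list with `retained` (trial sets) and `excluded_ids` (character).
#' @export
filter_subjects <- function(trialsets) {
  ok <- vapply(trialsets, function(ts) {
    sum(ts$labels == "stress") >= 1 && sum(ts$labels == "calm") >= 1
  }, TRUE)
  list(retained = trialsets[ok],
       excluded_ids = vapply(trialsets[!ok], `[[`, "", "subject_id"))
}

#' Remove the pretrial baseline from a trial
#'
#' Drops the first `round(pretrial_s * fs)` samples of every channel.
#'
#' @param trial channels x samples numeric matrix.
#' @param fs sampling rate in Hz.
#' @param pretrial_s pretrial duration in seconds (0 is the identity).
#' @return the trimmed matrix.
#' @export
trim_pretrial <- function(trial, fs, pretrial_s) {
  if (!is.matrix(trial)) trial <- matrix(trial, nrow = 1)
  drop_n <- round(pretrial_s * fs)
  if (drop_n < 0) abort_validation("pretrial_s must be non-negative")
  if (drop_n == 0) return(trial)
  if (ncol(trial) <= drop_n)
    abort_validation("trial (%d samples) shorter than pretrial (%d samples)",
                     ncol(trial), drop_n)
  trial[, -(seq_len(drop_n)), drop = FALSE]
}

#' Split a trial into contiguous equal-length windows
#'
#' @param trial channels x samples numeric matrix.
#' @param n_parts number of windows.
#' @param tolerant if `FALSE` (default) a sample count not divisible by
#'   `n_parts` is an error; if `TRUE` the trailing remainder is dropped
#'   with a message.
#' @return list of channels x (samples / n_parts) matrices, in time order.
#' @export
segment_trial <- function(trial, n_parts, tolerant = FALSE) {
  if (!is.matrix(trial)) trial <- matrix(trial, nrow = 1)
  if (n_parts < 1 || n_parts != round(n_parts))
    abort_validation("n_parts must be a positive integer")
  ns <- ncol(trial)
  rem <- ns %% n_parts
  if (rem != 0) {
    if (!tolerant)
      abort_validation("%d samples not divisible into %d parts", ns, n_parts)
    message(sprintf("segment_trial: dropping %d trailing samples", rem))
    ns <- ns - rem
  }
  len <- ns %/% n_parts
  if (len < 1) abort_validation("segments would be empty")
  lapply(seq_len(n_parts), function(i)
    trial[, ((i - 1) * len + 1):(i * len), drop = FALSE])
}

#' Segment every trial of a labelled trial set
#'
#' @param ts a `cchp_trialset`.
#' @param n_parts windows per trial (16 splits a 7680-sample trial into
#'   480-sample segments).
#' @param tolerant passed to [segment_trial()].
#' @return object of class `cchp_segmentset`: list with `segments` (list of
#'   matrices), `labels`, `trial_index`, `segment_index` (0-based within
#'   trial), `fs`, `channel_names`, `segment_samples`.
#' @export
segment_trials <- function(ts, n_parts, tolerant = FALSE) {
  stopifnot(inherits(ts, "cchp_trialset"))
  segs <- list(); labels <- character(); tri <- integer(); si <- integer()
  for (i in seq_along(ts$trials)) {
    parts <- segment_trial(ts$trials[[i]], n_parts, tolerant)
    segs <- c(segs, parts)
    labels <- c(labels, rep(ts$labels[i], n_parts))
    tri <- c(tri, rep(ts$trial_index[i], n_parts))
    si <- c(si, seq_len(n_parts) - 1L)
  }
  structure(list(subject_id = ts$subject_id, segments = segs, labels = labels,
                 trial_index = tri, segment_index = si, fs = ts$fs,
                 channel_names = ts$channel_names,
                 segment_samples = ncol(segs[[1]])),
            class = "cchp_segmentset")
}

#' @export
print.cchp_segmentset <- function(x, ...) {
  cat(sprintf("<cchp_segmentset> subject %s: %d segments of %d samples, %d channels\n",
              x$subject_id, length(x$segments), x$segment_samples,
              length(x$channel_names)))
  invisible(x)
}
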