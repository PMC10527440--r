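# Time-domain Hjorth parameters and the per-subject (trial, channel,
# parameter) table with feature-wise Z-score normalisation.
#
# Conventions: variances use the N-1 denominator throughout this module
# (matching the covariance convention of the selection stage); the discrete
# derivative is the first-order difference x[i] - x[i-1] without sampling-
# rate scaling -- mobility and complexity are ratios in which an fs factor
# would cancel, and activity does not involve the derivative at all.

#' Hjorth activity (signal variance)
#'
#' @param x numeric signal vector, length >= 2.
#' @return variance of `x` (N-1 denominator), >= 0.
#' @export
hjorth_activity <- function(x) {
  assert_numeric_vector(x, 2, "x")
  var(x)
}

#' Hjorth mobility (mean-frequency proxy)
#'
#' `sqrt(var(diff(x)) / var(x))`: the ratio of the standard deviation of
#' the first difference to that of the signal. For a slow sine of frequency
#' `f` sampled at `fs` this tends to `2*pi*f/fs`.
#'
#' @param x numeric signal vector, length >= 3.
#' @return mobility, >= 0.
#' @export
hjorth_mobility <- function(x) {
  assert_numeric_vector(x, 3, "x")
  v <- var(x)
  if (v <= 0) abort_degenerate("zero-variance signal: mobility undefined")
  sqrt(var(diff(x)) / v)
}

#' Hjorth complexity (bandwidth proxy)
#'
#' `mobility(diff(x)) / mobility(x)`; equals 1 in the pure-sine limit and
#' exceeds 1 for broadband signals.
#'
#' @param x numeric signal vector, length >= 4.
#' @return complexity, >= 1 for non-degenerate signals (up to estimation
#'   error).
#' @export
hjorth_complexity <- function(x) {
  assert_numeric_vector(x, 4, "x")
  m <- hjorth_mobility(x)
  if (m <= 0) abort_degenerate("zero-mobility signal: complexity undefined")
  hjorth_mobility(diff(x)) / m
}

#' All three Hjorth parameters of one signal
#'
#' @param x numeric signal vector, length >= 4.
#' @return named numeric vector `c(activity, mobility, complexity)`.
#' @export
hjorth_params <- function(x) {
  c(activity = hjorth_activity(x), mobility = hjorth_mobility(x),
    complexity = hjorth_complexity(x))
}

#' Hjorth parameter table of a labelled trial set
#'
#' Computes activity, mobility and complexity for every (trial, channel)
#' pair of a subject's labelled trials.
#'
#' @param ts a `cchp_trialset` from [annotate_trials()] (or a
#'   `cchp_segmentset` to use segments as pseudo-trials).
#' @return object of class `cchp_hjorth`: list with `values` (3-d array,
#'   trial x channel x parameter), `labels`, `channel_names`, `subject_id`,
#'   `normalized = FALSE`.
#' @export
hjorth_table <- function(ts) {
  trials <- if (inherits(ts, "cchp_segmentset")) ts$segments else ts$trials
  if (length(trials) == 0) abort_validation("empty trial set")
  nch <- length(ts$channel_names)
  vals <- array(NA_real_, dim = c(length(trials), nch, 3),
                dimnames = list(NULL, ts$channel_names,
                                c("activity", "mobility", "complexity")))
  # Single-pass equivalent of the scalar operations: with v0 = var(x),
  # v1 = var(diff(x)), v2 = var(diff(diff(x))), activity = v0, mobility =
  # sqrt(v1/v0), complexity = sqrt(v2/v1)/sqrt(v1/v0). Tested against the
  # scalar functions elementwise.
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    for (ch in seq_len(nch)) {
      x <- tr[ch, ]
      if (length(x) < 4 || anyNA(x) || any(!is.finite(x)))
        abort_validation("invalid signal at trial %d, channel %s",
                         i, ts$channel_names[ch])
      d1 <- diff(x); d2 <- diff(d1)
      v0 <- var(x); v1 <- var(d1); v2 <- var(d2)
      if (v0 <= 0 || v1 <= 0)
        abort_degenerate("degenerate signal at trial %d, channel %s",
                         i, ts$channel_names[ch])
      mob <- sqrt(v1 / v0)
      vals[i, ch, ] <- c(v0, mob, sqrt(v2 / v1) / mob)
    }
  }
  structure(list(values = vals, labels = ts$labels,
                 channel_names = ts$channel_names,
                 subject_id = ts$subject_id, normalized = FALSE),
            class = "cchp_hjorth")
}

#' @export
print.cchp_hjorth <- function(x, ...) {
  cat(sprintf("<cchp_hjorth> subject %s: %d trials x %d channels x 3 parameters%s\n",
              x$subject_id, dim(x$values)[1], dim(x$values)[2],
              if (x$normalized) " (z-scored)" else ""))
  invisible(x)
}

#' Feature-wise Z-score normalisation of a Hjorth table
#'
#' Each (channel, parameter) column is centred to mean 0 and scaled to
#' standard deviation 1 (N-1 convention) across the subject's trials, both
#' classes pooled. Applied once, before all correlation computations.
#'
#' @param tab a `cchp_hjorth` table.
#' @param per_class if `TRUE`, normalise within each class separately
#'   (sensitivity-analysis variant; default `FALSE`).
#' @return the table with `normalized = TRUE`.
#' @export
zscore_table <- function(tab, per_class = FALSE) {
  stopifnot(inherits(tab, "cchp_hjorth"))
  v <- tab$values
  if (dim(v)[1] < 2) abort_validation("z-scoring needs >= 2 trials")
  zs <- function(idx) {
    for (ch in seq_len(dim(v)[2])) for (p in 1:3) {
      col <- v[idx, ch, p]
      s <- sd(col)
      if (!is.finite(s) || s <= 0)
        abort_degenerate("constant feature across trials: channel %s, %s",
                         tab$channel_names[ch], dimnames(v)[[3]][p])
      v[idx, ch, p] <<- (col - mean(col)) / s
    }
  }
  if (per_class) for (cl in unique(tab$labels)) zs(tab$labels == cl)
  else zs(seq_len(dim(v)[1]))
  tab$values <- v
  tab$normalized <- TRUE
  tab
}
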