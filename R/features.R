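# The 20-dimensional multi-domain feature vector extracted per channel per
# fixed-length segment: 7 time-domain features (line length, peak-to-peak,
# kurtosis, skewness, three Hjorth parameters), 5 relative band powers,
# 6 wavelet band energies, spectral entropy and Katz fractal dimension.
#
# Moment features use population (1/T) normalisation, matching their
# printed definitions, unlike the N-1 convention of the Hjorth/selection
# stage; the discrepancy between the two conventions is deliberate and
# preserved per formula.

#' Line length (curve length)
#'
#' Total vertical excursion: `sum(|x[i] - x[i-1]|)`.
#'
#' @param x numeric signal vector, length >= 2.
#' @return line length, >= 0.
#' @export
line_length <- function(x) {
  assert_numeric_vector(x, 2, "x")
  sum(abs(diff(x)))
}

#' Peak-to-peak amplitude
#'
#' @param x non-empty numeric signal vector.
#' @return `max(x) - min(x)`.
#' @export
peak_to_peak <- function(x) {
  assert_numeric_vector(x, 1, "x")
  max(x) - min(x)
}

#' Kurtosis (standardised fourth moment, population convention)
#'
#' `mean((x - mu)^4) / sigma^4` with population moments; a large Gaussian
#' sample gives ~3 (no excess-kurtosis shift).
#'
#' @param x numeric signal vector with positive variance.
#' @return kurtosis.
#' @export
signal_kurtosis <- function(x) {
  assert_numeric_vector(x, 2, "x")
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 <= 0) abort_degenerate("zero-variance signal: kurtosis undefined")
  mean((x - m)^4) / s2^2
}

#' Skewness (standardised third moment, population convention)
#'
#' @param x numeric signal vector with positive variance.
#' @return skewness; 0 for symmetric signals.
#' @export
signal_skewness <- function(x) {
  assert_numeric_vector(x, 2, "x")
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 <= 0) abort_degenerate("zero-variance signal: skewness undefined")
  mean((x - m)^3) / s2^1.5
}

# The five classical bands of the 4-45 Hz preprocessed EEG, in Hz.
CCHP_BANDS <- list(theta = c(4, 8), low_alpha = c(8, 12),
                   high_alpha = c(12, 15), low_beta = c(15, 20),
                   high_beta = c(20, 30))

#' Relative band powers (theta to high beta)
#'
#' Welch band power in each of theta (4-8 Hz), low alpha (8-12), high
#' alpha (12-15), low beta (15-20) and high beta (20-30), each expressed
#' as a percentage of the total 4-45 Hz power (the full band of the
#' preprocessed data). Band edges are half-open `[lo, hi)` so adjacent
#' bands share no bin; the 4-45 Hz denominator is closed.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate in Hz (> 90, so 45 Hz content exists).
#' @param nperseg Welch window length (default 128).
#' @return named numeric vector of 5 percentages in `[0, 100]`.
#' @export
relative_band_powers <- function(x, fs, nperseg = 128) {
  if (fs <= 2 * 45)
    abort_validation("fs = %g cannot represent the 45 Hz band edge", fs)
  p <- welch_psd(x, fs, nperseg)
  total <- band_power(p$freq, p$psd, 4, 45, include_hi = TRUE)
  if (total <= 0) abort_degenerate("no power in the 4-45 Hz band")
  out <- vapply(CCHP_BANDS, function(b)
    100 * band_power(p$freq, p$psd, b[1], b[2]) / total, 0)
  setNames(out, paste0("relpow_", names(CCHP_BANDS)))
}

#' Spectral entropy of the Welch PSD over 4-45 Hz
#'
#' The PSD restricted to 4-45 Hz is normalised to sum 1 and its Shannon
#' entropy is returned (natural log by default, so the value lies in
#' `[0, ln(n_bins)]`; `base = 2` is offered for comparability with other
#' toolkits).
#'
#' @param x numeric signal vector.
#' @param fs sampling rate in Hz.
#' @param nperseg Welch window length (default 128).
#' @param base logarithm base (default `exp(1)`).
#' @return spectral entropy, >= 0.
#' @export
spectral_entropy <- function(x, fs, nperseg = 128, base = exp(1)) {
  p <- welch_psd(x, fs, nperseg)
  sel <- p$freq >= 4 & p$freq <= 45
  psd <- p$psd[sel]
  tot <- sum(psd)
  if (tot <= 0) abort_degenerate("all-zero PSD in the 4-45 Hz band")
  pr <- psd / tot
  pr <- pr[pr > 0]
  -sum(pr * log(pr, base = base))
}

#' Katz fractal dimension
#'
#' `D = log10(n) / (log10(d/L) + log10(n))` with `L` the line length, `n =
#' N - 1` the step count (line length over mean step), and `d` the maximal
#' absolute excursion from the first sample. A straight monotone ramp
#' gives 1; irregular waveforms exceed 1. Scale-invariant.
#'
#' @param x numeric signal vector, length >= 2, with positive line length.
#' @return Katz dimension, >= 1 up to floating point.
#' @export
katz_fd <- function(x) {
  assert_numeric_vector(x, 2, "x")
  L <- sum(abs(diff(x)))
  if (L <= 0) abort_degenerate("zero-length curve: Katz dimension undefined")
  d <- max(abs(x - x[1]))
  n <- length(x) - 1
  log10(n) / (log10(d / L) + log10(n))
}

cchp_feature_names <- function() {
  c("line_length", "ptp", "kurtosis", "skewness",
    "hjorth_activity", "hjorth_mobility", "hjorth_complexity",
    paste0("relpow_", names(CCHP_BANDS)),
    paste0("wavelet_e", 1:6),
    "spectral_entropy", "katz_fd")
}

segment_features <- function(x, fs, nperseg, wavelet_set, entropy_base) {
  hj <- hjorth_params(x)
  c(line_length = line_length(x),
    ptp = peak_to_peak(x),
    kurtosis = signal_kurtosis(x),
    skewness = signal_skewness(x),
    hjorth_activity = unname(hj["activity"]),
    hjorth_mobility = unname(hj["mobility"]),
    hjorth_complexity = unname(hj["complexity"]),
    relative_band_powers(x, fs, nperseg),
    wavelet_energies(x, 6, wavelet_set),
    spectral_entropy = spectral_entropy(x, fs, nperseg, entropy_base),
    katz_fd = katz_fd(x))
}

#' Extract the 20-feature table from a segment set
#'
#' One row per (segment, channel), restricted to `channels`; exactly 20
#' feature columns plus identifiers (`subject`, `trial`, `segment`,
#' `channel`) and the segment `label`.
#'
#' @param segs a `cchp_segmentset` from [segment_trials()].
#' @param channels channel-name subset (default: all channels).
#' @param nperseg Welch window length (default 128).
#' @param wavelet_set wavelet energy set, see [wavelet_energies()].
#' @param entropy_base spectral-entropy log base (default natural).
#' @return data.frame of class `cchp_features`.
#' @export
extract_features <- function(segs, channels = NULL, nperseg = 128,
                             wavelet_set = "d1_d6", entropy_base = exp(1)) {
  stopifnot(inherits(segs, "cchp_segmentset"))
  if (is.null(channels)) channels <- segs$channel_names
  unknown <- setdiff(channels, segs$channel_names)
  if (length(unknown))
    abort_validation("unknown channel(s): %s", paste(unknown, collapse = ", "))
  ch_idx <- match(channels, segs$channel_names)
  nseg <- length(segs$segments)
  nfeat <- length(cchp_feature_names())
  rows <- matrix(NA_real_, nseg * length(channels), nfeat)
  subject <- character(nrow(rows)); trial <- integer(nrow(rows))
  segment <- integer(nrow(rows)); channel <- character(nrow(rows))
  label <- character(nrow(rows))
  r <- 0L
  for (i in seq_len(nseg)) {
    for (j in seq_along(ch_idx)) {
      r <- r + 1L
      rows[r, ] <- segment_features(segs$segments[[i]][ch_idx[j], ], segs$fs,
                                    nperseg, wavelet_set, entropy_base)
      subject[r] <- segs$subject_id; trial[r] <- segs$trial_index[i]
      segment[r] <- segs$segment_index[i]; channel[r] <- channels[j]
      label[r] <- segs$labels[i]
    }
  }
  colnames(rows) <- cchp_feature_names()
  out <- data.frame(subject = subject, trial = trial, segment = segment,
                    channel = channel, label = label, rows,
                    stringsAsFactors = FALSE)
  class(out) <- c("cchp_features", "data.frame")
  out
}

#' Feature column names of a feature table
#'
#' @param ft a `cchp_features` data.frame.
#' @return character vector of the 20 feature column names.
#' @export
feature_columns <- function(ft) {
  intersect(cchp_feature_names(), names(ft))
}
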