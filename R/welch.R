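# Welch power spectral density on stats::fft. Defaults: 128-sample Hamming
# windows with 50% overlap, one-sided density normalisation, so at
# fs = 128 Hz the grid has 1 Hz resolution -- enough to resolve the 4 Hz
# lower band edge of the preprocessed EEG.

#' Welch power spectral density estimate
#'
#' Splits the signal into `nperseg`-sample windows overlapping by
#' `noverlap` samples, applies a Hamming taper to each, and averages the
#' one-sided modified periodograms. Density scaling: the integral of the
#' PSD over frequency approximates the signal power.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate in Hz.
#' @param nperseg window length in samples (default 128, capped at
#'   `length(x)`).
#' @param noverlap overlap in samples (default `nperseg / 2`).
#' @return list with `freq` (Hz, from 0 to fs/2) and `psd`.
#' @export
welch_psd <- function(x, fs, nperseg = 128, noverlap = NULL) {
  assert_numeric_vector(x, 2, "x")
  if (nperseg > length(x))
    abort_validation("segment of %d samples is shorter than the %d-sample window",
                     length(x), nperseg)
  if (is.null(noverlap)) noverlap <- nperseg %/% 2
  step <- nperseg - noverlap
  if (step < 1) abort_validation("noverlap must be smaller than nperseg")
  starts <- seq(1, length(x) - nperseg + 1, by = step)
  n <- nperseg
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))   # Hamming
  scale <- 1 / (fs * sum(w^2))
  nfreq <- n %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + n - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(fft(seg))[seq_len(nfreq)]^2 * scale
    # one-sided: double everything except DC and (for even n) Nyquist
    sp[2:(nfreq - 1)] <- 2 * sp[2:(nfreq - 1)]
    if (n %% 2 == 1) sp[nfreq] <- 2 * sp[nfreq]
    acc <- acc + sp
  }
  list(freq = (seq_len(nfreq) - 1) * fs / n, psd = acc / length(starts))
}

band_power <- function(freq, psd, lo, hi, include_hi = FALSE) {
  sel <- if (include_hi) freq >= lo & freq <= hi else freq >= lo & freq < hi
  df <- if (length(freq) > 1) freq[2] - freq[1] else 1
  sum(psd[sel]) * df
}
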