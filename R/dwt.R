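# Discrete wavelet transform, Daubechies-4 (8-tap, 4 vanishing moments),
# periodized. Periodization keeps the transform orthogonal -- every
# even-length analysis step is a rotation, so coefficient energies add up
# to the signal energy exactly (Parseval). When a level's input has odd
# length it is extended by duplicating its last sample (the usual
# periodization convention), which is the one place exactness is lost;
# dyadic lengths never hit it.

# db4 scaling (reconstruction lowpass) filter; sums to sqrt(2).
DB4_H <- c(0.230377813308855230, 0.714846570552541500,
           0.630880767929590400, -0.027983769416983850,
           -0.187034811718881140, 0.030841381835986965,
           0.032883011666982945, -0.010597401784997278)

dwt_step_db4 <- function(x) {
  n <- length(x)
  if (n %% 2 == 1) { x <- c(x, x[n]); n <- n + 1 }
  L <- rev(DB4_H)                       # analysis lowpass
  H <- DB4_H * c(1, -1, 1, -1, 1, -1, 1, -1)  # analysis highpass (QMF)
  half <- n / 2
  idx <- (outer(2 * (seq_len(half) - 1), 0:7, `+`) %% n) + 1
  xm <- matrix(x[idx], nrow = half)
  list(approx = as.numeric(xm %*% L), detail = as.numeric(xm %*% H))
}

#' Multi-level periodized db4 wavelet decomposition
#'
#' @param x numeric signal vector.
#' @param levels number of decomposition levels (default 6).
#' @return list with `details` (list of detail-coefficient vectors,
#'   finest D1 first) and `approx` (the final approximation coefficients).
#' @export
dwt_db4 <- function(x, levels = 6) {
  assert_numeric_vector(x, 2, "x")
  if (length(x) < 2^levels)
    abort_validation("signal of %d samples is too short for %d levels",
                     length(x), levels)
  details <- vector("list", levels)
  a <- x
  for (lev in seq_len(levels)) {
    st <- dwt_step_db4(a)
    details[[lev]] <- st$detail
    a <- st$approx
  }
  list(details = details, approx = a)
}

#' Wavelet band energies (db4, 6 levels)
#'
#' Energies are squared-coefficient sums per decomposition level. The
#' default set is the six detail levels D1 (finest) to D6; at 128 Hz the
#' excluded approximation band lies below 1 Hz, which the 4-45 Hz
#' preprocessing already removed. `set = "d2_a6"` swaps D1 for the
#' approximation energy instead.
#'
#' @param x numeric signal vector (>= 64 samples for 6 levels).
#' @param levels decomposition depth (default 6).
#' @param set `"d1_d6"` (default) or `"d2_a6"`.
#' @return named numeric vector of `levels` energies, all >= 0.
#' @export
wavelet_energies <- function(x, levels = 6, set = c("d1_d6", "d2_a6")) {
  set <- match.arg(set)
  dec <- dwt_db4(x, levels)
  e_det <- vapply(dec$details, function(d) sum(d^2), 0)
  if (set == "d1_d6") {
    setNames(e_det, paste0("wavelet_e", seq_len(levels)))
  } else {
    setNames(c(e_det[-1], sum(dec$approx^2)),
             paste0("wavelet_e", seq_len(levels)))
  }
}
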