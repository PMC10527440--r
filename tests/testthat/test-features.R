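# Time, frequency and time-frequency features, and the feature-table
# contract.

test_that("time-domain features match hand values and loop oracles", {
  expect_equal(line_length(rep(2, 10)), 0)
  expect_equal(line_length(c(0, 1, 0, 1)), 3)
  expect_equal(peak_to_peak(c(0, 1, 0, 1)), 1)
  expect_equal(peak_to_peak(rep(5, 4)), 0)
  expect_equal(signal_skewness(c(-1, 1, -1, 1)), 0)
  expect_equal(signal_kurtosis(c(-1, 1, -1, 1)), 1)   # all |z| = 1

  set.seed(33)
  for (i in 1:20) {
    x <- rnorm(100) * 3 + cumsum(rnorm(100))
    expect_equal(line_length(x), oracle_line_length(x), tolerance = 1e-10)
    expect_equal(signal_kurtosis(x), oracle_kurtosis(x), tolerance = 1e-10)
    expect_equal(signal_skewness(x), oracle_skewness(x), tolerance = 1e-10)
    expect_equal(katz_fd(x), oracle_katz(x), tolerance = 1e-10)
    c_ <- 2.5
    expect_equal(line_length(c_ * x), c_ * line_length(x))
    expect_equal(peak_to_peak(x + 7), peak_to_peak(x))
    expect_equal(katz_fd(c_ * x), katz_fd(x), tolerance = 1e-12)
  }
})

test_that("kurtosis of a large Gaussian sample is near 3 (population moments)", {
  set.seed(44)
  x <- rnorm(1e5)
  expect_equal(signal_kurtosis(x), 3, tolerance = 0.05)
  expect_error(signal_kurtosis(rep(1, 5)), class = "cchp_degenerate_error")
})

test_that("relative band powers concentrate on the tone's band", {
  fs <- 128; t <- (0:479) / fs
  x <- sin(2 * pi * 10 * t)
  rp <- relative_band_powers(x, fs)
  expect_length(rp, 5)
  expect_gte(rp[["relpow_low_alpha"]], 95)
  expect_lte(sum(rp[setdiff(names(rp), "relpow_low_alpha")]), 5)

  rp6 <- relative_band_powers(sin(2 * pi * 6 * t), fs)
  expect_gte(rp6[["relpow_theta"]], 95)

  expect_true(all(rp >= 0 & rp <= 100))
  expect_lte(sum(rp), 100 + 1e-9)
  expect_error(relative_band_powers(x, fs = 64),
               class = "cchp_validation_error")
})

test_that("white-noise band powers scale with bandwidth", {
  # flat spectrum: expected share of band [lo, hi) of the 4-45 total is
  # (hi - lo) / 41; average over segments to tame Monte-Carlo error
  set.seed(55)
  acc <- rep(0, 5)
  n_rep <- 40
  for (i in seq_len(n_rep))
    acc <- acc + relative_band_powers(rnorm(480), 128)
  avg <- acc / n_rep
  expected <- 100 * c(4, 4, 3, 5, 10) / 41
  expect_equal(unname(avg), expected, tolerance = 0.12)
})

test_that("db4 energies: zeros, Parseval at dyadic length, D1 localisation", {
  expect_equal(unname(wavelet_energies(rep(0, 512))), rep(0, 6))

  set.seed(66)
  for (n in c(256, 512)) {
    x <- rnorm(n)
    dec <- dwt_db4(x, 6)
    e <- sum(vapply(dec$details, function(d) sum(d^2), 0)) + sum(dec$approx^2)
    expect_equal(e, sum(x^2), tolerance = 1e-8)
  }

  # alternating +-1 is the highest-frequency signal: energy lands in D1
  x <- rep(c(1, -1), 256)
  e <- wavelet_energies(x)
  expect_gt(e[["wavelet_e1"]] / sum(e), 0.98)

  # analysis step agrees with an explicit circular-convolution loop
  lo <- rev(cchp:::DB4_H)
  hi <- cchp:::DB4_H * rep(c(1, -1), 4)
  set.seed(67)
  x <- rnorm(64)
  st <- cchp:::dwt_step_db4(x)
  or <- oracle_dwt_step(x, lo, hi)
  expect_equal(st$approx, or$approx, tolerance = 1e-12)
  expect_equal(st$detail, or$detail, tolerance = 1e-12)

  expect_error(dwt_db4(rnorm(16), 6), class = "cchp_validation_error")
})

test_that("spectral entropy separates tones from noise and ignores amplitude", {
  fs <- 128; t <- (0:479) / fs
  nbins <- sum((0:64) >= 4 & (0:64) <= 45)
  tone <- spectral_entropy(sin(2 * pi * 10 * t), fs)
  # an on-bin tone under a Hamming taper spreads over ~3 bins with weights
  # (0.54, 0.23, 0.23)^2, whose entropy is ~0.76 nats: far below noise
  expect_lt(tone, 0.25 * log(nbins))
  set.seed(77)
  noise <- spectral_entropy(rnorm(480), fs)
  expect_gt(noise, 0.9 * log(nbins))
  x <- rnorm(480)
  expect_equal(spectral_entropy(17 * x, fs), spectral_entropy(x, fs),
               tolerance = 1e-12)
  # base-2 option rescales by log(2)
  expect_equal(spectral_entropy(x, fs, base = 2),
               spectral_entropy(x, fs) / log(2), tolerance = 1e-12)
})

test_that("Katz dimension: ramp gives 1, noise exceeds 1", {
  expect_equal(katz_fd(seq(0, 1, length.out = 100)), 1, tolerance = 1e-12)
  set.seed(88)
  expect_gt(katz_fd(rnorm(200)), 1)
  expect_error(katz_fd(rep(1, 10)), class = "cchp_degenerate_error")
})

test_that("extract_features emits exactly 20 columns and carries labels", {
  ts <- random_trialset(n_trials = 4, n_channels = 3, n_samples = 960,
                        seed = 10)
  segs <- segment_trials(ts, 2)      # 8 segments of 480
  ft <- extract_features(segs, channels = c("C1", "C3"))
  expect_equal(nrow(ft), 8 * 2)
  expect_length(feature_columns(ft), 20)
  expect_false(anyNA(ft))
  expect_equal(unique(ft$channel), c("C1", "C3"))
  expect_equal(unique(ft$label), c("stress", "calm"))

  # restriction to one channel halves the rows
  expect_equal(nrow(extract_features(segs, channels = "C2")), 8)
  expect_error(extract_features(segs, channels = "Oz"),
               class = "cchp_validation_error")

  # the Hjorth columns are the hjorth module's scalar ops on the segment
  x <- segs$segments[[1]][1, ]
  expect_equal(ft$hjorth_activity[1], hjorth_activity(x))
  expect_equal(ft$hjorth_mobility[1], hjorth_mobility(x))
  expect_equal(ft$hjorth_complexity[1], hjorth_complexity(x))
  expect_equal(ft$katz_fd[1], katz_fd(x))
})
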