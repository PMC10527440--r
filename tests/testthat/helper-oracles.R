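# Independent brute-force oracles: explicit loops over the definitions,
# kept deliberately separate from the package implementations.

oracle_mean <- function(x) sum(x) / length(x)

oracle_var <- function(x) {
  m <- oracle_mean(x)
  s <- 0
  for (xi in x) s <- s + (xi - m)^2
  s / (length(x) - 1)
}

oracle_cov <- function(x, y) {
  mx <- oracle_mean(x); my <- oracle_mean(y)
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - mx) * (y[i] - my)
  s / (length(x) - 1)
}

oracle_diff <- function(x) {
  out <- numeric(length(x) - 1)
  for (i in 2:length(x)) out[i - 1] <- x[i] - x[i - 1]
  out
}

oracle_activity <- function(x) oracle_var(x)
oracle_mobility <- function(x) sqrt(oracle_var(oracle_diff(x)) / oracle_var(x))
oracle_complexity <- function(x)
  oracle_mobility(oracle_diff(x)) / oracle_mobility(x)

# Eq.-style channel-channel entry: sum of the three covariances over the sum
# of the three sd products, across the class's trials.
oracle_pair_entry <- function(vals, labels, class_label, s, k) {
  idx <- which(labels == class_label)
  num <- 0; den <- 0
  for (p in 1:3) {
    a <- vals[idx, s, p]; b <- vals[idx, k, p]
    num <- num + oracle_cov(a, b)
    den <- den + sqrt(oracle_var(a)) * sqrt(oracle_var(b))
  }
  num / den
}

oracle_line_length <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + abs(x[i] - x[i - 1])
  s
}

oracle_kurtosis <- function(x) {
  m <- oracle_mean(x)
  s2 <- oracle_mean((x - m)^2)
  oracle_mean((x - m)^4) / s2^2
}

oracle_skewness <- function(x) {
  m <- oracle_mean(x)
  s2 <- oracle_mean((x - m)^2)
  oracle_mean((x - m)^3) / s2^1.5
}

oracle_katz <- function(x) {
  L <- oracle_line_length(x)
  d <- 0
  for (xi in x) d <- max(d, abs(xi - x[1]))
  n <- length(x) - 1
  log10(n) / (log10(d / L) + log10(n))
}

# Brute-force single DWT analysis step: explicit circular convolution.
oracle_dwt_step <- function(x, lo, hi) {
  n <- length(x)
  a <- numeric(n / 2); d <- numeric(n / 2)
  for (k in seq_len(n / 2)) {
    for (m in seq_along(lo)) {
      j <- (2 * (k - 1) + m - 1) %% n + 1
      a[k] <- a[k] + lo[m] * x[j]
      d[k] <- d[k] + hi[m] * x[j]
    }
  }
  list(approx = a, detail = d)
}

# --- fixture builders ---------------------------------------------------

# A trial set built directly from a (trial x channel x 3) Hjorth value
# array is sometimes more convenient than raw signals.
make_hjorth_tab <- function(vals, labels, channel_names = NULL,
                            subject_id = "sX", normalized = FALSE) {
  if (is.null(channel_names))
    channel_names <- paste0("C", seq_len(dim(vals)[2]))
  dimnames(vals) <- list(NULL, channel_names,
                         c("activity", "mobility", "complexity"))
  structure(list(values = vals, labels = labels,
                 channel_names = channel_names, subject_id = subject_id,
                 normalized = normalized),
            class = "cchp_hjorth")
}

make_trialset <- function(trials, labels, fs = 128, channel_names = NULL,
                          subject_id = "sX") {
  if (is.null(channel_names))
    channel_names <- paste0("C", seq_len(nrow(trials[[1]])))
  structure(list(subject_id = subject_id, trials = trials, labels = labels,
                 trial_index = seq_along(trials) - 1L, fs = fs,
                 channel_names = channel_names),
            class = "cchp_trialset")
}

# Random trial set: white-noise channels, optionally with an activity
# boost on planted channels in stress trials.
random_trialset <- function(n_trials = 8, n_channels = 3, n_samples = 256,
                            fs = 128, planted = integer(0), boost = 0,
                            seed = 1, subject_id = "sX") {
  set.seed(seed)
  labels <- rep(c("stress", "calm"), length.out = n_trials)
  trials <- lapply(seq_len(n_trials), function(t) {
    sig <- matrix(rnorm(n_channels * n_samples), n_channels, n_samples)
    if (boost > 0 && labels[t] == "stress")
      sig[planted, ] <- sig[planted, , drop = FALSE] * (1 + boost)
    sig
  })
  make_trialset(trials, labels, fs = fs, subject_id = subject_id)
}

# A synthetic per-segment feature table with Gaussian class separation
# `delta` on every feature of the given channels (0 = pure noise).
blob_features <- function(n_per_class = 100, channels = "C1", delta = 0,
                          subject = "s01", seed = 1) {
  set.seed(seed)
  fcols <- cchp:::cchp_feature_names()
  rows <- list()
  n <- 2 * n_per_class
  labels <- rep(c("stress", "calm"), each = n_per_class)
  for (ch in channels) {
    mu <- ifelse(labels == "stress", delta, 0)
    m <- matrix(rnorm(n * length(fcols)) + mu, n, length(fcols))
    colnames(m) <- fcols
    rows[[ch]] <- data.frame(subject = subject,
                             trial = seq_len(n) - 1L, segment = 0L,
                             channel = ch, label = labels, m,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cchp_features", "data.frame")
  out
}
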