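# Synthetic EEG with planted class-sensitive channels. Backgrounds are
# synthesised in the frequency domain: complex-Gaussian bins under a 1/f
# amplitude envelope restricted to 4-45 Hz (matching the band of the
# preprocessed study data), inverse-transformed and scaled to unit
# standard deviation in expectation. Stress-labelled trials perturb the
# planted channels only; all other channels are statistically identical
# across classes.

# Standard 10-20/10-10 montage names of a 32-channel cap, in cap order.
MONTAGE_32 <- c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
                "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
                "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "Cz",
                "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2")

#' Simulation specification
#'
#' Defaults emulate the study conditions: 128 Hz sampling, 60 s trials, 40
#' trials per subject with balanced stress/calm labels, 1/f-weighted
#' 4-45 Hz background noise, and a small planted channel subset whose
#' signal differs between classes by `effect` standard-deviation units.
#'
#' @param n_subjects number of subjects (default 10).
#' @param n_channels channels per subject (default 32).
#' @param channel_names channel names (default: first `n_channels` of the
#'   standard 32-electrode montage).
#' @param fs sampling rate in Hz (default 128; must exceed 90 so 45 Hz
#'   content exists).
#' @param trial_s trial duration in seconds (default 60).
#' @param n_trials trials per subject (default 40).
#' @param stress_fraction fraction of stress trials (default 0.5).
#' @param planted_channels channels carrying the class effect (default:
#'   first 3 channel names).
#' @param effect dimensionless effect size in across-trial
#'   standard-deviation units (default 2; 0 gives a pure null).
#' @param effect_kind `"bandpower_shift"` (adds a 15-30 Hz narrowband
#'   component to stress trials), `"mobility_shift"` (tilts the spectrum
#'   upward so mobility rises by ~`effect` across-trial sd), or
#'   `"mixed"` (both).
#' @param mixing shared-background mixing coefficient in `[0, 1)` added
#'   across channels to emulate volume conduction (default 0).
#' @param seed master seed (default 1).
#' @return object of class `cchp_simspec`.
#' @export
sim_spec <- function(n_subjects = 10, n_channels = 32, channel_names = NULL,
                     fs = 128, trial_s = 60, n_trials = 40,
                     stress_fraction = 0.5, planted_channels = NULL,
                     effect = 2,
                     effect_kind = c("bandpower_shift", "mobility_shift",
                                     "mixed"),
                     mixing = 0, seed = 1) {
  effect_kind <- match.arg(effect_kind)
  if (is.null(channel_names)) {
    if (n_channels > length(MONTAGE_32))
      channel_names <- c(MONTAGE_32,
                         paste0("X", seq_len(n_channels - length(MONTAGE_32))))
    else channel_names <- MONTAGE_32[seq_len(n_channels)]
  }
  if (length(channel_names) != n_channels || anyDuplicated(channel_names))
    abort_validation("channel_names must be %d unique names", n_channels)
  if (is.null(planted_channels))
    planted_channels <- channel_names[seq_len(min(3, n_channels))]
  if (!all(planted_channels %in% channel_names))
    abort_validation("planted_channels must be a subset of channel_names")
  if (stress_fraction <= 0 || stress_fraction >= 1)
    abort_validation("stress_fraction must lie strictly in (0, 1)")
  if (fs <= 90) abort_validation("fs must exceed 90 Hz (45 Hz band edge)")
  if (effect < 0) abort_validation("effect must be >= 0")
  if (mixing < 0 || mixing >= 1) abort_validation("mixing must be in [0, 1)")
  structure(list(n_subjects = n_subjects, n_channels = n_channels,
                 channel_names = channel_names, fs = fs, trial_s = trial_s,
                 n_trials = n_trials, stress_fraction = stress_fraction,
                 planted_channels = planted_channels, effect = effect,
                 effect_kind = effect_kind, mixing = mixing, seed = seed),
            class = "cchp_simspec")
}

# Amplitude envelope over positive FFT bins: slope-tilted 1/f inside
# [lo, hi] Hz, zero elsewhere, scaled so the synthesised signal has unit
# variance in expectation.
sim_envelope <- function(n, fs, lo = 4, hi = 45, tilt = 0) {
  k <- seq_len(floor((n - 1) / 2))
  f <- k * fs / n
  a <- ifelse(f >= lo & f <= hi, (1 / f) * (f / lo)^tilt, 0)
  s2 <- 2 * sum(a^2) / n^2
  a / sqrt(s2)
}

# Realisations from envelopes: complex-Gaussian bins, inverse FFT. The
# matrix form synthesises one column per channel in a single mvfft call.
sim_draw_multi <- function(env_mat, n) {
  nb <- nrow(env_mat); nc <- ncol(env_mat)
  k <- seq_len(nb)
  w <- matrix(complex(real = rnorm(nb * nc), imaginary = rnorm(nb * nc)),
              nb, nc) / sqrt(2)
  spec <- matrix(complex(real = 0), n, nc)
  spec[k + 1, ] <- env_mat * w
  spec[n + 1 - k, ] <- Conj(spec[k + 1, ])
  Re(stats::mvfft(spec, inverse = TRUE)) / n
}

sim_draw <- function(env, n) {
  as.numeric(sim_draw_multi(matrix(env, ncol = 1), n))
}

# Expected discrete mobility implied by an envelope (first-difference
# transfer |1 - e^{-i 2 pi k / n}|^2 = 4 sin^2(pi k / n)).
env_mobility <- function(env, n) {
  k <- seq_along(env)
  w <- 4 * sin(pi * k / n)^2
  sqrt(sum(env^2 * w) / sum(env^2))
}

# Find the envelope tilt that raises expected mobility by delta.
calibrate_tilt <- function(n, fs, delta) {
  target <- env_mobility(sim_envelope(n, fs), n) + delta
  f <- function(t) env_mobility(sim_envelope(n, fs, tilt = t), n) - target
  if (f(8) < 0) abort_validation("mobility shift target unreachable")
  stats::uniroot(f, c(0, 8), tol = 1e-10)$root
}

#' Simulate one subject's labelled trial set
#'
#' @param spec a [sim_spec()].
#' @param subject_seed integer seed for this subject (reproducible:
#'   identical `(spec, subject_seed)` gives bit-identical output).
#' @param subject_id subject identifier (default `"s<seed>"`).
#' @return list with `trialset` (a `cchp_trialset`) and `ground_truth`
#'   (labels, planted channel set, per-kind effect parameters).
#' @export
simulate_subject <- function(spec, subject_seed, subject_id = NULL) {
  stopifnot(inherits(spec, "cchp_simspec"))
  if (is.null(subject_id)) subject_id <- sprintf("s%03d", subject_seed %% 1000)
  n <- round(spec$trial_s * spec$fs)
  env <- sim_envelope(n, spec$fs)
  beta_env <- sim_envelope(n, spec$fs, lo = 15, hi = 30)
  needs_mob <- spec$effect_kind %in% c("mobility_shift", "mixed") &&
    spec$effect > 0
  planted <- spec$channel_names %in% spec$planted_channels

  with_seed(subject_seed, {
    n_stress <- min(spec$n_trials - 1,
                    max(1, round(spec$stress_fraction * spec$n_trials)))
    labels <- sample(c(rep("stress", n_stress),
                       rep("calm", spec$n_trials - n_stress)))
    mob_pars <- NULL
    if (needs_mob) {
      # across-trial sd of null mobility, estimated once per subject
      null_mob <- vapply(seq_len(24), function(i)
        hjorth_mobility(sim_draw(env, n)), 0)
      tilt <- calibrate_tilt(n, spec$fs, spec$effect * sd(null_mob))
      mob_pars <- list(tilt = tilt, null_mobility_sd = sd(null_mob))
    }
    tilt_env <- if (needs_mob) sim_envelope(n, spec$fs, tilt = mob_pars$tilt)
      else env
    trials <- vector("list", spec$n_trials)
    for (t in seq_len(spec$n_trials)) {
      eff_ch <- planted & labels[t] == "stress" & spec$effect > 0
      env_mat <- matrix(env, length(env), spec$n_channels)
      if (any(eff_ch) && spec$effect_kind %in% c("mobility_shift", "mixed"))
        env_mat[, eff_ch] <- tilt_env
      x <- sim_draw_multi(env_mat, n)          # samples x channels
      if (any(eff_ch) && spec$effect_kind %in% c("bandpower_shift", "mixed"))
        x[, eff_ch] <- x[, eff_ch] + spec$effect *
          sim_draw_multi(matrix(beta_env, length(beta_env), sum(eff_ch)), n)
      if (spec$mixing > 0) {
        shared <- sim_draw(env, n)
        x <- sqrt(1 - spec$mixing) * x + sqrt(spec$mixing) * shared
      }
      trials[[t]] <- t(x)
    }
    ts <- structure(list(subject_id = subject_id, trials = trials,
                         labels = labels,
                         trial_index = seq_len(spec$n_trials) - 1L,
                         fs = spec$fs, channel_names = spec$channel_names),
                    class = "cchp_trialset")
    list(trialset = ts,
         ground_truth = list(subject_id = subject_id, labels = labels,
                             planted_channels = spec$planted_channels,
                             effect = spec$effect,
                             effect_kind = spec$effect_kind,
                             mobility = mob_pars))
  })
}

#' Simulate a multi-subject dataset
#'
#' Subject seeds are derived deterministically from the master seed; the
#' planted channel set is identical across subjects (the cross-subject
#' commonality the selection stage is designed to find), while backgrounds
#' are independent.
#'
#' @param spec a [sim_spec()].
#' @return list with `trialsets` (list of `cchp_trialset`) and
#'   `ground_truth` (per subject).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "cchp_simspec"))
  subs <- lapply(seq_len(spec$n_subjects), function(i)
    simulate_subject(spec, derive_seed(spec$seed, i),
                     subject_id = sprintf("s%02d", i)))
  list(trialsets = lapply(subs, `[[`, "trialset"),
       ground_truth = lapply(subs, `[[`, "ground_truth"))
}

#' Generate ratings consistent with known trial labels
#'
#' The inverse of [label_trial()]: stress trials draw valence in `[1, 3)`
#' and arousal in `(5, 9]`; calm trials draw valence in `(4, 6)` and
#' arousal in `[1, 4)`, so labelling the generated ratings recovers the
#' ground-truth labels exactly.
#'
#' @param ground_truth one subject's ground truth from
#'   [simulate_subject()], or the per-subject list from
#'   [simulate_dataset()].
#' @param seed rating-noise seed.
#' @return data.frame with columns subject, trial, valence, arousal.
#' @export
simulate_ratings <- function(ground_truth, seed = 1) {
  if (!is.null(ground_truth$labels)) ground_truth <- list(ground_truth)
  out <- lapply(seq_along(ground_truth), function(i) {
    gt <- ground_truth[[i]]
    nt <- length(gt$labels)
    with_seed(derive_seed(seed, i), {
      stress <- gt$labels == "stress"
      eps <- 1e-6
      valence <- ifelse(stress, runif(nt, 1, 3 - eps), runif(nt, 4 + eps, 6 - eps))
      arousal <- ifelse(stress, runif(nt, 5 + eps, 9), runif(nt, 1, 4 - eps))
      data.frame(subject = gt$subject_id, trial = seq_len(nt) - 1L,
                 valence = valence, arousal = arousal,
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, out)
}
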