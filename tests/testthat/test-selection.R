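# The CCHP selection core: correlation machinery, merit, greedy search,
# occurrence aggregation and ranking.

norm_tab <- function(...) zscore_table(hjorth_table(random_trialset(...)))

test_that("pair_channel_corr gives 1 for duplicated and -1 for negated channels", {
  ts <- random_trialset(n_trials = 6, n_channels = 1, n_samples = 128, seed = 2)
  trials <- lapply(ts$trials, function(tr) rbind(tr, tr, -tr))
  ts3 <- make_trialset(trials, ts$labels)
  tab <- zscore_table(hjorth_table(ts3))
  m <- pair_channel_corr(tab, "stress")
  expect_equal(unname(m[1, 2]), 1)
  expect_equal(unname(diag(m)), rep(1, 3))
  # negating a signal flips activity not at all and mobility/complexity not
  # at all, so the Hjorth vectors of channel 3 equal channel 1's: corr 1.
  expect_equal(unname(m[1, 3]), 1)

  # a genuinely anti-correlated Hjorth table: negate the feature columns
  vals <- array(rnorm(8 * 2 * 3), c(8, 2, 3))
  vals[, 2, ] <- -vals[, 1, ]
  tab2 <- make_hjorth_tab(vals, rep(c("stress", "calm"), 4), normalized = TRUE)
  expect_equal(unname(pair_channel_corr(tab2, "stress")[1, 2]), -1)
})

test_that("pair_channel_corr equals the brute-force covariance oracle to 1e-12", {
  for (seed in 1:5) {
    tab <- norm_tab(n_trials = 7, n_channels = 4, n_samples = 100, seed = seed)
    for (cl in c("stress", "calm")) {
      m <- pair_channel_corr(tab, cl)
      expect_true(isSymmetric(m))
      expect_true(all(m >= -1 - 1e-9 & m <= 1 + 1e-9))
      for (s in 1:4) for (k in 1:4)
        expect_equal(unname(m[s, k]),
                     oracle_pair_entry(tab$values, tab$labels, cl, s, k),
                     tolerance = 1e-12)
    }
  }
  tab <- norm_tab(n_trials = 3, n_channels = 2, n_samples = 64, seed = 1)
  expect_error(pair_channel_corr(tab, "calm"),
               class = "cchp_validation_error")  # single calm trial
})

test_that("pooled_pair_corr is the elementwise mean and preserves symmetry", {
  a <- matrix(c(1, .4, .4, 1), 2); b <- matrix(c(1, .8, .8, 1), 2)
  expect_equal(pooled_pair_corr(a, b), matrix(c(1, .6, .6, 1), 2))
  expect_identical(pooled_pair_corr(a, a), a)
  expect_true(isSymmetric(pooled_pair_corr(a, b)))
  expect_error(pooled_pair_corr(a, matrix(1, 3, 3)),
               class = "cchp_validation_error")
})

test_that("channel-class score approaches 1 for a strong planted contrast", {
  n <- 40
  labels <- rep(c("stress", "calm"), n / 2)
  delta <- 50
  set.seed(8)
  vals <- array(rnorm(n * 2 * 3), c(n, 2, 3))
  vals[, 1, ] <- vals[, 1, ] + ifelse(labels == "stress", delta, -delta)
  tab <- make_hjorth_tab(vals, labels, normalized = TRUE)
  sc <- channel_class_corr(tab)
  expect_gt(sc[1], 0.99)
  expect_lt(sc[2], 3 / sqrt(n))     # null channel: null-distribution bound

  # duplicating every trial leaves the point-biserial score unchanged
  tab2 <- make_hjorth_tab(vals[rep(1:n, 2), , ], rep(labels, 2),
                          normalized = TRUE)
  expect_equal(channel_class_corr(tab2), channel_class_corr(tab),
               tolerance = 1e-12)
})

test_that("null channels score near zero on average across seeds", {
  n <- 30
  scores <- vapply(1:40, function(seed) {
    set.seed(seed)
    vals <- array(rnorm(n * 1 * 3), c(n, 1, 3))
    tab <- make_hjorth_tab(vals, rep(c("stress", "calm"), n / 2),
                           normalized = TRUE)
    channel_class_corr(tab)
  }, 0)
  expect_lt(mean(scores), 2 / sqrt(n))
})

test_that("paired mode is defined for unequal classes and bounded for planted data", {
  set.seed(5)
  vals <- array(rnorm(11 * 2 * 3), c(11, 2, 3))
  labels <- c(rep("stress", 5), rep("calm", 6))
  tab <- make_hjorth_tab(vals, labels, normalized = TRUE)
  sc <- channel_class_corr(tab, mode = "paired")
  expect_true(all(is.finite(sc)))
  expect_true(all(sc >= 0 & sc <= 1 + 1e-9))
})

test_that("merit follows the printed formula and the cfs variant", {
  expect_equal(merit_score(0, 0.5, 3), 0)
  expect_equal(merit_score(0.5, 0, 1), 0.5)
  expect_equal(merit_score(0.5, 0.7, 1), 0.5)     # k = 1 has no pairs
  # direct substitution, k = 3: 3 r / (3 + 3*4*3 * rff)
  expect_equal(merit_score(0.6, 0.2, 3), 3 * 0.6 / (3 + 36 * 0.2))
  expect_equal(merit_score(0.6, 0.2, 3, mode = "cfs"),
               3 * 0.6 / sqrt(3 + 6 * 0.2))
  # strictly increasing in r_cf at fixed k, r_ff
  expect_gt(merit_score(0.7, 0.3, 4), merit_score(0.5, 0.3, 4))
  expect_error(merit_score(NaN, 0, 1), class = "cchp_validation_error")
})

test_that("greedy search recovers a planted pair under the cfs merit", {
  hits <- 0
  for (seed in 1:100) {
    set.seed(seed)
    n <- 40; nch <- 10
    labels <- rep(c("stress", "calm"), n / 2)
    vals <- array(rnorm(n * nch * 3), c(n, nch, 3))
    y <- ifelse(labels == "stress", 1, -1)
    for (ch in 1:2) vals[, ch, ] <- vals[, ch, ] + 2 * y   # effect 2 sd
    tab <- make_hjorth_tab(vals, labels, normalized = TRUE)
    sel <- select_subject_channels(tab, merit = "cfs")
    if (setequal(sel$channels, c("C1", "C2"))) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("identical copies collapse to a single channel (both merit modes)", {
  ts <- random_trialset(n_trials = 8, n_channels = 1, n_samples = 128, seed = 3)
  trials <- lapply(ts$trials, function(tr) tr[rep(1, 4), , drop = FALSE])
  ts4 <- make_trialset(trials, ts$labels)
  tab <- zscore_table(hjorth_table(ts4))
  for (mode in c("literal", "cfs")) {
    sel <- select_subject_channels(tab, merit = mode)
    expect_length(sel$channels, 1)
    # brute force over all non-empty subsets confirms no larger subset wins
    scores <- channel_class_corr(tab)
    pooled <- pooled_pair_corr(pair_channel_corr(tab, "stress"),
                               pair_channel_corr(tab, "calm"))
    best <- -Inf; best_k <- NA
    for (k in 1:4) for (sub in utils::combn(4, k, simplify = FALSE)) {
      m <- cchp:::subset_merit(sub, scores, pooled, mode)
      if (m > best + 1e-12) { best <- m; best_k <- k }
    }
    expect_equal(best_k, 1)
    expect_equal(sel$merit, best, tolerance = 1e-9)
  }
})

test_that("single-channel input selects that channel", {
  tab <- norm_tab(n_trials = 8, n_channels = 1, n_samples = 128, seed = 6)
  sel <- select_subject_channels(tab)
  expect_equal(sel$channels, "C1")
})

test_that("occurrence aggregation counts subjects per channel", {
  mk <- function(id, chans, all = c("A", "B", "C")) {
    structure(list(subject_id = id, channels = chans, merit = 0.5,
                   channel_scores = setNames(rep(0.1, length(all)), all)),
              class = "cchp_subject_selection")
  }
  u <- aggregate_occurrences(list(mk("1", c("A", "B")), mk("2", c("A", "C")),
                                  mk("3", c("A", "B"))))
  expect_equal(u[["A"]], 3); expect_equal(u[["B"]], 2); expect_equal(u[["C"]], 1)
  u2 <- aggregate_occurrences(list(mk("1", "A"), mk("2", "B"), mk("3", "C")))
  expect_true(all(u2 == 1))
  u3 <- aggregate_occurrences(list(mk("1", c("B", "C"))))
  expect_equal(unname(u3[c("A", "B", "C")]), c(0, 1, 1))
})

test_that("ranking thresholds, sorts by count and breaks ties by merit then name", {
  u <- c(A = 3L, B = 2L, C = 1L)
  expect_equal(rank_and_threshold(u, 2), c("A", "B"))
  expect_equal(rank_and_threshold(u, 1), c("A", "B", "C"))
  expect_equal(rank_and_threshold(u, 1, n_max = 2), c("A", "B"))
  u_tied <- c(A = 2L, B = 2L)
  expect_equal(rank_and_threshold(u_tied, 1,
                                  tie_break_scores = c(A = 0.4, B = 0.9)),
               c("B", "A"))
  expect_equal(rank_and_threshold(u_tied, 1), c("A", "B"))  # name fallback
  expect_warning(out <- rank_and_threshold(c(A = 1L), 5), "threshold")
  expect_equal(out, character(0))
})

test_that("selection is invariant to channel permutation and positive rescaling", {
  ts <- random_trialset(n_trials = 12, n_channels = 5, n_samples = 256,
                        planted = 1:2, boost = 2, seed = 13)
  base <- select_subject_channels(zscore_table(hjorth_table(ts)))

  perm <- c(4, 2, 5, 1, 3)
  ts_p <- make_trialset(lapply(ts$trials, function(tr) tr[perm, , drop = FALSE]),
                        ts$labels, channel_names = ts$channel_names[perm])
  sel_p <- select_subject_channels(zscore_table(hjorth_table(ts_p)))
  expect_setequal(sel_p$channels, base$channels)
  expect_equal(sort(sel_p$channel_scores[ts$channel_names]),
               sort(base$channel_scores), tolerance = 1e-12)

  scale <- c(0.1, 3, 10, 0.5, 2)
  ts_s <- make_trialset(lapply(ts$trials, function(tr) tr * scale),
                        ts$labels, channel_names = ts$channel_names)
  sel_s <- select_subject_channels(zscore_table(hjorth_table(ts_s)))
  expect_setequal(sel_s$channels, base$channels)
})
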