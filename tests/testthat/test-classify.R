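# Metrics, stratified folds, the three classifiers, leakage sentinels and
# the channel-count sweep.

test_that("confusion metrics reproduce the defining ratios", {
  m <- confusion_metrics(9, 1, 7, 3)
  expect_equal(unname(m), c(0.9, 0.75, 0.8))
  expect_equal(unname(confusion_metrics(4, 0, 6, 0)), c(1, 1, 1))
  m0 <- confusion_metrics(0, 0, 5, 5)
  expect_true(is.na(m0[["precision"]]))
  expect_equal(attr(m0, "undefined"), "precision")
  expect_equal(m0[["recall"]], 0)
  expect_equal(m0[["accuracy"]], 0.5)
  expect_error(confusion_metrics(-1, 0, 0, 0), class = "cchp_validation_error")
})

test_that("stratified folds cover every row once with balanced class counts", {
  labels <- rep(c("stress", "calm"), c(53, 47))
  f <- cchp:::stratified_folds(labels, 10, seed = 4)
  expect_length(f, 100)
  expect_true(all(f %in% 1:10))
  for (cl in c("stress", "calm")) {
    sizes <- table(f[labels == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_identical(f, cchp:::stratified_folds(labels, 10, seed = 4))
  expect_false(identical(f, cchp:::stratified_folds(labels, 10, seed = 5)))
  expect_error(cchp:::stratified_folds(rep("stress", 5), 10, seed = 1),
               class = "cchp_validation_error")
})

test_that("well-separated blobs are classified at >= 0.95 by all three classifiers", {
  ft <- blob_features(n_per_class = 100, delta = 3, seed = 1)
  for (nm in c("svm", "knn", "rlda")) {
    res <- crossvalidate_subject(ft, classifier_spec(nm), seed = 2)
    expect_gte(res$accuracy, 0.95)
  }
})

test_that("pure-noise features classify at chance", {
  ft <- blob_features(n_per_class = 100, delta = 0, seed = 3)
  for (nm in c("svm", "knn", "rlda")) {
    res <- crossvalidate_subject(ft, classifier_spec(nm), seed = 4)
    expect_gte(res$accuracy, 0.4)
    expect_lte(res$accuracy, 0.6)
  }
})

test_that("label-leaking features reach accuracy 1; fold index does not", {
  ft <- blob_features(n_per_class = 60, delta = 0, seed = 5)
  fcols <- feature_columns(ft)
  set.seed(5)
  leak <- as.numeric(ft$label == "stress")
  for (cl in fcols) ft[[cl]] <- leak + rnorm(nrow(ft), sd = 0.01)
  res <- crossvalidate_subject(ft, classifier_spec("svm"), seed = 6)
  expect_equal(res$accuracy, 1.0)

  # a feature recording the row's fold assignment carries no class signal;
  # if per-fold statistics leaked into scaling this would look informative
  ft2 <- blob_features(n_per_class = 60, delta = 0, seed = 7)
  fold <- cchp:::stratified_folds(ft2$label, 10, seed = 8)
  ft2$ptp <- as.numeric(fold)
  res2 <- crossvalidate_subject(ft2, classifier_spec("svm"), seed = 8)
  expect_lte(res2$accuracy, 0.65)
})

test_that("identical seeds reproduce folds and metrics exactly", {
  ft <- blob_features(n_per_class = 40, delta = 1, seed = 9)
  r1 <- crossvalidate_subject(ft, classifier_spec("svm"), seed = 11)
  r2 <- crossvalidate_subject(ft, classifier_spec("svm"), seed = 11)
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$confusion, r2$confusion)
})

test_that("evaluate_dataset averages per-subject metrics exactly", {
  ft <- rbind(blob_features(50, delta = 2, subject = "s01", seed = 12),
              blob_features(50, delta = 2, subject = "s02", seed = 13))
  class(ft) <- c("cchp_features", "data.frame")
  rep_ <- evaluate_dataset(ft, list(classifier_spec("rlda")), seed = 14)
  expect_equal(nrow(rep_$per_subject), 2)
  expect_equal(rep_$averages$accuracy, mean(rep_$per_subject$accuracy),
               tolerance = 1e-12)
})

test_that("channel sweep saturates at the informative channel count", {
  informative <- paste0("I", 1:3)
  nulls <- paste0("N", 1:3)
  ft <- rbind(blob_features(80, channels = informative, delta = 1.2, seed = 15),
              blob_features(80, channels = nulls, delta = 0, seed = 16))
  class(ft) <- c("cchp_features", "data.frame")
  ranked <- c(informative, nulls)
  sw <- channel_sweep(ft, ranked, set_sizes = c(1, 2, 3, 6),
                      spec = classifier_spec("rlda"), seed = 17)
  expect_equal(sw$size, c(1, 2, 3, 6))
  # more informative channels help; null channels add nothing substantial
  expect_gt(sw$mean_accuracy[3], sw$mean_accuracy[1])
  expect_gt(sw$mean_accuracy[4], sw$mean_accuracy[3] - 0.1)

  # size = all channels reproduces the plain cross-validation
  full <- crossvalidate_subject(ft, classifier_spec("rlda"),
                                seed = cchp:::derive_seed(17, 1),
                                channels = ranked)
  expect_equal(sw$mean_accuracy[4], full$accuracy, tolerance = 1e-12)
  expect_error(channel_sweep(ft, ranked, set_sizes = 10),
               class = "cchp_validation_error")

  expect_equal(eval(formals(channel_sweep)$set_sizes),
               c(1, 5, 8, 9, 15, 19, 32))
})
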