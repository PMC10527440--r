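# Classifier evaluation: SVM (RBF, C = 1, tolerance 1e-3), KNN (k = 10,
# Euclidean) and LDA ("regularized LDA" with shrinkage none, i.e. plain
# LDA), under stratified subject-wise 10-fold cross-validation with
# training-fold-only feature standardisation. Stress is the positive class.

#' Classifier specification
#'
#' @param name `"svm"`, `"knn"` or `"rlda"`.
#' @param ... parameter overrides: `cost`, `tolerance`, `gamma` (svm;
#'   `gamma = NULL` uses the 1/(n_features * mean feature variance)
#'   heuristic), `k` (knn), `scale` (all; set `FALSE` to skip within-fold
#'   standardisation).
#' @return object of class `cchp_classifier`.
#' @export
classifier_spec <- function(name = c("svm", "knn", "rlda"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    svm = list(cost = 1.0, tolerance = 1e-3, gamma = NULL, scale = TRUE),
    knn = list(k = 10L, scale = TRUE),
    rlda = list(scale = TRUE))
  structure(c(list(name = name), modifyList(defaults, list(...))),
            class = "cchp_classifier")
}

#' Precision, recall and accuracy from confusion counts
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`,
#' `accuracy = (tp+tn)/(tp+tn+fp+fn)`. A zero denominator yields `NA`
#' (undefined, not 0) with an `undefined` attribute naming the metric.
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return named numeric vector `c(precision, recall, accuracy)`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) abort_validation("negative confusion count")
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  out <- c(precision = safe(tp, tp + fp),
           recall = safe(tp, tp + fn),
           accuracy = safe(tp + tn, tp + tn + fp + fn))
  und <- names(out)[is.na(out)]
  if (length(und)) attr(out, "undefined") <- und
  out
}

# Stratified fold assignment: within each class, rows are shuffled with the
# seed and dealt round-robin, so per-class fold sizes differ by at most 1.
stratified_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < n_folds)
        abort_validation(
          "class '%s' has %d rows, fewer than %d folds; use a smaller n_folds",
          cl, length(idx), n_folds)
      fold[idx] <- (seq_along(idx) - 1L) %% n_folds + 1L
      fold[idx] <- fold[idx][order(sample.int(length(idx)))]
    }
  })
  fold
}

# Pivot the long feature table (one row per segment x channel) into one
# row per segment with channel-prefixed feature columns.
feature_design <- function(ft, channels = NULL) {
  fcols <- feature_columns(ft)
  if (is.null(channels)) channels <- unique(ft$channel)
  missing_ch <- setdiff(channels, unique(ft$channel))
  if (length(missing_ch))
    abort_validation("channels absent from feature table: %s",
                     paste(missing_ch, collapse = ", "))
  ft <- ft[ft$channel %in% channels, , drop = FALSE]
  key <- interaction(ft$subject, ft$trial, ft$segment, drop = TRUE)
  first <- !duplicated(key)
  ids <- ft[first, c("subject", "trial", "segment", "label")]
  x <- matrix(NA_real_, sum(first), length(channels) * length(fcols))
  colnames(x) <- as.vector(outer(fcols, channels, function(f, c)
    paste(c, f, sep = ".")))
  row_of <- match(key, key[first])
  for (ch in channels) {
    sel <- ft$channel == ch
    x[row_of[sel], paste(ch, fcols, sep = ".")] <-
      as.matrix(ft[sel, fcols, drop = FALSE])
  }
  if (anyNA(x)) abort_validation("feature table is not complete per segment")
  list(x = x, y = ids$label, ids = ids)
}

fit_predict <- function(spec, xtr, ytr, xte) {
  ytr <- factor(ytr, levels = c("calm", "stress"))
  if (spec$name == "svm") {
    gamma <- spec$gamma
    if (is.null(gamma)) {
      v <- mean(apply(xtr, 2, var))
      gamma <- if (v > 0) 1 / (ncol(xtr) * v) else 1 / ncol(xtr)
    }
    fit <- e1071::svm(xtr, ytr, type = "C-classification", kernel = "radial",
                      cost = spec$cost, gamma = gamma,
                      tolerance = spec$tolerance, scale = FALSE)
    as.character(predict(fit, xte))
  } else if (spec$name == "knn") {
    as.character(class::knn(xtr, xte, ytr, k = spec$k))
  } else {
    # near-duplicate features (e.g. activity vs wavelet energies) trip
    # lda's collinearity warning; the eigen solve itself is fine
    fit <- suppressWarnings(MASS::lda(xtr, grouping = ytr))
    as.character(predict(fit, xte)$class)
  }
}

#' Cross-validate one subject's feature table
#'
#' Stratified random partition into `n_folds` folds (seeded); each fold is
#' held out once while the others train. Feature columns are standardised
#' with training-fold statistics only (no leakage); training-constant
#' columns are dropped from both sides of that fold. Metrics come from the
#' confusion counts pooled across folds.
#'
#' @param ft `cchp_features` rows of one subject.
#' @param spec a [classifier_spec()].
#' @param n_folds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param channels channel subset (default: all channels present).
#' @return list with `precision`, `recall`, `accuracy`, `confusion`
#'   (tp/fp/tn/fn), `folds` (per-row assignment), `n_rows`, `seed`.
#' @export
crossvalidate_subject <- function(ft, spec, n_folds = 10, seed = 1,
                                  channels = NULL) {
  stopifnot(inherits(spec, "cchp_classifier"))
  d <- feature_design(ft, channels)
  fold <- stratified_folds(d$y, n_folds, seed)
  pred <- character(length(d$y))
  for (f in seq_len(n_folds)) {
    tr <- fold != f; te <- !tr
    xtr <- d$x[tr, , drop = FALSE]; xte <- d$x[te, , drop = FALSE]
    if (isTRUE(spec$scale)) {
      mu <- colMeans(xtr); sg <- apply(xtr, 2, sd)
      keep <- sg > 0
      if (!any(keep)) abort_degenerate("all features constant in a training fold")
      xtr <- sweep(sweep(xtr[, keep, drop = FALSE], 2, mu[keep]), 2,
                   sg[keep], "/")
      xte <- sweep(sweep(xte[, keep, drop = FALSE], 2, mu[keep]), 2,
                   sg[keep], "/")
    }
    pred[te] <- fit_predict(spec, xtr, d$y[tr], xte)
  }
  tp <- sum(pred == "stress" & d$y == "stress")
  fp <- sum(pred == "stress" & d$y == "calm")
  tn <- sum(pred == "calm" & d$y == "calm")
  fn <- sum(pred == "calm" & d$y == "stress")
  m <- confusion_metrics(tp, fp, tn, fn)
  list(precision = unname(m["precision"]), recall = unname(m["recall"]),
       accuracy = unname(m["accuracy"]),
       confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
       folds = fold, n_rows = length(d$y), seed = seed)
}

#' Evaluate classifiers subject-wise on a feature table
#'
#' Runs [crossvalidate_subject()] per subject and classifier and averages
#' the per-subject metrics.
#'
#' @param ft `cchp_features` rows of one or more subjects.
#' @param specs list of [classifier_spec()] objects (default: the three
#'   study classifiers).
#' @param n_folds folds per subject (default 10).
#' @param seed base seed; each subject gets a derived seed.
#' @param channels channel subset (default: all).
#' @return object of class `cchp_cvreport`: list with `per_subject`
#'   (data.frame subject x classifier metrics) and `averages`.
#' @export
evaluate_dataset <- function(ft, specs = NULL, n_folds = 10, seed = 1,
                             channels = NULL) {
  if (is.null(specs))
    specs <- list(classifier_spec("svm"), classifier_spec("knn"),
                  classifier_spec("rlda"))
  if (nrow(ft) == 0) abort_validation("empty feature table")
  subjects <- unique(ft$subject)
  rows <- list()
  for (si in seq_along(subjects)) {
    sub_ft <- ft[ft$subject == subjects[si], , drop = FALSE]
    for (spec in specs) {
      res <- crossvalidate_subject(sub_ft, spec, n_folds,
                                   seed = derive_seed(seed, si),
                                   channels = channels)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subjects[si], classifier = spec$name,
        precision = res$precision, recall = res$recall,
        accuracy = res$accuracy, stringsAsFactors = FALSE)
    }
  }
  per_subject <- do.call(rbind, rows)
  averages <- do.call(rbind, lapply(split(per_subject, per_subject$classifier),
    function(df) data.frame(classifier = df$classifier[1],
                            precision = mean(df$precision),
                            recall = mean(df$recall),
                            accuracy = mean(df$accuracy),
                            sd_accuracy = sd(df$accuracy))))
  rownames(averages) <- NULL
  structure(list(per_subject = per_subject, averages = averages,
                 n_folds = n_folds, seed = seed),
            class = "cchp_cvreport")
}

#' @export
print.cchp_cvreport <- function(x, ...) {
  cat("<cchp_cvreport> subject-wise", x$n_folds, "fold cross-validation\n")
  print(x$averages, row.names = FALSE)
  invisible(x)
}

#' Accuracy versus ranked channel-set size
#'
#' For each size `s` in `set_sizes`, evaluates the classifier on the top
#' `s` channels of `ranked_channels` (each channel contributing its 20
#' features) with subject-wise cross-validation, and reports the mean and
#' standard deviation of the per-subject accuracies.
#'
#' @param ft `cchp_features` containing all candidate channels.
#' @param ranked_channels channel names, best first (e.g. the `ranked`
#'   element of a [cchp_select()] result).
#' @param set_sizes integer sizes to evaluate (default
#'   `c(1, 5, 8, 9, 15, 19, 32)`, truncated to the available channels).
#' @param spec a [classifier_spec()] (default SVM).
#' @param n_folds,seed passed to [evaluate_dataset()].
#' @return data.frame with `size`, `mean_accuracy`, `sd_accuracy`.
#' @export
channel_sweep <- function(ft, ranked_channels,
                          set_sizes = c(1, 5, 8, 9, 15, 19, 32),
                          spec = classifier_spec("svm"), n_folds = 10,
                          seed = 1) {
  set_sizes <- unique(set_sizes[set_sizes >= 1])
  if (any(set_sizes > length(ranked_channels)))
    abort_validation("set size %d exceeds the %d ranked channels",
                     max(set_sizes), length(ranked_channels))
  out <- lapply(set_sizes, function(s) {
    rep_ <- evaluate_dataset(ft, specs = list(spec), n_folds = n_folds,
                             seed = seed, channels = ranked_channels[seq_len(s)])
    data.frame(size = s,
               mean_accuracy = rep_$averages$accuracy,
               sd_accuracy = rep_$averages$sd_accuracy)
  })
  do.call(rbind, out)
}
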