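#' Seeded stratified train/test split
#'
#' Shuffles the whole dataset, then partitions it 70/30 (by default)
#' preserving class proportions to within one sample per class.
#'
#' @param labels label vector.
#' @param train_fraction fraction assigned to training.
#' @param seed shuffle seed.
#' @param stratified preserve class proportions.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_data <- function(labels, train_fraction = 0.7, seed = 1,
                       stratified = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  set.seed(seed)
  n <- length(labels)
  if (stratified) {
    train <- integer(0)
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (length(idx) < 2) stop("need at least 2 samples per class")
      idx <- idx[sample.int(length(idx))]
      train <- c(train, idx[seq_len(round(train_fraction * length(idx)))])
    }
    train <- sort(train)
  } else {
    perm <- sample.int(n)
    train <- sort(perm[seq_len(round(train_fraction * n))])
  }
  test <- setdiff(seq_len(n), train)
  cover <- function(idx) length(unique(labels[idx])) == length(unique(labels))
  if (!cover(train) || !cover(test)) {
    stop("a class is absent from one partition; use stratified = TRUE")
  }
  list(train = train, test = test)
}

#' Subsample to a class-balanced index set
#'
#' Silence epochs make unheard the majority class; evaluation uses a
#' seeded subsample of the majority class so both labels are equally
#' represented, matching a chance level of 0.5.
#'
#' @param labels label vector.
#' @param seed subsample seed.
#' @return Sorted integer indices of the balanced subset.
#' @export
balance_classes <- function(labels, seed = 1) {
  set.seed(seed)
  classes <- unique(labels)
  n_min <- min(table(labels))
  sort(unlist(lapply(classes, function(cls) {
    idx <- which(labels == cls)
    sort(idx[sample.int(length(idx), n_min)])
  })))
}

#' Stratified k-fold cross-validation accuracy
#'
#' @param x feature matrix, documents x terms.
#' @param labels label vector.
#' @param family a [classifier_families()] entry.
#' @param k number of folds (at most the minority-class count).
#' @param seed fold-assignment seed.
#' @param ... passed on to [train_predict()] (e.g. `knn_k`).
#' @return List with `fold_accuracy` (length `k`) and `mean_accuracy`.
#' @export
kfold_cv <- function(x, labels, family, k = 5, seed = 1, ...) {
  stopifnot(k >= 2)
  if (k > min(table(labels))) stop("k exceeds the minority-class count")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(k), length(idx))
  }
  acc <- vapply(seq_len(k), function(f) {
    te <- which(fold == f); tr <- which(fold != f)
    out <- train_predict(x[tr, , drop = FALSE], x[te, , drop = FALSE],
                         labels[tr], family, seed = seed, ...)
    mean(out$pred == labels[te])
  }, numeric(1))
  list(fold_accuracy = acc, mean_accuracy = mean(acc))
}

#' Featurize a labeled epoch set with a training-frozen vocabulary
#'
#' Tokenizes every epoch, builds the vocabulary and document frequencies
#' from the training documents only, and TF-IDF-weights both partitions
#' with the training IDF. Out-of-vocabulary test tokens are ignored.
#'
#' @param epochs an `epoch_set`.
#' @param split index list from [split_data()] over the epoch labels.
#' @param l2_normalize passed to [tfidf_weights()].
#' @return List `train_x`, `test_x`, `train_y`, `test_y`, `vocab`, `idf`.
#' @export
featurize_split <- function(epochs, split, l2_normalize = TRUE) {
  corpus <- tokenize_epochs(epochs)
  train_fit <- featurize(corpus[split$train], l2_normalize = l2_normalize)
  test_counts <- count_vectorize(corpus[split$test], train_fit$vocab)
  list(train_x = train_fit$weights,
       test_x = tfidf_weights(test_counts, train_fit$idf, l2_normalize),
       train_y = epochs$labels[split$train],
       test_y = epochs$labels[split$test],
       vocab = train_fit$vocab, idf = train_fit$idf)
}

#' Evaluate a bank of classifiers on one epoch set
#'
#' Splits, featurizes with a training-frozen vocabulary, fits every
#' requested family, and reports confusion counts plus the full metric
#' suite per family (optionally with cross-validated accuracy).
#'
#' @param epochs an `epoch_set`.
#' @param families classifier families to run.
#' @param train_fraction,seed split parameters.
#' @param cv_folds stratified CV folds; 0 skips cross-validation.
#' @param l2_normalize passed to the TF-IDF stage.
#' @return Data frame, one row per family: `algorithm`, `tn`, `fp`, `fn`,
#'   `tp`, `accuracy`, `mse` (the classification error, as a rate),
#'   `recall`, `precision`, `f1`, `specificity`, `mcc`, `log_loss`,
#'   `auc`, `cv_accuracy`. Undefined metrics are `NA`.
#' @export
evaluate_classifiers <- function(epochs, families = classifier_families(),
                                 train_fraction = 0.7, seed = 1,
                                 cv_folds = 0, l2_normalize = TRUE) {
  split <- split_data(epochs$labels, train_fraction, seed = seed)
  fs <- featurize_split(epochs, split, l2_normalize)
  rows <- lapply(families, function(fam) {
    out <- train_predict(fs$train_x, fs$test_x, fs$train_y, fam, seed = seed)
    cm <- confusion_counts(fs$test_y, out$pred)
    m <- classification_metrics(cm, out$prob_heard, fs$test_y)
    cv <- NA_real_
    if (cv_folds >= 2) {
      all_x <- rbind(fs$train_x, fs$test_x)
      all_y <- c(fs$train_y, fs$test_y)
      cv <- kfold_cv(all_x, all_y, fam, k = cv_folds, seed = seed)$mean_accuracy
    }
    data.frame(algorithm = fam, tn = cm$tn, fp = cm$fp, fn = cm$fn,
               tp = cm$tp, accuracy = m$accuracy, mse = m$error,
               recall = m$recall, precision = m$precision, f1 = m$f1,
               specificity = m$specificity, mcc = m$mcc,
               log_loss = m$log_loss, auc = m$auc, cv_accuracy = cv)
  })
  do.call(rbind, rows)
}

#' Channel-ablation experiment
#'
#' Re-runs the epoch / feature / classifier pipeline on each channel
#' subset (all 16, the first 13, the first 8 by default), with a fresh
#' vocabulary per subset and the same split seed throughout, so subsets
#' differ only in the channels feeding the features.
#'
#' @param rec a preprocessed [eeg_recording()].
#' @param events labeled events from [label_events()].
#' @param subsets character vector of [channel_subset()] presets.
#' @param window_s epoch window.
#' @param balance subsample to class balance before splitting.
#' @inheritParams evaluate_classifiers
#' @return Data frame as [evaluate_classifiers()] with a leading
#'   `channels` column (one block of rows per subset).
#' @export
run_ablation <- function(rec, events, subsets = c("1-16", "1-13", "1-8"),
                         window_s = 0.7, families = classifier_families(),
                         train_fraction = 0.7, seed = 1, cv_folds = 0,
                         balance = TRUE) {
  blocks <- lapply(subsets, function(ss) {
    ep <- extract_epochs(rec, events, window_s = window_s, channels = ss)
    if (balance) {
      keep <- balance_classes(ep$labels, seed = seed)
      ep$data <- ep$data[, , keep, drop = FALSE]
      ep$labels <- ep$labels[keep]
      ep$kinds <- ep$kinds[keep]
      ep$positions <- ep$positions[keep]
    }
    res <- evaluate_classifiers(ep, families, train_fraction, seed, cv_folds)
    cbind(channels = ss, res)
  })
  do.call(rbind, blocks)
}

#' Render an evaluation table with percentages and "-" for undefined
#'
#' Formats rates as percentages with one decimal (the reporting
#' convention of the evaluation tables) and undefined metrics as `"-"`.
#'
#' @param report data frame from [evaluate_classifiers()] or
#'   [run_ablation()].
#' @return Character data frame ready for printing or CSV export.
#' @export
format_report <- function(report) {
  pct <- function(v) ifelse(is.na(v), "-", sprintf("%.1f", 100 * v))
  num <- function(v, d) ifelse(is.na(v), "-", sprintf(paste0("%.", d, "f"), v))
  out <- report
  for (col in intersect(c("accuracy", "mse", "recall", "precision", "f1",
                          "specificity", "cv_accuracy", "auc"), names(out))) {
    out[[col]] <- pct(out[[col]])
  }
  if ("mcc" %in% names(out)) out$mcc <- num(report$mcc, 3)
  if ("log_loss" %in% names(out)) out$log_loss <- num(report$log_loss, 3)
  out
}
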