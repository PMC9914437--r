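test_that("stratified split is disjoint, exhaustive, proportional and seeded", {
  labels <- rep(c("heard", "unheard"), each = 50)
  sp <- split_data(labels, 0.7, seed = 1)
  expect_length(sp$train, 70)
  expect_length(sp$test, 30)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_equal(sum(labels[sp$train] == "heard"), 35)
  expect_identical(sp, split_data(labels, 0.7, seed = 1))
  expect_false(identical(sp$train, split_data(labels, 0.7, seed = 2)$train))

  uneven <- rep(c("heard", "unheard"), c(30, 71))
  spu <- split_data(uneven, 0.7, seed = 3)
  expect_equal(sum(uneven[spu$train] == "heard"), 21)  # 0.7*30, within 1
  expect_error(split_data(c("heard", "unheard"), 0.5), "at least 2")
})

test_that("balance_classes equalizes label counts", {
  labels <- rep(c("heard", "unheard"), c(20, 55))
  keep <- balance_classes(labels, seed = 4)
  expect_equal(unname(table(labels[keep])), c(20L, 20L), ignore_attr = TRUE)
  expect_identical(keep, balance_classes(labels, seed = 4))
})

test_that("confusion counts follow the heard-positive convention", {
  cm <- confusion_counts(c("heard", "heard", "unheard"),
                         c("heard", "heard", "unheard"))
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]), c(tp = 2, fp = 0,
                                                        fn = 0, tn = 1))
  all_neg <- confusion_counts(rep("heard", 5), rep("unheard", 5))
  expect_equal(all_neg$fn, 5)
  expect_error(confusion_counts("heard", c("heard", "heard")), "mismatch")
})

test_that("metric identities hold over random confusion matrices", {
  set.seed(10)
  for (i in 1:200) {
    cm <- list(tp = rpois(1, 20), fp = rpois(1, 20),
               fn = rpois(1, 20), tn = rpois(1, 20))
    if (sum(unlist(cm)) == 0) next
    m <- classification_metrics(cm)
    expect_equal(m$accuracy + m$error, 1)
    if (!is.na(m$recall)) expect_equal(m$recall * (cm$tp + cm$fn), cm$tp)
    if (!is.na(m$f1)) {
      expect_equal(m$f1, 2 / (1 / m$precision + 1 / m$recall))
    }
    expect_lte(abs(m$mcc), 1)
  }
})

test_that("degenerate all-negative predictions yield undefined precision and zero MCC", {
  m <- classification_metrics(list(tp = 0, fp = 0, fn = 162, tn = 150))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$f1))
  expect_equal(m$mcc, 0)
  expect_equal(m$specificity, 1)
  perfect <- classification_metrics(list(tp = 10, fp = 0, fn = 0, tn = 10))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$error, 0)
  expect_error(classification_metrics(list(tp = 0, fp = 0, fn = 0, tn = 0)),
               "empty")
})

test_that("log loss matches direct cross-entropy and clips extremes", {
  y <- c(TRUE, FALSE, TRUE)
  p <- c(0.9, 0.2, 0.6)
  expect_equal(log_loss(y, p), -mean(log(c(0.9, 0.8, 0.6))))
  expect_lt(log_loss(TRUE, 0), -log(1e-15) + 1e-6)  # clipped, finite
})

test_that("trapezoidal AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:5) {
    y <- sample(c(TRUE, FALSE), 60, replace = TRUE)
    if (length(unique(y)) < 2) next
    p <- runif(60)
    ref <- as.numeric(pROC::auc(pROC::roc(as.numeric(y), p, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(y, p), ref, tolerance = 1e-10)
  }
  # random probabilities on balanced labels hover around 0.5
  set.seed(12)
  aucs <- replicate(20, roc_auc(rep(c(TRUE, FALSE), 50), runif(100)))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("every classifier family fits a separable toy problem deterministically", {
  set.seed(13)
  n <- 60
  x <- rbind(matrix(rnorm(n * 4, mean = 0), ncol = 4),
             matrix(rnorm(n * 4, mean = 3), ncol = 4))
  y <- rep(c("unheard", "heard"), each = n)
  test_x <- rbind(matrix(rnorm(40, mean = 0), ncol = 4),
                  matrix(rnorm(40, mean = 3), ncol = 4))
  test_y <- rep(c("unheard", "heard"), each = 10)
  for (fam in classifier_families()) {
    out <- train_predict(x, test_x, y, fam, seed = 1)
    expect_equal(mean(out$pred == test_y), 1,
                 info = fam, tolerance = 0.11)
    expect_true(all(out$prob_heard >= 0 & out$prob_heard <= 1), info = fam)
    again <- train_predict(x, test_x, y, fam, seed = 1)
    expect_identical(out, again, info = fam)
  }
  expect_error(train_predict(x, test_x, y, "perceptron"), "unknown")
})

test_that("label-shuffled training yields chance-level test accuracy", {
  set.seed(14)
  accs <- vapply(1:3, function(s) {
    x <- matrix(rnorm(120 * 6), ncol = 6)
    y <- sample(rep(c("heard", "unheard"), 60))
    sp <- split_data(y, 0.7, seed = s)
    out <- train_predict(x[sp$train, ], x[sp$test, ], y[sp$train],
                         "decision_tree", seed = s)
    mean(out$pred == y[sp$test])
  }, numeric(1))
  half <- 2.576 * sqrt(0.25 / 36)  # 99% binomial band at n = 36
  expect_lt(abs(mean(accs) - 0.5), half)
})

test_that("k-fold CV matches brute-force leave-one-out on a toy set", {
  x <- matrix(c(0, 0.1, 0.2, 5, 5.1, 5.2), ncol = 1)
  y <- rep(c("unheard", "heard"), each = 3)
  # explicit LOO with 1-NN: every point's nearest neighbour shares its class
  loo <- vapply(seq_along(y), function(i) {
    d <- abs(x[-i, 1] - x[i, 1])
    y[-i][which.min(d)] == y[i]
  }, logical(1))
  expect_equal(mean(loo), 1)
  cv <- kfold_cv(x, y, "k_nearest_neighbor", k = 3, seed = 2, knn_k = 1)
  expect_equal(cv$mean_accuracy, 1)
  expect_identical(kfold_cv(x, y, "k_nearest_neighbor", k = 3, seed = 5,
                            knn_k = 1),
                   kfold_cv(x, y, "k_nearest_neighbor", k = 3, seed = 5,
                            knn_k = 1))
  expect_error(kfold_cv(x, y, "k_nearest_neighbor", k = 4), "minority")
})

test_that("published confusion rows re-derive their printed metric cells", {
  rows <- published_metric_rows()
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    m <- classification_metrics(list(tp = r$tp, fp = r$fp,
                                     fn = r$fn, tn = r$tn))
    expect_lt(abs(100 * m$accuracy - r$accuracy), 0.051)
    expect_lt(abs(100 * m$error - r$mse), 0.051)
    expect_lt(abs(100 * m$recall - r$recall), 0.051)
    if (is.na(r$precision)) {
      expect_true(is.na(m$precision))
      expect_true(is.na(m$f1))
    } else {
      expect_lt(abs(100 * m$precision - r$precision), 0.051)
      expect_lt(abs(100 * m$f1 - r$f1), 0.051)
    }
    expect_lt(abs(100 * m$specificity - r$specificity), 0.051)
    digits <- nchar(sub("^[^.]*\\.?", "", format(r$mcc)))
    expect_lt(abs(m$mcc - r$mcc), 0.51 * 10^-max(digits, 1))
  }
})

test_that("formatted reports render rates as percentages and NA as dashes", {
  df <- data.frame(algorithm = "support_vector", tn = 150, fp = 0, fn = 162,
                   tp = 0, accuracy = 0.481, mse = 0.519, recall = 0,
                   precision = NA, f1 = NA, specificity = 1, mcc = 0,
                   log_loss = 0.692, auc = 0.5, cv_accuracy = NA)
  out <- format_report(df)
  expect_equal(out$precision, "-")
  expect_equal(out$f1, "-")
  expect_equal(out$accuracy, "48.1")
  expect_equal(out$specificity, "100.0")
  expect_equal(out$log_loss, "0.692")
})
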