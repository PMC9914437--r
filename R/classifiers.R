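#' Classifier families of the evaluation bank
#'
#' Seven standard families, each delegated to an established
#' implementation: Gaussian naive Bayes (`e1071::naiveBayes`), gradient
#' boosted trees (`xgboost`), support vector classifier (`e1071::svm`,
#' RBF), decision tree (`rpart`), k-nearest neighbours (`class::knn`),
#' L2-regularized logistic regression (`glmnet`, ridge) and random forest
#' (`randomForest`).
#'
#' @export
classifier_families <- function() {
  c("naive_bayes", "gradient_boosted_trees", "support_vector",
    "decision_tree", "k_nearest_neighbor", "logistic_regression",
    "random_forest")
}

as_label_factor <- function(y) {
  # "unheard" first so that "heard" is the positive (second) level
  factor(as.character(y), levels = c("unheard", "heard"))
}

#' Fit one classifier family and predict on held-out data
#'
#' Fits on the training partition only and returns hard labels plus
#' P(heard) for the test partition. All stochastic families are seeded so
#' identical inputs give identical predictions.
#'
#' @param train_x,test_x numeric feature matrices (documents x terms).
#' @param train_y training labels (`"heard"` / `"unheard"`).
#' @param family one of [classifier_families()].
#' @param seed RNG seed for stochastic fits.
#' @param knn_k neighbours for `k_nearest_neighbor`.
#' @return List with `pred` (character labels) and `prob_heard`.
#' @export
train_predict <- function(train_x, test_x, train_y, family, seed = 1,
                          knn_k = 5) {
  if (!family %in% classifier_families()) {
    stop("unknown classifier family: ", family)
  }
  y <- as_label_factor(train_y)
  if (nlevels(droplevels(y)) < 2) stop("training data must contain both classes")
  set.seed(seed)
  colnames(train_x) <- colnames(test_x) <- paste0("t", seq_len(ncol(train_x)))

  prob <- switch(family,
    naive_bayes = {
      fit <- e1071::naiveBayes(train_x, y)
      predict(fit, test_x, type = "raw")[, "heard"]
    },
    gradient_boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(train_x,
                                     label = as.numeric(y == "heard"))
      fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                              max_depth = 6, eta = 0.3,
                                              nthread = 1, seed = seed),
                                data = dtrain, nrounds = 100)
      predict(fit, xgboost::xgb.DMatrix(test_x))
    },
    support_vector = {
      fit <- e1071::svm(train_x, y, probability = TRUE, kernel = "radial")
      p <- predict(fit, test_x, probability = TRUE)
      attr(p, "probabilities")[, "heard"]
    },
    decision_tree = {
      df <- as.data.frame(train_x)
      df$.y <- y
      fit <- rpart::rpart(.y ~ ., data = df, method = "class")
      predict(fit, as.data.frame(test_x), type = "prob")[, "heard"]
    },
    k_nearest_neighbor = {
      p <- class::knn(train_x, test_x, y, k = knn_k, prob = TRUE)
      win <- attr(p, "prob")
      ifelse(p == "heard", win, 1 - win)
    },
    logistic_regression = {
      fit <- glmnet::glmnet(train_x, y, family = "binomial", alpha = 0,
                            lambda = 0.01)
      as.numeric(predict(fit, test_x, type = "response"))
    },
    random_forest = {
      fit <- randomForest::randomForest(train_x, y, ntree = 200)
      predict(fit, test_x, type = "prob")[, "heard"]
    })
  prob <- as.numeric(prob)
  list(pred = ifelse(prob >= 0.5, "heard", "unheard"), prob_heard = prob)
}
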