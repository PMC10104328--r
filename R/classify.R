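CLASSIFIERS <- c("svm", "knn", "tree", "nb", "logistic")

# train on (Xtr, ytr) and predict labels for Xte; y is a factor with levels
# c("pre", "post"). Hyperparameters follow the configured defaults: linear
# SVM with unit cost on unscaled [0,1] features, kNN with k = 5, rpart and
# naive Bayes defaults, plain logistic regression.
fit_predict <- function(classifier, Xtr, ytr, Xte, knn_k = 5) {
  classifier <- match.arg(classifier, CLASSIFIERS)
  Xtr <- as.matrix(Xtr); Xte <- as.matrix(Xte)
  lv <- levels(ytr)
  pred <- switch(
    classifier,
    svm = {
      m <- e1071::svm(Xtr, ytr, kernel = "linear", cost = 1, scale = FALSE)
      predict(m, Xte)
    },
    knn = {
      k <- min(knn_k, nrow(Xtr))
      class::knn(Xtr, Xte, ytr, k = k)
    },
    tree = {
      df <- data.frame(y = ytr, Xtr)
      m <- rpart::rpart(y ~ ., data = df, method = "class",
                        control = rpart::rpart.control(minsplit = 4,
                                                       minbucket = 2,
                                                       cp = 0.01))
      nd <- data.frame(Xte)
      names(nd) <- names(df)[-1]
      predict(m, nd, type = "class")
    },
    nb = {
      m <- e1071::naiveBayes(Xtr, ytr)
      predict(m, Xte)
    },
    logistic = {
      df <- data.frame(y = ytr, Xtr)
      m <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
      nd <- data.frame(Xte)
      names(nd) <- names(df)[-1]
      pr <- suppressWarnings(predict(m, nd, type = "response"))
      factor(ifelse(pr > 0.5, lv[2], lv[1]), levels = lv)
    })
  factor(as.character(pred), levels = lv)
}

#' Confusion counts with pre-SET as the positive class
#'
#' @param truth,pred Factors with levels `c("pre", "post")`.
#' @return Named integer vector `c(TP, FP, TN, FN)`: TP counts true `pre`
#'   predicted `pre`, FP true `post` predicted `pre`, TN true `post`
#'   predicted `post`, FN true `pre` predicted `post`.
#' @export
confusion_counts <- function(truth, pred) {
  c(TP = sum(truth == "pre" & pred == "pre"),
    FP = sum(truth == "post" & pred == "pre"),
    TN = sum(truth == "post" & pred == "post"),
    FN = sum(truth == "pre" & pred == "post"))
}

#' Classification performance metrics from confusion counts
#'
#' Accuracy `(TP + TN) / (TP + FP + TN + FN)`, sensitivity `TP / (TP + FN)`
#' (classification accuracy of pre-SET samples) and specificity
#' `TN / (TN + FP)` (of post-SET samples). A metric whose denominator is
#' zero is returned as `NA` (missing-value sentinel).
#'
#' @param counts Named vector with elements `TP`, `FP`, `TN`, `FN`.
#' @return Named numeric `c(accuracy, sensitivity, specificity)`.
#' @export
#' @examples
#' performance(c(TP = 9, FP = 1, TN = 8, FN = 2))
performance <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  total <- tp + fp + tn + fn
  c(accuracy = if (total > 0) (tp + tn) / total else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per horse: all samples of the held-out horse form the test set
#' and are never part of that fold's training set. Predictions are pooled
#' across folds into a single confusion-count table; per-fold metrics are
#' also returned so fold-level mean and SD can be reported.
#'
#' @param X Feature matrix (rows are samples).
#' @param y Labels, factor with levels `c("pre", "post")`.
#' @param horse_ids Subject id per row; defines the folds.
#' @param classifier One of `"svm"`, `"knn"`, `"tree"`, `"nb"`,
#'   `"logistic"`.
#' @return List with `counts` (pooled [confusion_counts()]), `metrics`
#'   (pooled [performance()]), and `folds` (data frame of per-fold metrics).
#' @export
loso_cv <- function(X, y, horse_ids,
                    classifier = c("svm", "knn", "tree", "nb", "logistic")) {
  classifier <- match.arg(classifier)
  X <- as.matrix(X)
  y <- factor(as.character(y), levels = c("pre", "post"))
  horses <- unique(horse_ids)
  if (length(horses) < 2L)
    stop("leave-one-subject-out needs at least 2 horses", call. = FALSE)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  fold_rows <- list()
  for (h in horses) {
    te <- horse_ids == h
    ph <- fit_predict(classifier, X[!te, , drop = FALSE], y[!te],
                      X[te, , drop = FALSE])
    pred[te] <- ph
    pm <- performance(confusion_counts(y[te], ph))
    fold_rows[[length(fold_rows) + 1L]] <- data.frame(
      horse = h, n = sum(te), accuracy = pm["accuracy"],
      sensitivity = pm["sensitivity"], specificity = pm["specificity"],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  counts <- confusion_counts(y, pred)
  list(counts = counts, metrics = performance(counts),
       folds = do.call(rbind, fold_rows))
}

# greedy prefix search over a ranked feature list given an accuracy
# evaluator: grow the prefix while accuracy does not decrease (ties
# continue); return the last prefix before the first strict decrease
greedy_prefix <- function(features, eval_fn) {
  if (!length(features)) stop("ranking is empty", call. = FALSE)
  acc_path <- numeric(0)
  best_k <- 0L
  for (k in seq_along(features)) {
    a <- eval_fn(features[seq_len(k)])
    if (k > 1L && a < acc_path[k - 1L]) break
    acc_path[k] <- a
    best_k <- k
  }
  list(selected = features[seq_len(best_k)], accuracy = acc_path[best_k],
       accuracy_path = acc_path)
}

#' Greedy forward selection over an NCA ranking
#'
#' Starting from the top-ranked feature, features are added in ranking order
#' and the leave-one-subject-out accuracy of the growing prefix is
#' evaluated; the process stops as soon as accuracy strictly decreases
#' (equal accuracy continues) and returns the previous prefix with its
#' metrics.
#'
#' @param ranking A [rank_features()] object (or character vector of ranked
#'   names).
#' @param X,y,horse_ids,classifier As in [loso_cv()].
#' @return List with `selected` (feature names), `result` (the [loso_cv()]
#'   output for the selected set), and `accuracy_path` (prefix accuracies
#'   evaluated).
#' @export
greedy_forward_selection <- function(ranking, X, y, horse_ids,
                                     classifier = "svm") {
  features <- if (inherits(ranking, "feature_ranking")) ranking$features
  else as.character(ranking)
  X <- as.matrix(X)
  gp <- greedy_prefix(features, function(fs) {
    loso_cv(X[, fs, drop = FALSE], y, horse_ids, classifier)$metrics[
      "accuracy"]
  })
  res <- loso_cv(X[, gp$selected, drop = FALSE], y, horse_ids, classifier)
  list(selected = gp$selected, result = res,
       accuracy_path = gp$accuracy_path)
}
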