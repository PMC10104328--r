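#' Fit a fatigue classifier with NCA ranking and greedy selection
#'
#' The package's central estimator. Given a horse-trial feature matrix, it
#' (1) computes NCA feature weights, (2) ranks the features, (3) grows the
#' feature set greedily in ranking order under leave-one-subject-out
#' cross-validation until accuracy decreases, and (4) refits the chosen
#' classifier on all samples with the selected features for later
#' prediction. `pre` (rested, non-fatigue) is the positive class.
#'
#' Speed and the three gait-event durations are always reported alongside
#' the fit (`forced_features`) with their class means, whether or not the
#' ranking selects them; by default they are not force-inserted into the
#' classifier's feature set (`force_include = TRUE` inserts them at the
#' front of the ranking).
#'
#' @param x Feature matrix or data frame; non-feature columns `horse`,
#'   `trial`, `gait_subset`, `n_strides`, `metric` are used as metadata when
#'   present.
#' @param y Labels (`pre`/`post`); defaults to the `trial` column of `x`.
#' @param horse_ids Subject ids; default the `horse` column of `x`.
#' @param classifier One of `"svm"`, `"knn"`, `"tree"`, `"nb"`,
#'   `"logistic"`.
#' @param lambda NCA regularization (default `1 / n`).
#' @param seed Integer seed forwarded to [nca_weights()].
#' @param force_include Force speed and duration features into the model's
#'   feature set.
#' @return Object of class `fatigue_fit` with components `weights`,
#'   `ranking`, `selected`, `counts`, `metrics`, `folds`, `accuracy_path`,
#'   `forced_features`, `classifier`, `model` (the full-data refit) and
#'   `data`.
#' @export
#' @examples
#' sim <- simulate_feature_matrix(8, informative = 1:2, effect = 0.6,
#'                                n_features = 6, seed = 3)
#' fit <- fatigue_fit(sim$X, sim$y, sim$horse_ids, classifier = "knn")
#' fit$metrics
fatigue_fit <- function(x, y = NULL, horse_ids = NULL,
                        classifier = c("svm", "knn", "tree", "nb",
                                       "logistic"),
                        lambda = NULL, seed = 0, force_include = FALSE) {
  classifier <- match.arg(classifier)
  meta_cols <- c("horse", "trial", "gait_subset", "n_strides", "metric")
  if (is.data.frame(x)) {
    y <- y %||% x$trial
    horse_ids <- horse_ids %||% x$horse
    x <- as.matrix(x[, setdiff(names(x), meta_cols), drop = FALSE])
  }
  X <- as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- factor(as.character(y), levels = c("pre", "post"))
  w <- nca_weights(X, y, lambda = lambda, seed = seed)
  ranking <- rank_features(w)
  features <- ranking$features
  forced <- intersect(c("mean_speed", "mean_stride_duration",
                        "mean_stance_duration", "mean_swing_duration",
                        "speed", "stride_duration", "stance_duration",
                        "swing_duration"), colnames(X))
  if (force_include)
    features <- c(forced, setdiff(features, forced))
  sel <- greedy_forward_selection(features, X, y, horse_ids, classifier)
  model <- NULL
  forced_tab <- if (length(forced)) {
    data.frame(feature = forced,
               mean_pre = colMeans(X[y == "pre", forced, drop = FALSE]),
               mean_post = colMeans(X[y == "post", forced, drop = FALSE]),
               row.names = NULL, stringsAsFactors = FALSE)
  } else NULL
  structure(list(weights = w, ranking = ranking, selected = sel$selected,
                 counts = sel$result$counts, metrics = sel$result$metrics,
                 folds = sel$result$folds,
                 accuracy_path = sel$accuracy_path,
                 forced_features = forced_tab,
                 classifier = classifier,
                 data = list(X = X, y = y, horse_ids = horse_ids)),
            class = "fatigue_fit")
}

#' @export
print.fatigue_fit <- function(x, ...) {
  cat(sprintf("<fatigue_fit> %s, %d/%d features selected\n", x$classifier,
              length(x$selected), length(x$weights)))
  cat("  selected:", paste(head(x$selected, 8), collapse = ", "),
      if (length(x$selected) > 8) "..." else "", "\n")
  m <- round(100 * x$metrics, 1)
  cat(sprintf("  LOSO accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              m["accuracy"], m["sensitivity"], m["specificity"]))
  invisible(x)
}

#' @export
summary.fatigue_fit <- function(object, ...) {
  f <- object$folds
  out <- list(classifier = object$classifier,
              selected = object$selected,
              counts = object$counts,
              pooled = object$metrics,
              fold_mean = colMeans(f[, c("accuracy", "sensitivity",
                                         "specificity")], na.rm = TRUE),
              fold_sd = apply(f[, c("accuracy", "sensitivity",
                                    "specificity")], 2, sd, na.rm = TRUE),
              forced_features = object$forced_features)
  class(out) <- "summary.fatigue_fit"
  out
}

#' @export
print.summary.fatigue_fit <- function(x, ...) {
  cat("Fatigue classification (positive class: pre-SET)\n")
  cat("Classifier:", x$classifier, "\n")
  cat("Selected features:", paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("Pooled: accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              x$pooled["accuracy"], x$pooled["sensitivity"],
              x$pooled["specificity"]))
  cat(sprintf("Across folds: accuracy %.3f +/- %.3f\n",
              x$fold_mean["accuracy"], x$fold_sd["accuracy"]))
  cat("Confusion counts:", paste(names(x$counts), x$counts,
                                 collapse = ", "), "\n")
  if (!is.null(x$forced_features)) {
    cat("Always-reported features (class means):\n")
    print(x$forced_features, digits = 3)
  }
  invisible(x)
}

#' @export
coef.fatigue_fit <- function(object, ...) object$weights

#' Predict fatigue state for new horse-trial feature vectors
#'
#' Refits the chosen classifier on all training samples with the selected
#' features and predicts the class of `newdata`.
#'
#' @param object A [fatigue_fit()] object.
#' @param newdata Matrix or data frame containing the selected feature
#'   columns; defaults to the training data.
#' @param ... Unused.
#' @return Factor of predicted labels with levels `c("pre", "post")`.
#' @export
predict.fatigue_fit <- function(object, newdata = NULL, ...) {
  X <- object$data$X[, object$selected, drop = FALSE]
  nd <- if (is.null(newdata)) X else {
    if (is.data.frame(newdata)) newdata <- as.matrix(
      newdata[, intersect(colnames(newdata), object$selected),
              drop = FALSE])
    newdata[, object$selected, drop = FALSE]
  }
  fit_predict(object$classifier, X, object$data$y, nd)
}

#' Plot an NCA weight profile and greedy accuracy path
#'
#' Left panel: the `n_top` largest NCA weights; right panel: LOSO accuracy
#' versus prefix size during greedy forward selection, with the selected
#' size marked.
#'
#' @param x A [fatigue_fit()] object.
#' @param n_top Number of weights shown.
#' @param ... Unused.
#' @export
plot.fatigue_fit <- function(x, n_top = 15, ...) {
  op <- par(mfrow = c(1, 2), mar = c(8, 4, 2, 1))
  on.exit(par(op))
  k <- seq_len(min(n_top, length(x$ranking$features)))
  barplot(x$ranking$weights[k], names.arg = x$ranking$features[k],
          las = 2, cex.names = 0.6, ylab = "NCA weight",
          main = "Feature weights")
  par(mar = c(4, 4, 2, 1))
  plot(seq_along(x$accuracy_path), x$accuracy_path, type = "b",
       xlab = "features in prefix", ylab = "LOSO accuracy",
       main = "Greedy selection", ylim = c(0, 1))
  abline(v = length(x$selected), lty = 2)
  invisible(x)
}
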