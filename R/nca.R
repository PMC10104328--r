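#' Neighborhood component analysis feature weights
#'
#' Feature-weighting NCA for binary (or multi-class) labels: per-feature
#' weights `w` parameterize the distance
#' `d(i, j) = sum_f w_f^2 |x_if - x_jf|`, and the objective is the expected
#' leave-one-out stochastic-neighbour classification accuracy
#' `F(w) = sum_i sum_{j != i, y_j = y_i} p_ij`, with softmax neighbour
#' probabilities `p_ij = exp(-d_ij) / sum_{k != i} exp(-d_ik)`, minus the
#' regularizer `lambda * sum_f w_f^2`. Optimization is gradient-based
#' (BFGS with the analytic gradient) from the all-ones start; the returned
#' weights are `|w|`, so they are non-negative and permutation-equivariant
#' in the feature columns.
#'
#' @param X Numeric n x p feature matrix (no missing values; features are
#'   expected on comparable scales, e.g. in `[0, 1]`).
#' @param y Class labels, length n.
#' @param lambda Regularization strength; default `1 / n`.
#' @param seed Integer seed (kept for interface stability; the optimizer is
#'   deterministic from its fixed start).
#' @param max_iter Maximum BFGS iterations.
#' @return Named non-negative weight vector of length p.
#' @export
#' @examples
#' sim <- simulate_feature_matrix(10, informative = 1, effect = 0.5,
#'                                n_features = 4, seed = 2)
#' w <- nca_weights(sim$X, sim$y)
#' names(which.max(w))
nca_weights <- function(X, y, lambda = NULL, seed = 0, max_iter = 100) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 4L) stop("nca_weights needs at least 4 samples", call. = FALSE)
  if (anyNA(X)) stop("X must not contain missing values", call. = FALSE)
  lambda <- lambda %||% (1 / n)
  y <- as.integer(as.factor(y))
  same <- outer(y, y, "==")
  diag(same) <- FALSE
  # |x_if - x_jf| flattened to an n^2 x p matrix, one column per feature
  Dm <- matrix(0, n * n, p)
  for (f in seq_len(p)) Dm[, f] <- abs(outer(X[, f], X[, f], "-"))
  set.seed(as.integer(seed))

  softmax_rows <- function(negd) {
    # negd: n x n matrix of -d_ij with -Inf on the diagonal
    m <- apply(negd, 1, max)
    E <- exp(negd - m)
    E / rowSums(E)
  }
  obj_grad <- function(w) {
    d <- matrix(Dm %*% (w^2), n, n)
    negd <- -d
    diag(negd) <- -Inf
    P <- softmax_rows(negd)
    pi_correct <- rowSums(P * same)
    FF <- sum(pi_correct) - lambda * sum(w^2)
    M <- P * (pi_correct - same)  # p_ij * (p_i - 1[same class])
    grad <- 2 * w * as.numeric(crossprod(as.numeric(M), Dm)) -
      2 * lambda * w
    list(value = FF, grad = grad)
  }
  if (all(Dm == 0)) {
    w <- rep(1, p)
  } else {
    fit <- optim(rep(1, p),
                 fn = function(w) -obj_grad(w)$value,
                 gr = function(w) -obj_grad(w)$grad,
                 method = "BFGS",
                 control = list(maxit = max_iter, reltol = 1e-8))
    w <- abs(fit$par)
  }
  names(w) <- colnames(X)
  w
}

#' Rank features by NCA weight
#'
#' Descending weight order; ties are broken by the canonical feature order
#' (the horse-trial feature layout when all names belong to it, otherwise
#' alphabetically), so the ranking does not depend on the column order of
#' the input matrix.
#'
#' @param weights Named non-negative weight vector.
#' @return Object of class `feature_ranking`: list with `features` (ordered
#'   names) and `weights` (in that order).
#' @export
rank_features <- function(weights) {
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  nms <- names(weights)
  if (is.null(nms)) nms <- paste0("f", seq_along(weights))
  canonical <- horse_trial_feature_names()
  tie_rank <- if (all(nms %in% canonical)) match(nms, canonical)
  else rank(nms, ties.method = "first")
  ord <- order(-weights, tie_rank)
  structure(list(features = nms[ord], weights = unname(weights[ord])),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, n = 10, ...) {
  cat("<feature_ranking> top", min(n, length(x$features)), "of",
      length(x$features), "features:\n")
  k <- seq_len(min(n, length(x$features)))
  print(setNames(round(x$weights[k], 4), x$features[k]))
  invisible(x)
}
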