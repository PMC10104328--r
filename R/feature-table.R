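#' Intra-individual min-max normalization of stride features
#'
#' For every horse and every feature, the pre- and post-trial strides are
#' pooled and mapped to `[0, 1]` by `(x - min) / (max - min)`. Normalizing
#' within horse removes inter-individual baselines so that classification
#' focuses on the pre/post contrast. A feature that is constant within a
#' horse (max equals min) is set to 0 for all of that horse's strides
#' (documented degenerate rule).
#'
#' @param stride_features Data frame from [extract_cohort_features()] (or a
#'   subset of it); must contain `horse`, `trial` and the feature columns.
#' @param feature_cols Feature column names; defaults to all of
#'   [stride_feature_names()] present.
#' @return The data frame with the feature columns normalized per horse.
#' @export
normalize_within_horse <- function(stride_features,
                                   feature_cols = NULL) {
  if (is.null(feature_cols))
    feature_cols <- intersect(stride_feature_names(),
                              names(stride_features))
  for (id in unique(stride_features$horse)) {
    sel <- stride_features$horse == id
    if (!any(stride_features$trial[sel] == "pre") ||
        !any(stride_features$trial[sel] == "post"))
      stop("both trials must be present for horse ", id, call. = FALSE)
    for (f in feature_cols) {
      x <- stride_features[sel, f]
      rng <- range(x, na.rm = TRUE)
      stride_features[sel, f] <-
        if (!is.finite(rng[1]) || rng[2] == rng[1]) 0
        else (x - rng[1]) / (rng[2] - rng[1])
    }
  }
  stride_features
}

#' Stride-to-stride variability metrics
#'
#' @param values Numeric vector (at least 2 values).
#' @param metric One of `"RMS"` (root mean square), `"CV"` (coefficient of
#'   variation, SD/mean), `"SD"` (sample standard deviation, n-1
#'   denominator), `"VAR"` (sample variance).
#' @return Scalar; `NA` for `CV` of a zero-mean vector (missing-value
#'   sentinel).
#' @export
#' @examples
#' variability(c(2, 4), "SD")   # sqrt(2)
#' variability(c(2, 4), "RMS")  # sqrt(10)
variability <- function(values, metric = c("RMS", "CV", "SD", "VAR")) {
  metric <- match.arg(metric)
  if (length(values) < 2L)
    stop("variability needs at least 2 values", call. = FALSE)
  switch(metric,
         SD = sd(values),
         VAR = var(values),
         RMS = sqrt(mean(values^2)),
         CV = {
           m <- mean(values)
           if (m == 0) NA_real_ else sd(values) / m
         })
}

#' Aggregate normalized strides to horse-trial feature vectors
#'
#' For every horse-trial the 52 feature means and 52 stride-to-stride
#' variabilities are computed, giving one 104-value vector per horse per
#' trial (columns `mean_*` then `var_*`). Strides with any missing feature
#' are excluded first; horse-trials with fewer than `min_strides` remaining
#' strides are excluded entirely (both exclusions are logged in attribute
#' `log`).
#'
#' With `sliding_window = TRUE` each horse-trial instead contributes one
#' vector per window of `window` consecutive strides (stepped by `step`),
#' mirroring per-stride sample counts; the default is one vector per
#' horse-trial.
#'
#' @param stride_features Normalized stride feature data frame.
#' @param metric Variability metric, see [variability()].
#' @param min_strides Validity floor: minimum strides per horse-trial
#'   (default 33).
#' @param gait_subset Label stored with the result (`"walk"`, `"trot"`,
#'   `"walk_trot"`).
#' @param sliding_window Produce one vector per stride window instead of one
#'   per horse-trial.
#' @param window,step Sliding-window length and step, strides.
#' @return Data frame: `horse`, `trial`, `gait_subset`, `n_strides`,
#'   `metric`, then the 104 feature columns.
#' @export
aggregate_features <- function(stride_features,
                               metric = c("RMS", "CV", "SD", "VAR"),
                               min_strides = 33,
                               gait_subset = NA_character_,
                               sliding_window = FALSE,
                               window = 33, step = 1) {
  metric <- match.arg(metric)
  fn <- intersect(stride_feature_names(), names(stride_features))
  rows <- list(); logs <- list()
  for (id in unique(stride_features$horse)) {
    for (trial in c("pre", "post")) {
      d <- stride_features[stride_features$horse == id &
                             stride_features$trial == trial, , drop = FALSE]
      fm <- as.matrix(d[, fn, drop = FALSE])
      complete <- stats::complete.cases(fm)
      n_excluded <- sum(!complete)
      fm <- fm[complete, , drop = FALSE]
      logs[[length(logs) + 1L]] <- data.frame(
        horse = id, trial = trial, n_strides = nrow(fm),
        n_excluded_strides = n_excluded,
        excluded = nrow(fm) < min_strides, stringsAsFactors = FALSE)
      if (nrow(fm) < min_strides) next
      if (sliding_window && nrow(fm) < window) next
      starts <- if (sliding_window) {
        seq(1L, nrow(fm) - window + 1L, by = step)
      } else 1L
      len <- if (sliding_window) window else nrow(fm)
      for (s0 in starts) {
        block <- fm[s0:(s0 + len - 1L), , drop = FALSE]
        mu <- colMeans(block)
        vb <- apply(block, 2, variability, metric = metric)
        row <- c(mu, vb)
        names(row) <- c(paste0("mean_", fn), paste0("var_", fn))
        rows[[length(rows) + 1L]] <- data.frame(
          horse = id, trial = trial, gait_subset = gait_subset,
          n_strides = nrow(block), metric = metric, as.list(row),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(out)) {
    out <- data.frame(horse = character(0), trial = character(0),
                      gait_subset = character(0), n_strides = integer(0),
                      metric = character(0))
  }
  rownames(out) <- NULL
  attr(out, "log") <- do.call(rbind, logs)
  out
}
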