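#' Assign SET intensity from group-mean maximum plasma lactate
#'
#' The anaerobic-threshold convention for Warmblood sport horses: a group
#' whose mean maximum plasma lactate during the exercise test reaches
#' 4.0 mmol/L or more performed a high-intensity test, below that a
#' low-intensity test (the boundary value itself is classified high).
#'
#' @param group_mean_max_la Mean maximum plasma lactate, mmol/L (>= 0).
#' @param cutoff Cut-off, mmol/L (default 4.0).
#' @return `"high"` or `"low"`.
#' @export
#' @examples
#' assign_intensity(4.04)  # "high"
#' assign_intensity(1.62)  # "low"
assign_intensity <- function(group_mean_max_la, cutoff = 4.0) {
  if (any(group_mean_max_la < 0))
    stop("lactate concentration must be non-negative", call. = FALSE)
  ifelse(group_mean_max_la >= cutoff, "high", "low")
}

#' Pipeline configuration
#'
#' Collects every tunable of the full analysis in one structure.
#'
#' @param metrics Variability metrics to try (inner loop).
#' @param classifiers Classifier menu (innermost loop).
#' @param min_strides Validity floor per horse-trial.
#' @param lambda NCA regularization (`NULL` = `1/n`).
#' @param la_cutoff Lactate cut-off, mmol/L.
#' @param filter_order,filter_cutoff Butterworth settings.
#' @param detector_theta Hoof-event detector threshold.
#' @param mad_k Stride-duration outlier multiplier.
#' @param stride_length_offset Speed-model offset, metres.
#' @param force_include Force speed/duration features into classifiers.
#' @param sliding_window,window,step Sliding-window aggregation controls.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(metrics = c("RMS", "CV", "SD", "VAR"),
                            classifiers = c("svm", "knn", "tree", "nb",
                                            "logistic"),
                            min_strides = 33, lambda = NULL,
                            la_cutoff = 4.0, filter_order = 4,
                            filter_cutoff = 30, detector_theta = 0.15,
                            mad_k = 3, stride_length_offset = 0,
                            force_include = FALSE,
                            sliding_window = FALSE, window = 33, step = 1) {
  structure(list(metrics = match.arg(metrics, several.ok = TRUE),
                 classifiers = match.arg(classifiers, CLASSIFIERS,
                                         several.ok = TRUE),
                 min_strides = min_strides, lambda = lambda,
                 la_cutoff = la_cutoff, filter_order = filter_order,
                 filter_cutoff = filter_cutoff,
                 detector_theta = detector_theta, mad_k = mad_k,
                 stride_length_offset = stride_length_offset,
                 force_include = force_include,
                 sliding_window = sliding_window, window = window,
                 step = step),
            class = "pipeline_config")
}

# dataset membership: all horses; the high-intensity arm; the low-intensity
# arm, with arm intensity confirmed from the arm's mean maximum lactate
dataset_members <- function(horses, cutoff = 4.0) {
  arm_mean <- tapply(horses$max_lactate, horses$arm, mean)
  arm_label <- assign_intensity(arm_mean, cutoff)
  list(all = horses$horse,
       high = horses$horse[arm_label[horses$arm] == "high"],
       low = horses$horse[arm_label[horses$arm] == "low"])
}

#' Run the full fatigue-indicator pipeline
#'
#' Orchestrates the nested loops of the analysis: for each of three datasets
#' (all horses, high-intensity arm, low-intensity arm) and three gait
#' subsets (walk, trot, walk+trot = union of both gaits of the same
#' horses), strides are normalized within horse, aggregated per horse-trial
#' under each variability metric, ranked by NCA, and classified through
#' greedy forward selection with leave-one-subject-out cross-validation for
#' each classifier; the best-accuracy (metric, classifier) combination is
#' kept per cell. Deterministic for a given cohort and seed.
#'
#' @param cohort An [generate_cohort()] cohort (or any object with the same
#'   structure).
#' @param config A [pipeline_config()].
#' @param seed Integer seed for the NCA optimizer.
#' @param stride_features Optional precomputed output of
#'   [extract_cohort_features()] (skips re-extraction).
#' @return Object of class `fatigue_report`: `table` (9-row data frame, one
#'   per dataset x gait-subset cell) and `cells` (per-cell details:
#'   selected features, weights, folds, forced-feature comparison).
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), seed = 1,
                         stride_features = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(stride_features))
    stride_features <- extract_cohort_features(
      cohort, order = config$filter_order, cutoff = config$filter_cutoff,
      theta = config$detector_theta, mad_k = config$mad_k,
      stride_length_offset = config$stride_length_offset)
  members <- dataset_members(cohort$horses, config$la_cutoff)
  subsets <- list(walk = "walk", trot = "trot",
                  walk_trot = c("walk", "trot"))
  rows <- list(); cells <- list()
  for (ds in names(members)) {
    for (sb in names(subsets)) {
      cell_id <- paste(ds, sb, sep = ".")
      gaits <- subsets[[sb]]
      d <- stride_features[stride_features$horse %in% members[[ds]] &
                             stride_features$gait %in% gaits, ,
                           drop = FALSE]
      have_both <- length(unique(d$gait)) == length(gaits)
      ok_ids <- if (nrow(d)) {
        tab <- table(d$horse, d$trial)
        rownames(tab)[rowSums(tab > 0) == 2L]
      } else character(0)
      if (!have_both || length(ok_ids) < 2L) {
        rows[[cell_id]] <- report_row(ds, sb, status = "not_evaluable")
        cells[[cell_id]] <- list(status = "not_evaluable")
        next
      }
      d <- d[d$horse %in% ok_ids, , drop = FALSE]
      d <- normalize_within_horse(d)
      best <- NULL
      for (metric in config$metrics) {
        agg <- aggregate_features(d, metric = metric,
                                  min_strides = config$min_strides,
                                  gait_subset = sb,
                                  sliding_window = config$sliding_window,
                                  window = config$window,
                                  step = config$step)
        keep <- table(agg$horse, agg$trial)
        valid <- rownames(keep)[rowSums(keep > 0) == 2L]
        agg <- agg[agg$horse %in% valid, , drop = FALSE]
        if (length(unique(agg$horse)) < 2L) next
        fcols <- intersect(horse_trial_feature_names(), names(agg))
        X <- as.matrix(agg[, fcols, drop = FALSE])
        cc <- stats::complete.cases(X)
        X <- X[cc, , drop = FALSE]
        yv <- factor(agg$trial[cc], levels = c("pre", "post"))
        hid <- agg$horse[cc]
        if (length(unique(hid)) < 2L) next
        w <- nca_weights(X, yv, lambda = config$lambda, seed = seed)
        ranking <- rank_features(w)
        feats <- ranking$features
        if (config$force_include) {
          forced <- intersect(paste0("mean_", c("speed", "stride_duration",
                                                "stance_duration",
                                                "swing_duration")), fcols)
          feats <- c(forced, setdiff(feats, forced))
        }
        for (cl in config$classifiers) {
          sel <- greedy_forward_selection(feats, X, yv, hid, cl)
          cand <- list(metric = metric, classifier = cl,
                       selected = sel$selected, result = sel$result,
                       accuracy_path = sel$accuracy_path,
                       weights = w, agg = agg[cc, , drop = FALSE])
          acc_new <- sel$result$metrics[["accuracy"]]
          if (is.null(best) || (is.finite(acc_new) &&
                                acc_new > best$result$metrics[["accuracy"]]))
            best <- cand
        }
      }
      if (is.null(best)) {
        rows[[cell_id]] <- report_row(ds, sb, status = "not_evaluable")
        cells[[cell_id]] <- list(status = "not_evaluable")
        next
      }
      f <- best$result$folds
      strides <- tapply(best$agg$n_strides,
                        factor(best$agg$trial, c("pre", "post")), sum)
      forced <- paste0("mean_", c("speed", "stride_duration",
                                  "stance_duration", "swing_duration"))
      forced <- intersect(forced, names(best$agg))
      Xa <- as.matrix(best$agg[, forced, drop = FALSE])
      forced_tab <- data.frame(
        feature = forced,
        mean_pre = colMeans(Xa[best$agg$trial == "pre", , drop = FALSE]),
        mean_post = colMeans(Xa[best$agg$trial == "post", , drop = FALSE]),
        row.names = NULL, stringsAsFactors = FALSE)
      rows[[cell_id]] <- report_row(
        ds, sb, status = "ok", n_horses = length(unique(best$agg$horse)),
        metric = best$metric, classifier = best$classifier,
        n_selected = length(best$selected),
        selected = paste(best$selected, collapse = ";"),
        accuracy_mean = mean(f$accuracy, na.rm = TRUE),
        accuracy_sd = sd(f$accuracy, na.rm = TRUE),
        sensitivity_mean = mean(f$sensitivity, na.rm = TRUE),
        sensitivity_sd = sd(f$sensitivity, na.rm = TRUE),
        specificity_mean = mean(f$specificity, na.rm = TRUE),
        specificity_sd = sd(f$specificity, na.rm = TRUE),
        accuracy_pooled = unname(best$result$metrics["accuracy"]),
        strides_pre = unname(strides["pre"]),
        strides_post = unname(strides["post"]))
      cells[[cell_id]] <- list(status = "ok", metric = best$metric,
                               classifier = best$classifier,
                               selected = best$selected,
                               weights = best$weights,
                               accuracy_path = best$accuracy_path,
                               counts = best$result$counts,
                               folds = f, forced_features = forced_tab)
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(table = table, cells = cells, seed = seed,
                 config = config),
            class = "fatigue_report")
}

report_row <- function(dataset, gait_subset, status,
                       n_horses = NA_integer_, metric = NA_character_,
                       classifier = NA_character_,
                       n_selected = NA_integer_, selected = NA_character_,
                       accuracy_mean = NA_real_, accuracy_sd = NA_real_,
                       sensitivity_mean = NA_real_,
                       sensitivity_sd = NA_real_,
                       specificity_mean = NA_real_,
                       specificity_sd = NA_real_,
                       accuracy_pooled = NA_real_,
                       strides_pre = NA_integer_,
                       strides_post = NA_integer_) {
  data.frame(dataset = dataset, gait_subset = gait_subset, status = status,
             n_horses = n_horses, metric = metric, classifier = classifier,
             n_selected = n_selected, selected = selected,
             accuracy_mean = accuracy_mean, accuracy_sd = accuracy_sd,
             sensitivity_mean = sensitivity_mean,
             sensitivity_sd = sensitivity_sd,
             specificity_mean = specificity_mean,
             specificity_sd = specificity_sd,
             accuracy_pooled = accuracy_pooled, strides_pre = strides_pre,
             strides_post = strides_post, stringsAsFactors = FALSE)
}

#' @export
print.fatigue_report <- function(x, ...) {
  cat("<fatigue_report> best (variability metric, classifier) per cell\n")
  t <- x$table
  for (i in seq_len(nrow(t))) {
    if (t$status[i] != "ok") {
      cat(sprintf("  %-5s %-10s not evaluable\n", t$dataset[i],
                  t$gait_subset[i]))
    } else {
      cat(sprintf(
        "  %-5s %-10s %3s/%-8s acc %3.0f+/-%2.0f%%  sens %3.0f%%  spec %3.0f%%  (%d feats)\n",
        t$dataset[i], t$gait_subset[i], t$metric[i], t$classifier[i],
        100 * t$accuracy_mean[i], 100 * t$accuracy_sd[i],
        100 * t$sensitivity_mean[i], 100 * t$specificity_mean[i],
        t$n_selected[i]))
    }
  }
  invisible(x)
}

#' Write / read a classification report
#'
#' `write_report` writes the 9-cell table as a machine-readable CSV and a
#' human-readable fixed-width text table; `read_report` reads the CSV back.
#'
#' @param report A [run_pipeline()] report.
#' @param path Output path without extension; `<path>.csv` and `<path>.txt`
#'   are written.
#' @return `write_report` returns the paths invisibly; `read_report`
#'   returns the table data frame.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "fatigue_report"))
  csv <- paste0(path, ".csv"); txt <- paste0(path, ".txt")
  write.csv(report$table, csv, row.names = FALSE)
  con <- file(txt, "w")
  on.exit(close(con))
  writeLines("Fatigue classification report (one row per dataset x gait subset)",
             con)
  writeLines(utils::capture.output(print(report)), con)
  t <- report$table
  for (i in which(t$status == "ok")) {
    writeLines(sprintf("%s / %s: features = %s; strides pre/post = %s/%s",
                       t$dataset[i], t$gait_subset[i], t$selected[i],
                       t$strides_pre[i], t$strides_post[i]), con)
  }
  invisible(c(csv = csv, txt = txt))
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  read.csv(paste0(path, ".csv"), stringsAsFactors = FALSE)
}
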