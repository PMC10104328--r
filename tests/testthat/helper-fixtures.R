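# shared fixtures, built once per test run and memoized

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_env))
    assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# noise-free effect configuration (no fatigue effects either)
clean_effects <- function(inter_horse_cv = 0, ...) {
  fatigue_effects(noise_sd_accel = 0, noise_sd_gyro = 0,
                  inter_horse_cv = inter_horse_cv, stride_cv = 0, ...)
}

# small deterministic zero-noise cohort, both gaits
tiny_cohort <- function() {
  fixture("tiny_cohort", function() {
    generate_cohort(3, 6, effects = clean_effects(inter_horse_cv = 0.05),
                    seed = 42, gaits = c("walk", "trot"))
  })
}

tiny_features <- function() {
  fixture("tiny_features", function() extract_cohort_features(tiny_cohort()))
}

# one preprocessed recording of the tiny cohort
tiny_preprocessed <- function() {
  fixture("tiny_preprocessed", function() {
    equifatigue:::preprocess_recording(tiny_cohort()$recordings$H01$pre$walk)
  })
}

# match each extracted stride to its ground-truth stride by hoof-on time;
# returns aligned matrices of extracted and true feature values
align_truth <- function(cohort, stride_features) {
  fn <- stride_feature_names()
  ev <- cohort$events
  key_gt <- paste(ev$horse, ev$trial, ev$gait)
  key_sf <- paste(stride_features$horse, stride_features$trial,
                  stride_features$gait)
  truth <- matrix(NA_real_, nrow(stride_features), length(fn),
                  dimnames = list(NULL, fn))
  timing_err <- numeric(nrow(stride_features))
  for (i in seq_len(nrow(stride_features))) {
    sel <- which(key_gt == key_sf[i])
    j <- sel[which.min(abs(ev$hoof_on_s[sel] - stride_features$hoof_on_s[i]))]
    truth[i, ] <- as.numeric(cohort$stride_truth[j, fn])
    timing_err[i] <- abs(ev$hoof_on_s[j] - stride_features$hoof_on_s[i])
  }
  list(extracted = as.matrix(stride_features[, fn]), truth = truth,
       timing_err_s = timing_err)
}
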