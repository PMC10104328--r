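#' Generate a synthetic IMU cohort with ground truth
#'
#' Simulates a cohort of horses measured at walk and/or trot before (`pre`)
#' and after (`post`) a standardized exercise test. Each horse receives a
#' baseline parameter set drawn multiplicatively around the configured gait
#' parameters (`inter_horse_cv`); the post-trial parameters are the pre-trial
#' baseline with the configured fatigue effects applied exactly
#' (multiplicative, before any noise). Every stride is generated from
#' stride-level jittered parameters (`stride_cv`) on its own sample grid and
#' concatenated; sensor noise is added per sample. Ground truth (hoof events
#' and the true per-stride value of all 52 features) is recorded for every
#' stride.
#'
#' Margin strides are prepended and appended to each recording
#' (`pad_strides`, default 2) so that edge strides whose events cannot be
#' detected, or strides lost to event-timing jitter under noise, do not eat
#' into the requested stride count.
#'
#' Each horse belongs to an exercise-intensity arm (`high`/`low`, mirroring
#' disciplines with high- and low-intensity tests) and draws a maximum plasma
#' lactate from the arm's normal distribution (defaults: high 4.04 (SD 1.80)
#' mmol/L, low 1.62 (SD 0.57) mmol/L).
#'
#' @param n_horses Number of horses (>= 2).
#' @param strides_per_trial Usable strides per trial per gait (>= 2).
#' @param effects A [fatigue_effects()] configuration.
#' @param seed Integer seed; identical seed + configuration give an identical
#'   cohort.
#' @param gaits Character subset of `c("walk", "trot")`.
#' @param rate Sampling rate, Hz.
#' @param base_params Named list of [gait_params()] per gait.
#' @param pad_strides Margin strides added at each end of a recording.
#' @param fraction_high Fraction of horses in the high-intensity arm.
#' @param lactate_high,lactate_low `c(mean, sd)` of maximum plasma lactate
#'   (mmol/L) per arm.
#' @return Object of class `imu_cohort`: `horses` (id, arm, max lactate),
#'   `recordings[[horse]][[trial]][[gait]]` (named list of 7
#'   [sensor_stream()]s), `events` (ground-truth hoof-on/off table),
#'   `stride_truth` (per-stride true feature values), `trial_truth` (exact
#'   per-trial parameter truth, before stride jitter), `seed`, `config`.
#' @export
#' @examples
#' co <- generate_cohort(2, 4, seed = 1, gaits = "walk")
#' co$horses
generate_cohort <- function(n_horses, strides_per_trial,
                            effects = fatigue_effects(), seed = 1,
                            gaits = c("walk", "trot"), rate = 200,
                            base_params = NULL, pad_strides = 2,
                            fraction_high = 44 / 60,
                            lactate_high = c(4.04, 1.80),
                            lactate_low = c(1.62, 0.57)) {
  if (n_horses < 2) stop("n_horses must be >= 2", call. = FALSE)
  if (strides_per_trial < 2)
    stop("strides_per_trial must be >= 2", call. = FALSE)
  gaits <- match.arg(gaits, c("walk", "trot"), several.ok = TRUE)
  if (is.null(base_params))
    base_params <- sapply(gaits, gait_params, simplify = FALSE)
  set.seed(as.integer(seed))

  ids <- sprintf("H%02d", seq_len(n_horses))
  n_high <- round(n_horses * fraction_high)
  arm <- rep(c("high", "low"), c(n_high, n_horses - n_high))
  la <- ifelse(arm == "high",
               rnorm(n_horses, lactate_high[1], lactate_high[2]),
               rnorm(n_horses, lactate_low[1], lactate_low[2]))
  la <- pmax(la, 0.1)
  horses <- data.frame(horse = ids, arm = arm, max_lactate = la,
                       stringsAsFactors = FALSE)

  n_str <- strides_per_trial + 2L * pad_strides
  recordings <- list()
  ev_rows <- list(); st_rows <- list(); tt_rows <- list()
  fn <- stride_feature_names()

  for (h in seq_len(n_horses)) {
    id <- ids[h]
    recordings[[id]] <- list(pre = list(), post = list())
    for (g in gaits) {
      baseline <- jitter_params(base_params[[g]], effects$inter_horse_cv)
      trial_params <- list(pre = baseline,
                           post = apply_effects(baseline, effects))
      for (trial in c("pre", "post")) {
        tp <- trial_params[[trial]]
        tt_rows[[length(tt_rows) + 1L]] <- data.frame(
          horse = id, trial = trial, gait = g,
          as.list(params_to_truth(tp)), stringsAsFactors = FALSE)
        acc <- lapply(ALL_LOCATIONS, function(l) vector("list", n_str))
        gyr <- acc
        names(acc) <- names(gyr) <- ALL_LOCATIONS
        t0 <- 0
        for (s in seq_len(n_str)) {
          sp <- jitter_params(tp, effects$stride_cv)
          kin <- generate_stride_kinematics(sp, rate)
          for (l in ALL_LOCATIONS) {
            acc[[l]][[s]] <- kin$locations[[l]]$acc / G0
            gyr[[l]][[s]] <- kin$locations[[l]]$angvel
          }
          truth <- params_to_truth(sp)
          truth["stride_duration"] <- kin$stride_duration
          truth["stance_duration"] <- kin$duty_factor * kin$stride_duration
          truth["swing_duration"] <- truth["stride_duration"] -
            truth["stance_duration"]
          truth["speed"] <- truth["disp_long_sacrum"] /
            truth["stride_duration"]
          ev_rows[[length(ev_rows) + 1L]] <- data.frame(
            horse = id, trial = trial, gait = g, stride_index = s,
            hoof_on_s = t0,
            hoof_off_s = t0 + truth["stance_duration"],
            is_pad = s <= pad_strides || s > n_str - pad_strides,
            stringsAsFactors = FALSE)
          st_rows[[length(st_rows) + 1L]] <- data.frame(
            horse = id, trial = trial, gait = g, stride_index = s,
            is_pad = s <= pad_strides || s > n_str - pad_strides,
            as.list(truth), stringsAsFactors = FALSE)
          t0 <- t0 + kin$stride_duration
        }
        streams <- lapply(ALL_LOCATIONS, function(l) {
          a <- do.call(rbind, acc[[l]])
          w <- do.call(rbind, gyr[[l]])
          n <- nrow(a)
          if (effects$noise_sd_accel > 0)
            a <- a + matrix(rnorm(3 * n, sd = effects$noise_sd_accel), n, 3)
          if (effects$noise_sd_gyro > 0)
            w <- w + matrix(rnorm(3 * n, sd = effects$noise_sd_gyro), n, 3)
          sensor_stream(l, rate, a, w)
        })
        names(streams) <- ALL_LOCATIONS
        recordings[[id]][[trial]][[g]] <- list(horse = id, trial = trial,
                                               gait = g, streams = streams)
      }
    }
  }
  events <- do.call(rbind, ev_rows); rownames(events) <- NULL
  stride_truth <- do.call(rbind, st_rows); rownames(stride_truth) <- NULL
  trial_truth <- do.call(rbind, tt_rows); rownames(trial_truth) <- NULL
  names(stride_truth)[-(1:5)] <- fn
  names(trial_truth)[-(1:3)] <- fn
  structure(list(horses = horses, recordings = recordings, events = events,
                 stride_truth = stride_truth, trial_truth = trial_truth,
                 seed = seed,
                 config = list(n_horses = n_horses,
                               strides_per_trial = strides_per_trial,
                               effects = effects, gaits = gaits, rate = rate,
                               pad_strides = pad_strides,
                               fraction_high = fraction_high)),
            class = "imu_cohort")
}

#' @export
print.imu_cohort <- function(x, ...) {
  cat(sprintf(
    "<imu_cohort> %d horses (%d high / %d low intensity), gaits: %s\n",
    nrow(x$horses), sum(x$horses$arm == "high"), sum(x$horses$arm == "low"),
    paste(x$config$gaits, collapse = ", ")))
  cat(sprintf("  %d strides per trial (+%d margin each end), %g Hz, seed %s\n",
              x$config$strides_per_trial, x$config$pad_strides,
              x$config$rate, format(x$seed)))
  invisible(x)
}

#' Simulate a horse-trial feature matrix directly
#'
#' Bypasses signal generation: draws a 104-column (by default) horse-trial
#' feature matrix in which a chosen set of columns carries a pre-to-post
#' shift of `effect` on top of i.i.d. Gaussian stride-level noise of SD
#' `noise_sd`, and all remaining columns are pure noise. Used to study
#' feature-selection behaviour under a known signal-to-noise ratio.
#'
#' @param n_horses Number of horses; each contributes one `pre` and one
#'   `post` row.
#' @param informative Names or indices of the informative columns.
#' @param effect Mean pre-to-post difference injected in the informative
#'   columns.
#' @param noise_sd SD of the noise in every column.
#' @param n_features Total number of columns.
#' @param seed Integer seed.
#' @return List with matrix `X` (2 * n_horses rows), factor `y` with levels
#'   `pre`/`post`, and `horse_ids`.
#' @export
simulate_feature_matrix <- function(n_horses, informative = 1:3,
                                    effect = 0.3, noise_sd = 0.1,
                                    n_features = 104, seed = 1) {
  set.seed(as.integer(seed))
  n <- 2L * n_horses
  X <- matrix(rnorm(n * n_features, mean = 0.5, sd = noise_sd),
              n, n_features)
  colnames(X) <- horse_trial_feature_names()[seq_len(n_features)]
  y <- factor(rep(c("pre", "post"), n_horses), levels = c("pre", "post"))
  if (is.character(informative))
    informative <- match(informative, colnames(X))
  X[y == "post", informative] <- X[y == "post", informative] + effect
  X[] <- pmin(pmax(X, 0), 1.5)
  list(X = X, y = y,
       horse_ids = rep(sprintf("H%02d", seq_len(n_horses)), each = 2))
}
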