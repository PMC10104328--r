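#' Gait-event durations of one stride
#'
#' Stride duration is the time between consecutive right-front hoof-ons,
#' stance the hoof-on to hoof-off interval, and swing the remainder, so
#' stance + swing equals stride exactly by construction.
#'
#' @param window One row of a [segment_strides()] data frame (or any list
#'   with `hoof_on_s`, `hoof_off_s`, `next_on_s`).
#' @return Named numeric: `stride_duration`, `stance_duration`,
#'   `swing_duration` (seconds). All `NA` (stride flagged invalid) when
#'   hoof-off lies outside `[hoof_on, next_on)`.
#' @export
#' @examples
#' gait_event_durations(list(hoof_on_s = 0, hoof_off_s = 0.7, next_on_s = 1))
gait_event_durations <- function(window) {
  on <- window$hoof_on_s; off <- window$hoof_off_s; nxt <- window$next_on_s
  if (is.na(off) || off < on || off >= nxt)
    return(c(stride_duration = NA_real_, stance_duration = NA_real_,
             swing_duration = NA_real_))
  stride <- nxt - on
  stance <- off - on
  c(stride_duration = stride, stance_duration = stance,
    swing_duration = stride - stance)
}

#' Angular range of motion from one stride of angular velocity
#'
#' The angle is the cumulative trapezoidal integral of the mean-removed
#' angular-velocity channel (mean removal discards the constant-rate
#' component so the per-stride angle closes on itself); the range of motion
#' is its maximum minus minimum.
#'
#' @param gyr_channel Numeric vector, one stride of one gyroscope channel in
#'   deg/s.
#' @param rate Sampling rate, Hz.
#' @return Range of motion in degrees (>= 0).
#' @export
angular_rom <- function(gyr_channel, rate) {
  if (!length(gyr_channel)) stop("empty series", call. = FALSE)
  ang <- cumtrapz_u(gyr_channel - mean(gyr_channel), 1 / rate)
  max(ang) - min(ang)
}

#' Cyclic double integration of acceleration to displacement
#'
#' Converts one stride of an acceleration channel from g to m/s^2, removes
#' the stride mean (cyclic constraint: zero net velocity change over the
#' periodically continued stride), integrates to velocity, removes the
#' velocity mean (which removes the linear drift of the displacement),
#' integrates to displacement and centres it. The stride window is treated
#' as one period of a cyclic signal sampled half-open, so the displacement
#' closes exactly at the wrap-around point one sample step past the window:
#' `d[1] == d[n] + dt * (v[n] + v[1]) / 2` to machine precision.
#'
#' @param acc_channel Numeric vector, one stride of acceleration in g.
#' @param rate Sampling rate, Hz.
#' @return Displacement series in metres (mean-centred, cyclic).
#' @export
cyclic_displacement <- function(acc_channel, rate) {
  if (!length(acc_channel)) stop("empty series", call. = FALSE)
  dt <- 1 / rate
  a <- acc_channel * G0
  a <- a - mean(a)
  v <- cumtrapz_u(a, dt)
  v <- v - mean(v)
  d <- cumtrapz_u(v, dt)
  d - mean(d)
}

#' Displacement range of motion
#'
#' @param disp Displacement series, metres.
#' @return `max(disp) - min(disp)` (>= 0).
#' @export
displacement_rom <- function(disp) {
  if (!length(disp)) stop("empty series", call. = FALSE)
  max(disp) - min(disp)
}

# circular local extrema of a cyclic series (last sample assumed to repeat
# the first; ties resolved towards the left neighbour)
circular_extrema <- function(x) {
  n <- length(x)
  if (n >= 2L && x[n] == x[1]) { x <- x[-n]; n <- n - 1L }
  if (n < 3L) return(list(max = numeric(0), min = numeric(0)))
  prv <- x[c(n, 1:(n - 1L))]
  nxt <- x[c(2:n, 1L)]
  list(max = x[x > prv & x >= nxt], min = x[x < prv & x <= nxt])
}

#' Vertical-displacement symmetry indices MaxDiff and MinDiff
#'
#' Within one stride the trunk (and head) vertical displacement shows two
#' peaks and two troughs. MaxDiff is the absolute difference between the two
#' largest local maxima, MinDiff between the two smallest local minima; both
#' are movement-(a)symmetry indices, zero for perfectly symmetric motion.
#'
#' @param vertical_disp One stride of vertical displacement, metres
#'   (cyclic; the series is analysed circularly).
#' @return Named numeric `c(maxdiff, mindiff)`, metres; both 0 for a
#'   constant (motionless) series, `NA` (missing-value sentinel) when the
#'   series moves but fewer than two maxima or minima exist.
#' @export
maxdiff_mindiff <- function(vertical_disp) {
  if (length(vertical_disp) &&
      max(vertical_disp) == min(vertical_disp))
    return(c(maxdiff = 0, mindiff = 0))
  ex <- circular_extrema(vertical_disp)
  maxdiff <- if (length(ex$max) >= 2L) {
    p <- sort(ex$max, decreasing = TRUE)[1:2]
    abs(p[1] - p[2])
  } else NA_real_
  mindiff <- if (length(ex$min) >= 2L) {
    q <- sort(ex$min)[1:2]
    abs(q[1] - q[2])
  } else NA_real_
  c(maxdiff = maxdiff, mindiff = mindiff)
}

#' Stride speed estimate from sacrum longitudinal displacement
#'
#' Simplified displacement-based speed model: the per-stride advance is
#' taken as the sacrum longitudinal cyclic-displacement range plus a
#' configurable constant stride-length offset, divided by stride duration.
#' The definition is deliberately simple and pluggable; it is monotone in
#' true speed whenever the longitudinal excursion scales with stride length.
#'
#' @param sacrum_stream The (filtered) sacrum [sensor_stream()].
#' @param window One stride window row (needs `start`, `end`, `hoof_on_s`,
#'   `next_on_s`).
#' @param stride_length_offset Constant added to the displacement range,
#'   metres.
#' @return Speed in m/s.
#' @export
estimate_speed <- function(sacrum_stream, window, stride_length_offset = 0) {
  dur <- window$next_on_s - window$hoof_on_s
  if (is.na(dur) || dur <= 0)
    stop("stride duration must be positive", call. = FALSE)
  idx <- window$start:(window$end - 1L)
  d <- cyclic_displacement(sacrum_stream$acc[idx, "x"], sacrum_stream$rate)
  (displacement_rom(d) + stride_length_offset) / dur
}

#' Extract the 52 per-stride biomechanical features
#'
#' Computes, for one stride window over the seven filtered sensor streams:
#' gait-event durations (3), speed (1), MaxDiff and MinDiff of sacrum,
#' withers and poll vertical displacement (6), limb angular ranges of motion
#' about the protraction/retraction, abduction/adduction and
#' internal/external axes (12), trunk/poll roll, pitch and yaw ranges of
#' motion (9), and longitudinal, mediolateral and vertical displacement
#' ranges of all seven locations (21).
#'
#' @param streams Named list of the seven filtered [sensor_stream()]s.
#' @param window One stride window row from [segment_strides()].
#' @param stride_length_offset Passed to [estimate_speed()].
#' @return Named numeric vector of length 52 in [stride_feature_names()]
#'   order. MaxDiff/MinDiff may be `NA` when the peak structure is missing.
#' @export
extract_stride_features <- function(streams, window,
                                    stride_length_offset = 0) {
  missing_loc <- setdiff(ALL_LOCATIONS, names(streams))
  if (length(missing_loc))
    stop("missing sensor location(s): ", paste(missing_loc, collapse = ", "),
         call. = FALSE)
  rate <- streams[[1]]$rate
  idx <- window$start:(window$end - 1L)
  v <- setNames(numeric(52), stride_feature_names())
  v[c("stride_duration", "stance_duration", "swing_duration")] <-
    gait_event_durations(window)
  v["speed"] <- estimate_speed(streams$sacrum, window, stride_length_offset)
  gyro_cols <- c("x", "y", "z")
  for (loc in TRUNK_LOCATIONS) {
    st <- streams[[loc]]
    dz <- cyclic_displacement(st$acc[idx, "z"], rate)
    md <- maxdiff_mindiff(dz)
    v[paste0("maxdiff_", loc)] <- md["maxdiff"]
    v[paste0("mindiff_", loc)] <- md["mindiff"]
    for (k in 1:3) {
      ax <- c("roll", "pitch", "yaw")[k]
      v[paste0(ax, "_rom_", loc)] <- angular_rom(st$gyr[idx, gyro_cols[k]],
                                                 rate)
    }
    v[paste0("disp_vert_", loc)] <- displacement_rom(dz)
  }
  for (loc in LIMB_LOCATIONS) {
    st <- streams[[loc]]
    v[paste0("introt_rom_", loc)] <- angular_rom(st$gyr[idx, "x"], rate)
    v[paste0("abdadd_rom_", loc)] <- angular_rom(st$gyr[idx, "y"], rate)
    v[paste0("proret_rom_", loc)] <- angular_rom(st$gyr[idx, "z"], rate)
  }
  for (loc in ALL_LOCATIONS) {
    st <- streams[[loc]]
    v[paste0("disp_long_", loc)] <-
      displacement_rom(cyclic_displacement(st$acc[idx, "x"], rate))
    v[paste0("disp_med_", loc)] <-
      displacement_rom(cyclic_displacement(st$acc[idx, "y"], rate))
    if (loc %in% LIMB_LOCATIONS)
      v[paste0("disp_vert_", loc)] <-
        displacement_rom(cyclic_displacement(st$acc[idx, "z"], rate))
  }
  v
}

#' Run preprocessing and feature extraction over a whole cohort
#'
#' Filters every recording, detects right-front hoof events, windows the
#' recording into strides and extracts the 52 features per stride.
#'
#' @param cohort An [generate_cohort()] object.
#' @param order,cutoff Butterworth filter settings.
#' @param theta Hoof-event detector threshold.
#' @param mad_k Stride-duration outlier multiplier for [segment_strides()].
#' @param stride_length_offset Passed to [estimate_speed()].
#' @return Data frame with columns `horse`, `trial`, `gait`, `stride_index`,
#'   `hoof_on_s` and the 52 features; attribute `log` holds per-recording
#'   stride and drop counts.
#' @export
extract_cohort_features <- function(cohort, order = 4, cutoff = 30,
                                    theta = 0.15, mad_k = 3,
                                    stride_length_offset = 0) {
  stopifnot(inherits(cohort, "imu_cohort"))
  rows <- list(); logs <- list()
  for (id in names(cohort$recordings)) {
    for (trial in names(cohort$recordings[[id]])) {
      for (g in names(cohort$recordings[[id]][[trial]])) {
        rec <- cohort$recordings[[id]][[trial]][[g]]
        pp <- preprocess_recording(rec, order = order, cutoff = cutoff,
                                   theta = theta, mad_k = mad_k)
        w <- pp$windows
        logs[[length(logs) + 1L]] <- data.frame(
          horse = id, trial = trial, gait = g, n_strides = nrow(w),
          n_dropped = attr(w, "n_dropped") %||% 0L)
        if (!nrow(w)) next
        fm <- matrix(NA_real_, nrow(w), 52,
                     dimnames = list(NULL, stride_feature_names()))
        for (i in seq_len(nrow(w)))
          fm[i, ] <- extract_stride_features(
            pp$streams, w[i, ], stride_length_offset = stride_length_offset)
        rows[[length(rows) + 1L]] <- data.frame(
          horse = id, trial = trial, gait = g,
          stride_index = w$stride_index, hoof_on_s = w$hoof_on_s,
          fm, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "log") <- do.call(rbind, logs)
  out
}
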