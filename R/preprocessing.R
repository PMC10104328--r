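#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass filter forward and backward
#' (zero phase, so event timings are not shifted; the effective magnitude
#' response is the squared single-pass response) to all six channels of a
#' sensor stream.
#'
#' @param stream A [sensor_stream()].
#' @param order Filter order (default 4).
#' @param cutoff Cut-off frequency in Hz (default 30); must be below the
#'   Nyquist frequency.
#' @return A filtered [sensor_stream()] of identical length.
#' @export
lowpass <- function(stream, order = 4, cutoff = 30) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (cutoff >= stream$rate / 2)
    stop("cutoff must be below the Nyquist frequency (rate/2)",
         call. = FALSE)
  bf <- signal::butter(order, cutoff / (stream$rate / 2), type = "low")
  # filter about the channel mean so the DC level passes exactly and
  # start-up transients act only on the oscillatory part
  filt <- function(m) apply(m, 2, function(ch) {
    mu <- mean(ch)
    signal::filtfilt(bf, ch - mu) + mu
  })
  sensor_stream(stream$location, stream$rate, filt(stream$acc),
                filt(stream$gyr))
}

# centred moving average, length-preserving
smooth_ma <- function(x, width) {
  if (width <= 1L) return(x)
  k <- rep(1 / width, width)
  y <- stats::filter(x, k, sides = 2)
  y <- as.numeric(y)
  # fill edge NAs with nearest computed value
  idx <- which(!is.na(y))
  if (!length(idx)) return(x)
  first <- idx[1]; last <- idx[length(idx)]
  if (first > 1L) y[1:(first - 1L)] <- y[first]
  if (last < length(y)) y[(last + 1L):length(y)] <- y[last]
  y
}

# dominant cycle period (samples) of a quasi-periodic signal via the
# autocorrelation peak; NA if none found
estimate_period <- function(x, rate, min_s = 0.25, max_s = 3) {
  x <- x - mean(x)
  if (sd(x) == 0) return(NA_real_)
  max_lag <- min(length(x) - 1L, round(max_s * rate))
  a <- acf(x, lag.max = max_lag, plot = FALSE)$acf[, 1, 1]
  lo <- round(min_s * rate)
  if (lo + 2 > length(a)) return(NA_real_)
  seg <- a[(lo + 1):length(a)]
  p <- which.max(seg) + lo - 1
  if (seg[which.max(seg)] <= 0.1) return(NA_real_)
  p
}

# rolling robust maximum (95th percentile) evaluated on a coarse grid and
# linearly interpolated back to every sample
rolling_robust_max <- function(x, width) {
  n <- length(x)
  width <- min(max(width, 3L), n)
  step <- max(1L, width %/% 8L)
  centers <- unique(c(seq(1L, n, by = step), n))
  vals <- vapply(centers, function(i) {
    lo <- max(1L, i - width %/% 2L)
    hi <- min(n, i + width %/% 2L)
    quantile(x[lo:hi], 0.95, names = FALSE)
  }, numeric(1))
  approx(centers, vals, xout = seq_len(n), rule = 2)$y
}

# refine an edge index to the half-amplitude crossing (linear interpolation),
# in samples (1-based, fractional); NA if no crossing found in the window
refine_edge <- function(mag, i, level, period, falling = TRUE) {
  n <- length(mag)
  half <- level / 2
  win <- max(3L, round(period / 4))
  if (falling) {
    lo <- max(1L, i - win)
    j <- i
    while (j > lo && mag[j] < half) j <- j - 1L
    if (mag[j] < half) return(NA_real_)  # window exhausted
    # crossing between j and j+1
    if (j >= n) return(NA_real_)
    j + (mag[j] - half) / (mag[j] - mag[j + 1L])
  } else {
    hi <- min(n, i + win)
    j <- i
    while (j < hi && mag[j] < half) j <- j + 1L
    if (mag[j] < half) return(NA_real_)
    if (j <= 1L) return(NA_real_)
    (j - 1L) + (half - mag[j - 1L]) / (mag[j] - mag[j - 1L])
  }
}

#' Detect hoof-on / hoof-off events from a limb sensor stream
#'
#' Rule-based stance detector: the smoothed gyroscope magnitude of a limb
#' sensor is compared against `theta` times a rolling robust maximum (95th
#' percentile over a window of about two stride periods). Contiguous
#' below-threshold regions longer than a fraction of the stride period are
#' stance phases; the stance onset is hoof-on and the stance offset hoof-off.
#' Both edges are refined to the half-amplitude crossing of the local swing
#' level, which matches the edge-midpoint convention of the synthetic
#' stance/swing gate. Events whose refinement window touches the start or
#' end of the recording are discarded.
#'
#' @param limb_stream A (filtered) limb [sensor_stream()].
#' @param theta Threshold as a fraction of the rolling robust maximum.
#' @param window_strides Width of the rolling-maximum window, in estimated
#'   stride periods.
#' @param smooth_s Moving-average smoothing width, seconds.
#' @param min_stance_frac Minimum stance length as a fraction of the
#'   estimated stride period.
#' @return A list with numeric vectors `on` and `off` (seconds, strictly
#'   increasing; `off[i]` is the stance end following `on[i]`). Both empty
#'   when no cycles are detectable.
#' @export
detect_hoof_events <- function(limb_stream, theta = 0.15,
                               window_strides = 2, smooth_s = 0.025,
                               min_stance_frac = 0.15) {
  stopifnot(inherits(limb_stream, "sensor_stream"))
  rate <- limb_stream$rate
  mag <- sqrt(rowSums(limb_stream$gyr^2))
  empty <- list(on = numeric(0), off = numeric(0))
  if (!length(mag) || max(mag) == 0) return(empty)
  mag_s <- smooth_ma(mag, max(1L, round(smooth_s * rate)))
  period <- estimate_period(mag_s, rate)
  if (is.na(period) || length(mag) < 1.5 * period) return(empty)
  env <- rolling_robust_max(mag_s, round(window_strides * period))
  below <- mag_s < theta * env
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_stance_frac * period
  on_idx <- starts[keep]; off_idx <- ends[keep]
  if (!length(on_idx)) return(empty)
  ons <- offs <- rep(NA_real_, length(on_idx))
  for (k in seq_along(on_idx)) {
    lvl_on <- max(mag_s[max(1L, on_idx[k] - round(period / 3)):on_idx[k]])
    lvl_off <- max(mag_s[off_idx[k]:min(length(mag_s),
                                        off_idx[k] + round(period / 3))])
    ons[k] <- refine_edge(mag_s, on_idx[k], lvl_on, period, falling = TRUE)
    offs[k] <- refine_edge(mag_s, off_idx[k], lvl_off, period,
                           falling = FALSE)
    # edge-of-recording stances cannot be refined reliably: require the
    # full local swing context on the relevant side
    if (on_idx[k] <= period / 4) ons[k] <- NA_real_
    if (off_idx[k] >= length(mag_s) - period / 4) offs[k] <- NA_real_
  }
  valid <- !is.na(ons) & !is.na(offs) & offs > ons
  list(on = (ons[valid] - 1) / rate, off = (offs[valid] - 1) / rate)
}

#' Window a recording into labelled strides
#'
#' Builds one half-open stride window per pair of consecutive right-front
#' hoof-on events. Strides whose duration deviates more than `mad_k` median
#' absolute deviations from the recording's median stride duration are
#' dropped (guards against missed events); the number dropped is attached as
#' attribute `n_dropped`.
#'
#' @param events Event list from [detect_hoof_events()] for the right front
#'   limb.
#' @param rate Sampling rate, Hz.
#' @param horse,trial,gait Labels attached to every window.
#' @param mad_k Outlier multiplier; `Inf` disables dropping.
#' @return Data frame with one row per stride: labels, 1-based half-open
#'   sample interval `[start, end)`, and `hoof_on_s`, `hoof_off_s`,
#'   `next_on_s` in seconds. Zero rows when fewer than two hoof-ons.
#' @export
segment_strides <- function(events, rate, horse = NA_character_,
                            trial = NA_character_, gait = NA_character_,
                            mad_k = 3) {
  ons <- events$on; offs <- events$off
  if (length(ons) < 2L) {
    out <- data.frame(horse = character(0), trial = character(0),
                      gait = character(0), stride_index = integer(0),
                      start = integer(0), end = integer(0),
                      hoof_on_s = numeric(0), hoof_off_s = numeric(0),
                      next_on_s = numeric(0))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  if (any(diff(ons) <= 0))
    stop("hoof-on events must be strictly increasing", call. = FALSE)
  n <- length(ons) - 1L
  off_for <- vapply(seq_len(n), function(i) {
    cand <- offs[offs >= ons[i] & offs < ons[i + 1L]]
    if (length(cand)) cand[1] else NA_real_
  }, numeric(1))
  out <- data.frame(horse = horse, trial = trial, gait = gait,
                    stride_index = seq_len(n),
                    start = round(ons[-length(ons)] * rate) + 1L,
                    end = round(ons[-1L] * rate) + 1L,
                    hoof_on_s = ons[-length(ons)],
                    hoof_off_s = off_for,
                    next_on_s = ons[-1L],
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$hoof_off_s), , drop = FALSE]
  n_dropped <- 0L
  if (is.finite(mad_k) && nrow(out) >= 3L) {
    dur <- out$next_on_s - out$hoof_on_s
    md <- median(dur); m <- mad(dur)
    # tolerance floor of 2 samples so event-timing jitter on otherwise
    # constant stride durations (MAD ~ 0) is never flagged
    keep <- abs(dur - md) <= max(mad_k * m, 2 / rate)
    n_dropped <- sum(!keep)
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

# filter all 7 streams of a recording and window it into strides using the
# right-front limb detector
preprocess_recording <- function(rec, order = 4, cutoff = 30, theta = 0.15,
                                 mad_k = 3) {
  streams <- lapply(rec$streams, lowpass, order = order, cutoff = cutoff)
  ev <- detect_hoof_events(streams$RF, theta = theta)
  windows <- segment_strides(ev, rate = streams$RF$rate, horse = rec$horse,
                             trial = rec$trial, gait = rec$gait,
                             mad_k = mad_k)
  list(streams = streams, events = ev, windows = windows)
}
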