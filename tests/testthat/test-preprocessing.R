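make_stream <- function(acc_z, rate = 200, location = "RF",
                        gyr = NULL) {
  n <- length(acc_z)
  if (is.null(gyr)) gyr <- matrix(0, n, 3)
  sensor_stream(location, rate, cbind(0, 0, acc_z), gyr)
}

test_that("lowpass is zero-phase, linear and passes DC", {
  n <- 2000
  z <- make_stream(rep(0, n))
  expect_equal(lowpass(z)$acc, z$acc)

  dc <- make_stream(rep(0.37, n))
  expect_equal(lowpass(dc)$acc[, 3], rep(0.37, n), tolerance = 1e-8)

  t <- (0:(n - 1)) / 200
  x <- make_stream(sin(2 * pi * 3 * t))
  y <- make_stream(cos(2 * pi * 7 * t) + 0.2)
  lin <- make_stream(2 * x$acc[, 3] - 3 * y$acc[, 3])
  expect_equal(lowpass(lin)$acc[, 3],
               2 * lowpass(x)$acc[, 3] - 3 * lowpass(y)$acc[, 3],
               tolerance = 1e-9)
  expect_equal(nrow(lowpass(x)$acc), n)
  expect_error(lowpass(x, cutoff = 100), "Nyquist")
})

test_that("out-of-band attenuation matches the analytic Butterworth response", {
  # zero-phase (forward-backward) filtering applies the squared magnitude
  # response; the digital filter's exact analytic response carries the
  # bilinear frequency warping tan(pi f / fs) in place of f
  rate <- 200; fc <- 30
  t <- (0:3999) / rate
  mid <- 1001:3000
  for (f in c(40, 60, 80)) {
    s <- make_stream(sin(2 * pi * f * t))
    out <- lowpass(s, order = 4, cutoff = fc)$acc[, 3]
    ratio <- sqrt(mean(out[mid]^2)) / sqrt(mean(s$acc[mid, 3]^2))
    warped <- 1 / (1 + (tan(pi * f / rate) / tan(pi * fc / rate))^8)
    expect_equal(ratio, warped, tolerance = 0.02 * warped)
    # never weaker than the analog-prototype prediction |H|^2
    expect_lte(ratio, 1 / (1 + (f / fc)^8))
  }
})

test_that("hoof-event detector handles degenerate inputs", {
  expect_equal(detect_hoof_events(make_stream(rep(0, 1000))),
               list(on = numeric(0), off = numeric(0)))
  # shorter than one stride period
  short <- tiny_cohort()$recordings$H01$pre$walk$streams$RF
  short$acc <- short$acc[1:100, ]; short$gyr <- short$gyr[1:100, ]
  ev <- detect_hoof_events(short)
  expect_length(ev$on, 0)
})

test_that("detected events match simulator ground truth within 2 samples", {
  co <- tiny_cohort()
  for (g in c("walk", "trot")) {
    rec <- co$recordings$H02$pre[[g]]
    streams <- lapply(rec$streams, lowpass)
    ev <- detect_hoof_events(streams$RF)
    gt <- co$events[co$events$horse == "H02" & co$events$trial == "pre" &
                      co$events$gait == g, ]
    expect_gte(length(ev$on), co$config$strides_per_trial)
    on_err <- vapply(ev$on, function(o) min(abs(o - gt$hoof_on_s)),
                     numeric(1)) * 200
    off_err <- vapply(ev$off, function(o) min(abs(o - gt$hoof_off_s)),
                      numeric(1)) * 200
    expect_lt(max(on_err), 2)
    expect_lt(max(off_err), 2)
  }
})

test_that("detector recovers 95% of hoof-ons within 3 samples under noise", {
  # ~100 strides across two horses; gyro noise ~5% of swing amplitude
  eff <- fatigue_effects(noise_sd_accel = 0.01, noise_sd_gyro = 12,
                         inter_horse_cv = 0.05, stride_cv = 0.02)
  co <- generate_cohort(2, 48, effects = eff, seed = 17, gaits = "walk")
  hits <- total <- 0
  for (id in co$horses$horse) {
    rec <- co$recordings[[id]]$pre$walk
    ev <- detect_hoof_events(lowpass(rec$streams$RF))
    gt <- co$events[co$events$horse == id & co$events$trial == "pre", ]
    err <- vapply(ev$on, function(o) min(abs(o - gt$hoof_on_s)),
                  numeric(1)) * 200
    hits <- hits + sum(err <= 3)
    total <- total + length(err)
  }
  expect_gte(total, 90)
  expect_gte(hits / total, 0.95)
})

test_that("segmentation builds half-open windows that tile the event span", {
  ev <- list(on = c(0, 1, 2), off = c(0.6, 1.6, 2.6))
  w <- segment_strides(ev, rate = 200)
  expect_equal(nrow(w), 2)
  expect_equal(w$next_on_s - w$hoof_on_s, c(1, 1))
  expect_equal(w$start, c(1, 201))
  expect_equal(w$end, c(201, 401))

  # one hoof-on -> no strides; n hoof-ons -> n - 1 windows
  expect_equal(nrow(segment_strides(list(on = 1, off = 1.5), 200)), 0)
  ons <- cumsum(c(0, rep(1, 66)))
  ev67 <- list(on = ons, off = ons[-67] + 0.6)
  w67 <- segment_strides(ev67, 200, mad_k = Inf)
  expect_equal(nrow(w67), 66)
  # windows partition [first on, last on): no gaps, no overlaps
  expect_equal(w67$start[-1], w67$end[-nrow(w67)])
  expect_error(segment_strides(list(on = c(1, 0.5), off = c()), 200),
               "strictly increasing")
})

test_that("stride-duration outliers are dropped by the MAD rule", {
  ons <- c(0, 1, 2, 3, 4, 7, 8, 9, 10)   # one 3-s gap from a missed event
  ev <- list(on = ons, off = ons[-length(ons)] + 0.5)
  w <- segment_strides(ev, rate = 200, mad_k = 3)
  expect_equal(attr(w, "n_dropped"), 1L)
  expect_true(all(w$next_on_s - w$hoof_on_s == 1))
  w_all <- segment_strides(ev, rate = 200, mad_k = Inf)
  expect_equal(attr(w_all, "n_dropped"), 0L)
  expect_equal(nrow(w_all), 8)
})
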