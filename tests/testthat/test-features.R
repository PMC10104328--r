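test_that("gait-event durations follow the hoof-event definitions", {
  d <- gait_event_durations(list(hoof_on_s = 0, hoof_off_s = 0.7,
                                 next_on_s = 1.0))
  expect_equal(unname(d), c(1.0, 0.7, 0.3))
  expect_equal(sum(d[c("stance_duration", "swing_duration")]),
               d[["stride_duration"]])
  # degenerate: zero stance
  d0 <- gait_event_durations(list(hoof_on_s = 2, hoof_off_s = 2,
                                  next_on_s = 3))
  expect_equal(unname(d0), c(1, 0, 1))
  # hoof-off outside the stride flags the stride invalid
  bad <- gait_event_durations(list(hoof_on_s = 0, hoof_off_s = 1.2,
                                   next_on_s = 1.0))
  expect_true(all(is.na(bad)))
})

test_that("angular ROM integrates angular velocity to a closed form", {
  expect_equal(angular_rom(rep(0, 100), 200), 0)
  expect_error(angular_rom(numeric(0), 200), "empty")
  # omega(t) = A (2pi/T) cos(2pi t/T) integrates to A sin -> ROM 2A
  T <- 1.0; A <- 12; rate <- 200
  t <- seq(0, T - 1 / rate, by = 1 / rate)
  w <- A * (2 * pi / T) * cos(2 * pi * t / T)
  expect_equal(angular_rom(w, rate), 2 * A, tolerance = 1e-3)
})

test_that("angular ROM matches a fine-grid integration oracle", {
  # random smooth band-limited signal, compared against 10x oversampling
  set.seed(4)
  T <- 1.2
  coefs <- rnorm(4); phases <- runif(4, 0, 2 * pi)
  omega <- function(t) {
    rowSums(sapply(1:4, function(k)
      coefs[k] * 20 * cos(2 * pi * k * t / T + phases[k])))
  }
  t_lo <- seq(0, T - 1 / 200, by = 1 / 200)
  t_hi <- seq(0, T - 1 / 2000, by = 1 / 2000)
  rom_lo <- angular_rom(omega(t_lo), 200)
  rom_hi <- angular_rom(omega(t_hi), 2000)
  expect_equal(rom_lo, rom_hi, tolerance = 0.005)
})

test_that("cyclic displacement inverts the analytic acceleration", {
  expect_equal(max(abs(cyclic_displacement(rep(0, 50), 200))), 0)
  expect_error(cyclic_displacement(numeric(0), 200), "empty")
  T <- 1.0; A <- 0.04; rate <- 200
  t <- seq(0, T - 1 / rate, by = 1 / rate)
  acc_g <- -A * (2 * pi / T)^2 * sin(2 * pi * t / T) / 9.81
  d <- cyclic_displacement(acc_g, rate)
  expect_equal(displacement_rom(d), 2 * A, tolerance = 0.02 * 2 * A)
  expect_equal(d, A * sin(2 * pi * t / T) - mean(A * sin(2 * pi * t / T)),
               tolerance = 1e-3)
})

test_that("cyclic displacement closes at the wrap-around point", {
  set.seed(8)
  rate <- 200
  t <- seq(0, 1 - 1 / rate, by = 1 / rate)
  a <- 0.3 * sin(2 * pi * t + 1) + 0.1 * cos(4 * pi * t) + rnorm(200, 0, 0.05)
  d <- cyclic_displacement(a, rate)
  v <- equifatigue:::cumtrapz_u(a * 9.81 - mean(a * 9.81), 1 / rate)
  v <- v - mean(v)
  wrap <- d[length(d)] + (v[length(v)] + v[1]) / 2 / rate
  expect_lt(abs(wrap - (d[1] - 0)), 1e-9 * displacement_rom(d))
})

test_that("displacement ROM scales linearly with acceleration amplitude", {
  set.seed(5)
  t <- seq(0, 0.995, by = 1 / 200)
  a <- 0.2 * sin(2 * pi * t) + 0.05 * sin(4 * pi * t + 0.3)
  r1 <- displacement_rom(cyclic_displacement(a, 200))
  r3 <- displacement_rom(cyclic_displacement(3 * a, 200))
  expect_equal(r3 / r1, 3, tolerance = 1e-6)
})

test_that("MaxDiff and MinDiff measure peak and trough asymmetry", {
  t <- seq(0, 0.995, by = 1 / 200)
  # symmetric double sinusoid: both indices zero
  sym <- 0.03 * cos(4 * pi * t)
  expect_equal(unname(maxdiff_mindiff(sym)), c(0, 0), tolerance = 1e-12)
  # constructed peaks at 0.040 and 0.030 -> MaxDiff 0.010
  A2 <- 0.0325; A1 <- 0.005
  th <- 2 * pi * t - pi / 4
  d <- A2 * cos(2 * th) + A1 * cos(th)
  md <- maxdiff_mindiff(d)
  peaks <- sort(equifatigue:::circular_extrema(d)$max, decreasing = TRUE)
  expect_equal(peaks[1], A2 + A1, tolerance = 1e-4)   # 0.0375 + eps grid
  expect_equal(md[["maxdiff"]], 0.010, tolerance = 1e-4)
  # single-peak signal yields the missing-value sentinel
  expect_true(is.na(maxdiff_mindiff(sin(2 * pi * t))[["maxdiff"]]))
  # motionless series: both zero by the degenerate rule
  expect_equal(unname(maxdiff_mindiff(rep(0.1, 100))), c(0, 0))
})

test_that("speed estimate follows its displacement definition", {
  rate <- 200
  n <- 200
  zero <- sensor_stream("sacrum", rate, matrix(0, n, 3), matrix(0, n, 3))
  win <- list(start = 1, end = n + 1, hoof_on_s = 0, hoof_off_s = 0.6,
              next_on_s = 1)
  expect_equal(estimate_speed(zero, win), 0)
  # displacement ROM 1.5 m over 1.0 s -> 1.5 m/s
  t <- (0:(n - 1)) / rate
  A <- 0.75
  acc <- cbind(-A * (2 * pi)^2 * sin(2 * pi * t) / 9.81, 0, 0)
  s <- sensor_stream("sacrum", rate, acc, matrix(0, n, 3))
  expect_equal(estimate_speed(s, win), 1.5, tolerance = 0.01)
  expect_equal(estimate_speed(s, win, stride_length_offset = 0.5), 2.0,
               tolerance = 0.01)
  expect_error(estimate_speed(s, list(start = 1, end = n + 1, hoof_on_s = 0,
                                      hoof_off_s = 0, next_on_s = 0)),
               "positive")
})

test_that("speed estimates track prescribed speed across a cohort", {
  co <- tiny_cohort()
  sf <- tiny_features()
  al <- align_truth(co, sf)
  expect_gt(cor(al$extracted[, "speed"], al$truth[, "speed"],
                method = "spearman"), 0.9)
})

test_that("extract_stride_features returns exactly the 52 named features", {
  pp <- tiny_preprocessed()
  f <- extract_stride_features(pp$streams, pp$windows[2, ])
  expect_length(f, 52)
  expect_named(f, stride_feature_names())
  rom_like <- grepl("_rom_|disp_|diff_", names(f))
  expect_true(all(f[rom_like] >= 0, na.rm = TRUE))
  expect_equal(f[["stance_duration"]] + f[["swing_duration"]],
               f[["stride_duration"]])
  expect_error(extract_stride_features(pp$streams[-2], pp$windows[2, ]),
               "withers")
})

test_that("all-zero streams give zero motion features", {
  n <- 400
  streams <- sapply(equifatigue:::ALL_LOCATIONS, function(l)
    sensor_stream(l, 200, matrix(0, n, 3), matrix(0, n, 3)),
    simplify = FALSE)
  win <- list(start = 1, end = 201, hoof_on_s = 0, hoof_off_s = 0.6,
              next_on_s = 1)
  f <- extract_stride_features(streams, win)
  motion <- setdiff(stride_feature_names(),
                    c("stride_duration", "stance_duration",
                      "swing_duration"))
  expect_true(all(f[motion] == 0))
  expect_equal(unname(f[c("stride_duration", "stance_duration",
                          "swing_duration")]), c(1, 0.6, 0.4))
})

test_that("zero-noise extraction recovers simulator ground truth", {
  co <- tiny_cohort()
  sf <- tiny_features()
  al <- align_truth(co, sf)
  rel <- abs(al$extracted - al$truth) /
    ifelse(abs(al$truth) > 1e-9, abs(al$truth), 1)
  med <- apply(rel, 2, median, na.rm = TRUE)
  expect_lt(max(med), 0.05)
  expect_lt(max(al$timing_err_s) * 200, 2)
})
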