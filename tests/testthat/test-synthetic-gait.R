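test_that("gait parameter objects validate their invariants", {
  expect_error(gait_params("walk", stride_duration = 0), "positive")
  expect_error(gait_params("walk", duty_factor = 1), "duty_factor")
  expect_error(gait_params("walk", vertical_peak_asymmetry = -1),
               "non-negative")
  p <- gait_params("walk")
  expect_equal(p$disp_rom["sacrum", "long"], p$speed * p$stride_duration)
  expect_error(fatigue_effects(noise_sd_accel = -1), "non-negative")
})

test_that("stride kinematics honour prescribed ranges and timing", {
  p <- gait_params("walk", duty_factor = 0.6, stride_duration = 1.0,
                   limb_rom = matrix(10, 4, 3,
                                     dimnames = list(c("LF", "RF", "LH", "RH"),
                                                     c("proret", "abdadd",
                                                       "introt"))))
  k <- generate_stride_kinematics(p, rate = 200)
  # duty 0.6, stride 1.0 s -> stance 0.6 s, swing 0.4 s ground truth
  expect_equal(k$stride_duration, 1.0)
  expect_equal(k$events$RF$on, 0)
  expect_equal(k$events$RF$off, 0.6)
  # limb pro/ret ROM is exactly the prescribed 10 deg
  ang <- k$locations$RF$angle[, "z"]
  expect_equal(max(ang) - min(ang), 10)
  # trunk vertical range matches the configured displacement ROM
  dz <- k$locations$sacrum$disp[, "z"]
  expect_equal(max(dz) - min(dz), p$disp_rom["sacrum", "vert"],
               tolerance = 1e-3)
})

test_that("trunk vertical displacement has two peaks with prescribed difference", {
  for (asym in c(0, 0.005, 0.012)) {
    p <- gait_params("walk", vertical_peak_asymmetry = asym)
    k <- generate_stride_kinematics(p, rate = 400)
    dz <- k$locations$withers$disp[, "z"]
    ex <- equifatigue:::circular_extrema(dz)
    expect_length(ex$max, 2)
    expect_length(ex$min, 2)
    peaks <- sort(ex$max, decreasing = TRUE)
    expect_equal(peaks[1] - peaks[2], asym, tolerance = 1e-4)
    # troughs of the two-harmonic model are equal
    expect_equal(diff(sort(ex$min)[1:2]), 0, tolerance = 1e-4)
  }
})

test_that("ground-truth trajectories are cyclic at the wrap-around point", {
  k <- generate_stride_kinematics(gait_params("trot"), rate = 200)
  dt <- 1 / 200
  for (loc in c("RF", "LH")) {
    L <- k$locations[[loc]]
    for (col in c("x", "y", "z")) {
      # limb angles are numerical integrals; their periodic continuation
      # one sample past the window must return to the first value
      a <- L$angle[, col]
      rng_a <- max(a) - min(a)
      w <- L$angvel[, col]
      wrap <- a[length(a)] + dt * (w[length(w)] + w[1]) / 2 - mean(w) * dt
      expect_lt(abs(wrap - a[1]), 1e-9 * rng_a)
    }
  }
})

test_that("kinematics_to_imu emits analytic accelerations in g", {
  p <- gait_params("walk")
  k <- generate_stride_kinematics(p, rate = 200)
  im <- kinematics_to_imu(k)
  # displacement A sin(w t + psi) must emit acceleration -A w^2 sin(.)/9.81
  A <- p$disp_rom["withers", "long"] / 2
  w0 <- 2 * pi / k$stride_duration
  psi <- equifatigue:::disp_phase("withers", "long")
  expect_equal(im$withers$acc[, "x"],
               -A * w0^2 * sin(w0 * k$t + psi) / 9.81, tolerance = 1e-12)
  # same seed twice gives identical noise realizations
  set.seed(9); s1 <- kinematics_to_imu(k, noise_sd_accel = 0.05)
  set.seed(9); s2 <- kinematics_to_imu(k, noise_sd_accel = 0.05)
  expect_identical(s1, s2)
})

test_that("cohort generation is deterministic and injects effects exactly", {
  expect_error(generate_cohort(1, 5), "n_horses")
  expect_error(generate_cohort(3, 1), "strides_per_trial")
  a <- generate_cohort(3, 4, seed = 11, gaits = "walk")
  b <- generate_cohort(3, 4, seed = 11, gaits = "walk")
  expect_identical(a, b)

  # zero effects, zero noise: pre and post trial truth identical per horse
  co0 <- generate_cohort(3, 4, effects = clean_effects(), seed = 1,
                         gaits = "walk")
  tt <- co0$trial_truth
  fn <- stride_feature_names()
  pre <- tt[tt$trial == "pre", fn]; post <- tt[tt$trial == "post", fn]
  expect_equal(unname(as.matrix(post)), unname(as.matrix(pre)))

  # configured multiplicative deltas hold exactly before noise
  eff <- fatigue_effects(stance_duration_walk = 0.10,
                         front_limb_longitudinal_disp = -0.15,
                         hind_limb_proret_rom = -0.2,
                         noise_sd_accel = 0, noise_sd_gyro = 0,
                         inter_horse_cv = 0.1, stride_cv = 0)
  co <- generate_cohort(4, 4, effects = eff, seed = 2, gaits = "walk")
  tt <- co$trial_truth
  for (id in co$horses$horse) {
    pre <- tt[tt$horse == id & tt$trial == "pre", ]
    post <- tt[tt$horse == id & tt$trial == "post", ]
    expect_equal(post$stance_duration / pre$stance_duration, 1.10)
    expect_equal(post$disp_long_LF / pre$disp_long_LF, 0.85)
    expect_equal(post$disp_long_RF / pre$disp_long_RF, 0.85)
    expect_equal(post$proret_rom_LH / pre$proret_rom_LH, 0.80)
    # untouched parameters unchanged
    expect_equal(post$disp_long_LH, pre$disp_long_LH)
  }
})

test_that("named extra effects resolve to the right parameters", {
  p <- gait_params("trot")
  eff <- fatigue_effects(extra = list(speed = -0.1, roll_rom_sacrum = 0.2,
                                      disp_vert_poll = -0.3))
  q <- equifatigue:::apply_effects(p, eff)
  expect_equal(q$speed / p$speed, 0.9)
  expect_equal(q$trunk_rom["sacrum", "roll"] / p$trunk_rom["sacrum", "roll"],
               1.2)
  expect_equal(q$disp_rom["poll", "vert"] / p$disp_rom["poll", "vert"], 0.7)
  expect_error(
    equifatigue:::apply_effects(p, fatigue_effects(extra = list(bogus = 1))),
    "unknown effect target")
})

test_that("double-integrating emitted acceleration recovers prescribed displacement", {
  # consistency oracle between the simulator and the feature stage
  p <- gait_params("trot")
  k <- generate_stride_kinematics(p, rate = 200)
  for (loc in c("sacrum", "poll", "RF")) {
    for (ax in c("x", "y", "z")) {
      target <- p$disp_rom[loc, c(x = "long", y = "med", z = "vert")[[ax]]]
      d <- cyclic_displacement(k$locations[[loc]]$acc[, ax] / 9.81, 200)
      expect_equal(displacement_rom(d), target, tolerance = 0.02)
    }
  }
})
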