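#' Construct a sensor stream
#'
#' One IMU location's synchronized tri-axial acceleration (g) and angular
#' velocity (deg/s) at a fixed sampling rate. Axis convention: for limb
#' sensors the gyroscope axes x/y/z are internal-external rotation,
#' abduction-adduction and protraction-retraction; for sacrum/withers/poll
#' they are roll/pitch/yaw. Accelerometer axes are locomotion axes for all
#' locations: x longitudinal, y mediolateral, z vertical.
#'
#' @param location One of sacrum, withers, poll, LF, RF, LH, RH.
#' @param rate Sampling rate in Hz.
#' @param acc T x 3 acceleration matrix, g.
#' @param gyr T x 3 angular-velocity matrix, deg/s.
#' @return Object of class `sensor_stream`.
#' @export
sensor_stream <- function(location, rate, acc, gyr) {
  location <- match.arg(location, ALL_LOCATIONS)
  acc <- as.matrix(acc); gyr <- as.matrix(gyr)
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  if (ncol(acc) != 3L || ncol(gyr) != 3L || nrow(acc) != nrow(gyr))
    stop("acc and gyr must be T x 3 matrices of equal length", call. = FALSE)
  colnames(acc) <- c("x", "y", "z"); colnames(gyr) <- c("x", "y", "z")
  structure(list(location = location, rate = rate, acc = acc, gyr = gyr),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %s: %d samples @ %g Hz (%.1f s)\n",
              x$location, nrow(x$acc), x$rate, nrow(x$acc) / x$rate))
  invisible(x)
}

# C1 smoothstep
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# signed circular distance on the unit phase circle, in [-0.5, 0.5)
circ_dist <- function(x) x - round(x)

# smooth stance/swing gate on stride phase phi in [0,1): ~0 during stance
# [0, duty), ~1 during swing. Written as a smoothstep of the circular
# distance to the swing centre, so the rising-edge midpoint sits exactly at
# phi = duty (hoof-off) and the falling-edge midpoint at phi = 1 == 0
# (hoof-on). Edges have half-width h; needs h < min(duty, 1 - duty) / 2.
stance_gate <- function(phi, duty, h = 0.02) {
  centre <- (duty + 1) / 2
  halfwidth <- (1 - duty) / 2
  smoothstep((halfwidth + h - abs(circ_dist(phi - centre))) / (2 * h))
}

# fixed per-(location, axis) phase offsets (radians) so channels are not all
# in phase; arbitrary but deterministic
disp_phase <- function(location, axis) {
  li <- match(location, ALL_LOCATIONS)
  ai <- match(axis, c("long", "med", "vert"))
  0.40 * li + 1.10 * ai
}
angle_phase <- function(location, axis) {
  li <- match(location, TRUNK_LOCATIONS)
  ai <- match(axis, c("roll", "pitch", "yaw"))
  0.70 * li + 0.90 * ai + 0.30
}

# limb stance phase offsets (fraction of stride, right front = reference)
limb_phase_offsets <- function(gait) {
  if (gait == "walk") c(LF = 0.50, RF = 0.00, LH = 0.75, RH = 0.25)
  else c(LF = 0.50, RF = 0.00, LH = 0.00, RH = 0.50)
}

# amplitudes of the two-harmonic trunk vertical model:
# d(theta) = A2 cos(2 theta) + A1 cos(theta) with range rom and peak
# difference asym (the two troughs are equal)
vertical_amplitudes <- function(rom, asym) {
  if (rom <= 0) return(c(A2 = 0, A1 = 0))
  if (asym > 0.5 * rom)
    stop("vertical_peak_asymmetry must not exceed half the vertical range",
         call. = FALSE)
  a1 <- asym / 2
  disc <- (rom - a1)^2 - a1^2
  a2 <- ((rom - a1) + sqrt(disc)) / 4
  c(A2 = a2, A1 = a1)
}

rot_idx <- function(n, frac) {
  k <- round(frac * n) %% n
  if (k == 0) seq_len(n) else c((k + 1):n, 1:k)
}

#' Analytic kinematics of one synthetic stride
#'
#' Builds the ground-truth displacement and angle trajectories of all seven
#' sensor locations over exactly one stride, together with their analytic
#' time derivatives (linear acceleration in m/s^2, angular velocity in
#' deg/s). Every channel is a sum of at most two stride-frequency harmonics,
#' so accelerations are exact second derivatives and all trajectories are
#' cyclic. Trunk and poll vertical displacement follows a two-harmonic model
#' with exactly two peaks and two troughs per stride and a prescribed peak
#' difference. Limb angular velocity is shaped by a smooth stance/swing gate
#' (near zero during stance), whose falling-edge midpoint defines hoof-on and
#' rising-edge midpoint hoof-off; limb angles are the cyclic integrals of the
#' gated angular velocities, scaled to the prescribed ranges of motion.
#'
#' Accelerations are gravity-compensated (linear acceleration only); the
#' simulator emits no gravity component.
#'
#' @param params A [gait_params()] object.
#' @param rate Sampling rate, Hz. The stride is sampled on
#'   `n = round(stride_duration * rate)` points; the realized stride duration
#'   is `n / rate`.
#' @param edge_halfwidth Half-width of the gate transition, as a fraction of
#'   the stride.
#' @return A list of class `stride_kinematics` with elements `t` (sample
#'   times, s), `stride_duration` (realized, s), `events` (hoof-on/off times
#'   of every limb, s), `gate` (RF gate values) and, per location, matrices
#'   `disp` (m), `acc` (m/s^2), `angle` (deg), `angvel` (deg/s).
#' @export
#' @examples
#' k <- generate_stride_kinematics(gait_params("walk"))
#' range(k$locations$sacrum$disp[, "z"])
generate_stride_kinematics <- function(params, rate = 200,
                                       edge_halfwidth = 0.02) {
  stopifnot(inherits(params, "gait_params"))
  if (params$stride_duration <= 0)
    stop("stride_duration must be positive", call. = FALSE)
  n <- max(round(params$stride_duration * rate), 8L)
  T_used <- n / rate
  phi <- (seq_len(n) - 1) / n
  t <- phi * T_used
  w0 <- 2 * pi / T_used
  duty <- params$duty_factor
  dt <- 1 / rate

  harmonic <- function(A, psi) {
    list(d = A * sin(w0 * t + psi),
         dd = -A * w0^2 * sin(w0 * t + psi))
  }

  locs <- list()
  for (loc in ALL_LOCATIONS) {
    disp <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
    acc <- disp
    for (ax in c("long", "med", "vert")) {
      col <- c(long = "x", med = "y", vert = "z")[[ax]]
      rom <- params$disp_rom[loc, ax]
      if (loc %in% TRUNK_LOCATIONS && ax == "vert") {
        A <- vertical_amplitudes(rom, params$vertical_peak_asymmetry)
        th <- w0 * t - pi / 4
        disp[, col] <- A["A2"] * cos(2 * th) + A["A1"] * cos(th)
        acc[, col] <- -w0^2 * (4 * A["A2"] * cos(2 * th) +
                                 A["A1"] * cos(th))
      } else {
        hh <- harmonic(rom / 2, disp_phase(loc, ax))
        disp[, col] <- hh$d
        acc[, col] <- hh$dd
      }
    }
    angle <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
    angvel <- angle
    if (loc %in% TRUNK_LOCATIONS) {
      for (ax in c("roll", "pitch", "yaw")) {
        col <- c(roll = "x", pitch = "y", yaw = "z")[[ax]]
        A <- params$trunk_rom[loc, ax] / 2
        psi <- angle_phase(loc, ax)
        angle[, col] <- A * sin(w0 * t + psi)
        angvel[, col] <- A * w0 * cos(w0 * t + psi)
      }
    } else {
      gate <- stance_gate(phi, duty, edge_halfwidth)
      u <- phi - (duty + 1) / 2
      shapes <- list(z = gate * sin(2 * pi * u),   # pro/ret
                     y = gate * cos(4 * pi * u),   # abd/add
                     x = gate * sin(4 * pi * u))   # int/ext
      roms <- c(z = params$limb_rom[loc, "proret"],
                y = params$limb_rom[loc, "abdadd"],
                x = params$limb_rom[loc, "introt"])
      for (col in c("x", "y", "z")) {
        sh <- shapes[[col]]
        base_ang <- cumtrapz_u(sh - mean(sh), dt)
        romb <- max(base_ang) - min(base_ang)
        K <- if (romb > 0) roms[[col]] / romb else 0
        angvel[, col] <- K * sh
        angle[, col] <- K * base_ang
      }
      # rotate limbs to their footfall phase within the stride, so the
      # limb's hoof-on falls at phase `off` (RF stays at 0)
      off <- limb_phase_offsets(params$gait)[[loc]]
      if (off != 0) {
        idx <- rot_idx(n, (1 - off) %% 1)
        angvel <- angvel[idx, , drop = FALSE]
        angle <- angle[idx, , drop = FALSE]
        disp <- disp[idx, , drop = FALSE]
        acc <- acc[idx, , drop = FALSE]
      }
      if (loc == "RF") locs$.gate <- gate
    }
    locs[[loc]] <- list(disp = disp, acc = acc, angle = angle,
                        angvel = angvel)
  }
  gate <- locs$.gate
  locs$.gate <- NULL
  offs <- limb_phase_offsets(params$gait)
  events <- lapply(LIMB_LOCATIONS, function(l) {
    on <- (offs[[l]] %% 1) * T_used
    list(on = on, off = ((offs[[l]] + duty) %% 1) * T_used)
  })
  names(events) <- LIMB_LOCATIONS
  structure(list(t = t, stride_duration = T_used, duty_factor = duty,
                 events = events, gate = gate, locations = locs,
                 rate = rate),
            class = "stride_kinematics")
}

#' Convert ground-truth kinematics to IMU sensor streams
#'
#' Emits, per location, the analytic linear acceleration converted to g and
#' the analytic angular velocity in deg/s, each with optional additive
#' i.i.d. Gaussian sensor noise. Gravity is not added: the streams are
#' gravity-compensated linear accelerations, matching the convention assumed
#' by the cyclic double-integration stage.
#'
#' @param kin A `stride_kinematics` object (or any list with per-location
#'   `acc` in m/s^2 and `angvel` in deg/s under `$locations`).
#' @param noise_sd_accel Accelerometer noise SD, g.
#' @param noise_sd_gyro Gyroscope noise SD, deg/s.
#' @return Named list of [sensor_stream()] objects, one per location.
#' @export
kinematics_to_imu <- function(kin, noise_sd_accel = 0, noise_sd_gyro = 0) {
  rate <- kin$rate
  out <- lapply(ALL_LOCATIONS, function(loc) {
    L <- kin$locations[[loc]]
    n <- nrow(L$acc)
    acc_g <- L$acc / G0
    gyr <- L$angvel
    if (noise_sd_accel > 0)
      acc_g <- acc_g + matrix(rnorm(3 * n, sd = noise_sd_accel), n, 3)
    if (noise_sd_gyro > 0)
      gyr <- gyr + matrix(rnorm(3 * n, sd = noise_sd_gyro), n, 3)
    sensor_stream(loc, rate, acc_g, gyr)
  })
  names(out) <- ALL_LOCATIONS
  out
}
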