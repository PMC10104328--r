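#' Gait parameter set for the synthetic stride model
#'
#' Bundles the per-gait quantities the simulator prescribes and the feature
#' pipeline is expected to recover: timing (stride duration, duty factor),
#' forward speed, limb and trunk angular ranges of motion, per-location
#' displacement ranges, and the trunk vertical peak asymmetry that becomes
#' MaxDiff. Defaults are order-of-magnitude realistic for in-hand walk and
#' trot on a hard surface; they are a stand-in, not measured equine
#' kinematics.
#'
#' The sacrum longitudinal displacement range defaults to
#' `speed * stride_duration` (the stride length), which ties the simulator's
#' speed ground truth to the displacement-based speed estimate of
#' [estimate_speed()].
#'
#' @param gait `"walk"` or `"trot"`.
#' @param stride_duration Stride period in seconds.
#' @param duty_factor Stance fraction of the stride, in (0, 1).
#' @param speed Forward speed in m/s.
#' @param vertical_peak_asymmetry Prescribed difference between the two trunk
#'   vertical-displacement peaks within a stride (metres); the ground-truth
#'   MaxDiff. The two troughs of the harmonic model are equal, so the
#'   ground-truth MinDiff is 0.
#' @param limb_rom 4 x 3 matrix (rows LF, RF, LH, RH; columns proret, abdadd,
#'   introt) of limb angular ranges of motion in degrees.
#' @param trunk_rom 3 x 3 matrix (rows sacrum, withers, poll; columns roll,
#'   pitch, yaw) of angular ranges of motion in degrees.
#' @param disp_rom 7 x 3 matrix (rows sacrum, withers, poll, LF, RF, LH, RH;
#'   columns long, med, vert) of displacement ranges in metres. A `NA` in
#'   `[sacrum, long]` is replaced by `speed * stride_duration`.
#' @return An object of class `gait_params`.
#' @export
#' @examples
#' p <- gait_params("walk")
#' p$duty_factor
gait_params <- function(gait = c("walk", "trot"),
                        stride_duration = NULL,
                        duty_factor = NULL,
                        speed = NULL,
                        vertical_peak_asymmetry = NULL,
                        limb_rom = NULL,
                        trunk_rom = NULL,
                        disp_rom = NULL) {
  gait <- match.arg(gait)
  def <- if (gait == "walk") {
    list(stride_duration = 1.10, duty_factor = 0.60, speed = 1.6,
         vertical_peak_asymmetry = 0.005,
         limb = c(proret = 55, abdadd = 10, introt = 8),
         trunk = rbind(sacrum = c(8, 7, 8), withers = c(6, 6, 5),
                       poll = c(10, 12, 10)),
         disp = rbind(sacrum  = c(NA,   0.040, 0.060),
                      withers = c(0.080, 0.040, 0.060),
                      poll    = c(0.100, 0.050, 0.080),
                      LF = c(0.250, 0.060, 0.120), RF = c(0.250, 0.060, 0.120),
                      LH = c(0.230, 0.060, 0.110), RH = c(0.230, 0.060, 0.110)))
  } else {
    list(stride_duration = 0.75, duty_factor = 0.40, speed = 3.5,
         vertical_peak_asymmetry = 0.008,
         limb = c(proret = 60, abdadd = 12, introt = 9),
         trunk = rbind(sacrum = c(6, 6, 5), withers = c(5, 5, 4),
                       poll = c(8, 9, 7)),
         disp = rbind(sacrum  = c(NA,   0.030, 0.090),
                      withers = c(0.070, 0.030, 0.090),
                      poll    = c(0.090, 0.040, 0.100),
                      LF = c(0.300, 0.070, 0.150), RF = c(0.300, 0.070, 0.150),
                      LH = c(0.280, 0.070, 0.140), RH = c(0.280, 0.070, 0.140)))
  }
  stride_duration <- stride_duration %||% def$stride_duration
  duty_factor <- duty_factor %||% def$duty_factor
  speed <- speed %||% def$speed
  vertical_peak_asymmetry <- vertical_peak_asymmetry %||%
    def$vertical_peak_asymmetry
  if (is.null(limb_rom)) {
    limb_rom <- matrix(rep(def$limb, each = 4), nrow = 4,
                       dimnames = list(LIMB_LOCATIONS, names(def$limb)))
  }
  if (is.null(trunk_rom)) {
    trunk_rom <- def$trunk
    dimnames(trunk_rom) <- list(TRUNK_LOCATIONS, c("roll", "pitch", "yaw"))
  }
  if (is.null(disp_rom)) {
    disp_rom <- def$disp
    dimnames(disp_rom) <- list(ALL_LOCATIONS, c("long", "med", "vert"))
  }
  if (is.na(disp_rom["sacrum", "long"]))
    disp_rom["sacrum", "long"] <- speed * stride_duration

  if (stride_duration <= 0)
    stop("stride_duration must be positive", call. = FALSE)
  if (duty_factor <= 0 || duty_factor >= 1)
    stop("duty_factor must lie in (0, 1)", call. = FALSE)
  if (any(limb_rom < 0) || any(trunk_rom < 0) || any(disp_rom < 0) ||
      vertical_peak_asymmetry < 0)
    stop("ranges of motion and peak asymmetry must be non-negative",
         call. = FALSE)

  structure(list(gait = gait, stride_duration = stride_duration,
                 duty_factor = duty_factor, speed = speed,
                 vertical_peak_asymmetry = vertical_peak_asymmetry,
                 limb_rom = limb_rom, trunk_rom = trunk_rom,
                 disp_rom = disp_rom),
            class = "gait_params")
}

#' Fatigue-effect and noise configuration
#'
#' Multiplicative pre-to-post deltas applied to the gait parameters of the
#' post-SET trial, plus the simulator's noise model. Default directions follow
#' the observed fatigue signature: longer stance at walk, shorter swing at
#' trot, reduced front-limb longitudinal displacement, reduced hind-limb
#' protraction/retraction range.
#'
#' @param stance_duration_walk Fractional change of stance duration at walk
#'   (stride duration held fixed); +0.10 means 10% longer stance.
#' @param swing_duration_trot Fractional change of swing duration at trot.
#' @param front_limb_longitudinal_disp Fractional change of LF/RF longitudinal
#'   displacement range.
#' @param hind_limb_proret_rom Fractional change of LH/RH
#'   protraction/retraction range of motion.
#' @param extra Named list of additional deltas keyed by parameter name:
#'   `"speed"`, `"stride_duration"`, `"vertical_peak_asymmetry"`, or any
#'   per-stride feature name such as `"proret_rom_LF"`, `"disp_vert_sacrum"`,
#'   `"roll_rom_withers"`.
#' @param noise_sd_accel Accelerometer noise SD, g (per sample, per axis).
#' @param noise_sd_gyro Gyroscope noise SD, deg/s.
#' @param inter_horse_cv Coefficient of variation of per-horse baselines
#'   around the configured gait parameters.
#' @param stride_cv Stride-to-stride coefficient of variation of each
#'   parameter within a trial.
#' @return Object of class `fatigue_effects`.
#' @export
fatigue_effects <- function(stance_duration_walk = 0,
                            swing_duration_trot = 0,
                            front_limb_longitudinal_disp = 0,
                            hind_limb_proret_rom = 0,
                            extra = list(),
                            noise_sd_accel = 0.02,
                            noise_sd_gyro = 1.0,
                            inter_horse_cv = 0.08,
                            stride_cv = 0.03) {
  if (noise_sd_accel < 0 || noise_sd_gyro < 0 || inter_horse_cv < 0 ||
      stride_cv < 0)
    stop("noise and CV values must be non-negative", call. = FALSE)
  structure(list(stance_duration_walk = stance_duration_walk,
                 swing_duration_trot = swing_duration_trot,
                 front_limb_longitudinal_disp = front_limb_longitudinal_disp,
                 hind_limb_proret_rom = hind_limb_proret_rom,
                 extra = extra,
                 noise_sd_accel = noise_sd_accel,
                 noise_sd_gyro = noise_sd_gyro,
                 inter_horse_cv = inter_horse_cv,
                 stride_cv = stride_cv),
            class = "fatigue_effects")
}

# default effect set used for "strong effect" experiments: the four
# documented fatigue directions
fatigue_effects_default <- function(...) {
  fatigue_effects(stance_duration_walk = 0.10,
                  swing_duration_trot = -0.10,
                  front_limb_longitudinal_disp = -0.15,
                  hind_limb_proret_rom = -0.15, ...)
}

# apply the configured multiplicative deltas to a gait_params object,
# returning the post-trial parameters; ratios are exact (no noise here)
apply_effects <- function(params, effects) {
  stopifnot(inherits(params, "gait_params"), inherits(effects, "fatigue_effects"))
  p <- params
  if (p$gait == "walk" && effects$stance_duration_walk != 0) {
    p$duty_factor <- min(p$duty_factor * (1 + effects$stance_duration_walk),
                         0.95)
  }
  if (p$gait == "trot" && effects$swing_duration_trot != 0) {
    p$duty_factor <- max(1 - (1 - p$duty_factor) *
                           (1 + effects$swing_duration_trot), 0.05)
  }
  if (effects$front_limb_longitudinal_disp != 0) {
    p$disp_rom[c("LF", "RF"), "long"] <-
      p$disp_rom[c("LF", "RF"), "long"] *
      (1 + effects$front_limb_longitudinal_disp)
  }
  if (effects$hind_limb_proret_rom != 0) {
    p$limb_rom[c("LH", "RH"), "proret"] <-
      p$limb_rom[c("LH", "RH"), "proret"] * (1 + effects$hind_limb_proret_rom)
  }
  for (nm in names(effects$extra)) {
    d <- effects$extra[[nm]]
    p <- apply_named_delta(p, nm, d)
  }
  p
}

# resolve a feature-style parameter name to a slot of gait_params and scale it
apply_named_delta <- function(p, nm, d) {
  f <- 1 + d
  if (nm %in% c("speed", "stride_duration", "vertical_peak_asymmetry")) {
    p[[nm]] <- p[[nm]] * f
    if (nm == "speed" || nm == "stride_duration")
      p$disp_rom["sacrum", "long"] <- p$speed * p$stride_duration
    return(p)
  }
  m <- regmatches(nm, regexec(
    "^(proret|abdadd|introt)_rom_(LF|RF|LH|RH)$", nm))[[1]]
  if (length(m)) {
    p$limb_rom[m[3], m[2]] <- p$limb_rom[m[3], m[2]] * f
    return(p)
  }
  m <- regmatches(nm, regexec(
    "^(roll|pitch|yaw)_rom_(sacrum|withers|poll)$", nm))[[1]]
  if (length(m)) {
    p$trunk_rom[m[3], m[2]] <- p$trunk_rom[m[3], m[2]] * f
    return(p)
  }
  m <- regmatches(nm, regexec(
    "^disp_(long|med|vert)_(sacrum|withers|poll|LF|RF|LH|RH)$", nm))[[1]]
  if (length(m)) {
    p$disp_rom[m[3], m[2]] <- p$disp_rom[m[3], m[2]] * f
    return(p)
  }
  stop("unknown effect target: ", nm, call. = FALSE)
}

# multiplicative jitter of every scalar kinematic quantity; used for both
# inter-horse baselines and stride-to-stride variation. duty_factor is kept
# inside (0.05, 0.95).
jitter_params <- function(p, cv) {
  if (cv <= 0) return(p)
  jit <- function(x) x * (1 + cv * rnorm(length(x)))
  p$stride_duration <- max(jit(p$stride_duration), 0.2 * p$stride_duration)
  p$duty_factor <- min(max(jit(p$duty_factor), 0.05), 0.95)
  p$speed <- max(jit(p$speed), 0)
  p$vertical_peak_asymmetry <- max(jit(p$vertical_peak_asymmetry), 0)
  p$limb_rom[] <- pmax(jit(as.numeric(p$limb_rom)), 0)
  p$trunk_rom[] <- pmax(jit(as.numeric(p$trunk_rom)), 0)
  p$disp_rom[] <- pmax(jit(as.numeric(p$disp_rom)), 0)
  # keep the speed <-> stride-length link consistent after jitter
  p$disp_rom["sacrum", "long"] <- p$speed * p$stride_duration
  p
}

# ground-truth feature vector implied by a gait_params object (the values the
# extraction pipeline should recover at zero noise)
params_to_truth <- function(p) {
  v <- setNames(numeric(52), stride_feature_names())
  v["stride_duration"] <- p$stride_duration
  v["stance_duration"] <- p$duty_factor * p$stride_duration
  v["swing_duration"] <- (1 - p$duty_factor) * p$stride_duration
  v["speed"] <- p$disp_rom["sacrum", "long"] / p$stride_duration
  v[paste0("maxdiff_", TRUNK_LOCATIONS)] <- p$vertical_peak_asymmetry
  v[paste0("mindiff_", TRUNK_LOCATIONS)] <- 0
  v[paste0("proret_rom_", LIMB_LOCATIONS)] <- p$limb_rom[, "proret"]
  v[paste0("abdadd_rom_", LIMB_LOCATIONS)] <- p$limb_rom[, "abdadd"]
  v[paste0("introt_rom_", LIMB_LOCATIONS)] <- p$limb_rom[, "introt"]
  v[paste0("roll_rom_", TRUNK_LOCATIONS)] <- p$trunk_rom[, "roll"]
  v[paste0("pitch_rom_", TRUNK_LOCATIONS)] <- p$trunk_rom[, "pitch"]
  v[paste0("yaw_rom_", TRUNK_LOCATIONS)] <- p$trunk_rom[, "yaw"]
  v[paste0("disp_long_", ALL_LOCATIONS)] <- p$disp_rom[, "long"]
  v[paste0("disp_med_", ALL_LOCATIONS)] <- p$disp_rom[, "med"]
  v[paste0("disp_vert_", ALL_LOCATIONS)] <- p$disp_rom[, "vert"]
  v
}
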