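#' Gait profile describing one population's walking statistics
#'
#' A `gait_profile` parameterizes the synthetic gait generator: walking speed,
#' gait-cycle timing, stance fraction, the shape of the vertical ground
#' reaction force (VGRF) during stance, and the accelerometer noise level.
#'
#' The two built-in profiles emulate the populations the analysis targets:
#'
#' * `"healthy"` — self-selected speed 1.28 +/- 0.13 m/s, a pronounced
#'   double-bump VGRF (mid-stance valley 0.35 body weight below the peaks).
#' * `"mkoa"` — medial knee osteoarthritis: slower (0.75 +/- 0.23 m/s),
#'   with `vgrf_valley_depth = 0`, i.e. a flat mid-stance plateau with no
#'   interior VGRF minimum, as seen in slow/pathological walking.
#'
#' @param group `"healthy"` or `"mkoa"`; selects the defaults below.
#' @param mean_speed population mean self-selected walking speed (m/s).
#' @param speed_sd between-participant SD of self-selected speed (m/s).
#' @param cycle_duration_mean mean gait-cycle duration (s) at the population
#'   mean speed.  Cycle duration scales inversely with walking speed.
#' @param cycle_duration_cv within-record coefficient of variation of cycle
#'   duration (unitless).
#' @param stance_proportion fraction of the gait cycle spent in stance,
#'   strictly between 0 and 1.
#' @param vgrf_valley_depth depth of the mid-stance VGRF minimum below the
#'   two stance peaks, as a fraction of body weight.  `0` disables the
#'   interior minimum and yields a flat plateau between the two peak
#'   locations.
#' @param impact_sharpness unitless factor (> 0) scaling how steep the
#'   loading edge of the VGRF is and how sharp the accelerometer impact
#'   transients are.
#' @param noise_sd accelerometer noise SD as a fraction of each channel's
#'   deterministic signal scale (RMS).
#' @param body_mass_mean,body_mass_sd participant mass distribution (kg);
#'   body weight is mass times 9.81 m/s^2.
#' @return an object of class `gait_profile` (a named list).
#' @examples
#' gait_profile("healthy")
#' gait_profile("mkoa")$vgrf_valley_depth  # 0: flat mid-stance plateau
#' @export
gait_profile <- function(group = c("healthy", "mkoa"),
                         mean_speed = NULL,
                         speed_sd = NULL,
                         cycle_duration_mean = NULL,
                         cycle_duration_cv = 0.02,
                         stance_proportion = NULL,
                         vgrf_valley_depth = NULL,
                         impact_sharpness = NULL,
                         noise_sd = 0.05,
                         body_mass_mean = NULL,
                         body_mass_sd = NULL) {
  group <- match.arg(group)
  def <- if (group == "healthy") {
    list(mean_speed = 1.28, speed_sd = 0.13,
         # 0.7 x 1.514 s reproduces the 1.06 s healthy peak-finder window
         cycle_duration_mean = 1.06 / 0.7,
         stance_proportion = 0.62, vgrf_valley_depth = 0.35,
         impact_sharpness = 1.0,
         body_mass_mean = 73.11, body_mass_sd = 16.45)
  } else {
    list(mean_speed = 0.75, speed_sd = 0.23,
         cycle_duration_mean = 1.09 / 0.7,
         stance_proportion = 0.65, vgrf_valley_depth = 0,
         impact_sharpness = 0.6,
         body_mass_mean = 80.51, body_mass_sd = 15.27)
  }
  p <- list(
    group = group,
    mean_speed = mean_speed %||% def$mean_speed,
    speed_sd = speed_sd %||% def$speed_sd,
    cycle_duration_mean = cycle_duration_mean %||% def$cycle_duration_mean,
    cycle_duration_cv = cycle_duration_cv,
    stance_proportion = stance_proportion %||% def$stance_proportion,
    vgrf_valley_depth = vgrf_valley_depth %||% def$vgrf_valley_depth,
    impact_sharpness = impact_sharpness %||% def$impact_sharpness,
    noise_sd = noise_sd,
    body_mass_mean = body_mass_mean %||% def$body_mass_mean,
    body_mass_sd = body_mass_sd %||% def$body_mass_sd
  )
  check_scalar_num(p$mean_speed, "mean_speed", lower = 0, strict_lower = TRUE)
  check_scalar_num(p$speed_sd, "speed_sd", lower = 0)
  check_scalar_num(p$cycle_duration_mean, "cycle_duration_mean",
                   lower = 0, strict_lower = TRUE)
  check_scalar_num(p$cycle_duration_cv, "cycle_duration_cv", lower = 0)
  check_scalar_num(p$stance_proportion, "stance_proportion",
                   lower = 0, upper = 1, strict_lower = TRUE,
                   strict_upper = TRUE)
  check_scalar_num(p$vgrf_valley_depth, "vgrf_valley_depth", lower = 0)
  check_scalar_num(p$impact_sharpness, "impact_sharpness",
                   lower = 0, strict_lower = TRUE)
  check_scalar_num(p$noise_sd, "noise_sd", lower = 0)
  structure(p, class = "gait_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gait_profile <- function(x, ...) {
  cat(sprintf("<gait_profile: %s>\n", x$group))
  cat(sprintf("  speed        %.2f +/- %.2f m/s\n", x$mean_speed, x$speed_sd))
  cat(sprintf("  cycle        %.3f s (cv %.2f), stance %.0f%%\n",
              x$cycle_duration_mean, x$cycle_duration_cv,
              100 * x$stance_proportion))
  cat(sprintf("  VGRF valley  %.2f BW%s\n", x$vgrf_valley_depth,
              if (x$vgrf_valley_depth == 0) " (flat plateau)" else ""))
  cat(sprintf("  noise sd     %.2f x signal scale\n", x$noise_sd))
  invisible(x)
}

# Sensor locations on the lower limb: top of shoe, heel, medial malleolus,
# mid-front tibia, medial shank near the knee.
#' @export
GAIT_LOCATIONS <- c("TS", "H", "MM", "MFT", "MK")

# Axis-combination tokens for the input vector (AP, ML, V ordering within
# each combination).
#' @export
GAIT_AXES <- c("AP", "ML", "V", "AP-ML", "ML-V", "AP-V", "AP-ML-V")

# Default force-plate contact threshold (N) defining the rising/falling
# edges of the VGRF; ~3% of body weight for a 70 kg adult.
#' @export
DEFAULT_RISE_THRESHOLD <- 20
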