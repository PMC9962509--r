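# Synthetic gait generation: double-bump vertical GRF with a known event
# layout, phase-locked accelerometer waveforms at five lower-limb sensor
# locations, and seeded multi-participant datasets.

# Half-cosine ease from `from` to `to` over n samples (endpoints included).
# `q` != 1 sharpens (q < 1) or softens (q > 1) the transition; the segment
# stays strictly monotone so constructed extrema sit exactly at the knots.
.ease <- function(from, to, n, q = 1) {
  if (n == 1L) return(to)
  t <- seq(0, 1, length.out = n)
  base <- (1 - cos(pi * t)) / 2
  from + (to - from) * base^q
}

#' Generate one synthetic gait cycle of ground reaction force
#'
#' Builds a 3 x n GRF array (rows AP, ML, V) for a single gait cycle starting
#' at initial contact, together with the construction-time sample indices of
#' the five stance events (HS, HP, FF, TP, TO).  The vertical channel is a
#' double-bump curve composed of strictly monotone half-cosine segments:
#' zero during swing, a rising edge at HS, a first maximum (heel push), an
#' interior minimum (foot flat; disabled when `vgrf_valley_depth = 0`, which
#' yields a flat plateau between the two peak locations), a last maximum
#' (toe push), and a falling edge at TO.  The AP channel holds a braking
#' (negative) then propulsion (positive) lobe whose discrete integrals
#' cancel, as they must at steady treadmill speed; the ML channel is a small
#' single bump.
#'
#' Contact convention: the vertical force jumps from 0 to `rise_threshold`
#' at the HS sample and back to 0 after the TO sample, so the generator's
#' true HS/TO coincide exactly with threshold-crossing edge detection and
#' the swing phase is exactly zero.
#'
#' @param profile a [gait_profile()].
#' @param cycle_duration gait-cycle duration in seconds.
#' @param body_weight participant body weight in newtons.
#' @param fs sampling rate in Hz.
#' @param rise_threshold contact threshold in newtons (default 20 N).
#' @return list with `grf` (3 x n matrix, rows `ap`, `ml`, `v`),
#'   `events` (named integer vector `hs`, `hp`, `ff`, `tp`, `to`),
#'   `n` (samples in the cycle) and `n_stance`.
#' @examples
#' cyc <- generate_gait_cycle(gait_profile("healthy"), 1.0, 700, 200)
#' cyc$events
#' @export
generate_gait_cycle <- function(profile, cycle_duration, body_weight, fs,
                                rise_threshold = DEFAULT_RISE_THRESHOLD) {
  stopifnot(inherits(profile, "gait_profile"))
  check_scalar_num(cycle_duration, "cycle_duration", lower = 0,
                   strict_lower = TRUE)
  check_scalar_num(fs, "fs", lower = 0, strict_lower = TRUE)
  check_scalar_num(body_weight, "body_weight", lower = 0, strict_lower = TRUE)
  n <- as.integer(round(cycle_duration * fs))
  m <- as.integer(round(profile$stance_proportion * n))
  if (n < 20L || m < 8L)
    stop_invalid("cycle too short at this sampling rate to carry the five stance events")
  W <- body_weight
  depth <- profile$vgrf_valley_depth
  peak <- (1 + 0.45 * depth) * W
  valley <- peak - depth * W
  if (rise_threshold >= valley)
    stop_invalid("rise_threshold exceeds the mid-stance force; lower it or raise body_weight")
  q <- 1 / profile$impact_sharpness

  # stance knots (relative samples 1..m)
  k_hp <- 1L + as.integer(round(0.25 * (m - 1L)))
  k_ff <- 1L + as.integer(round(0.50 * (m - 1L)))
  k_tp <- 1L + as.integer(round(0.75 * (m - 1L)))

  v <- numeric(n)
  v[1:k_hp] <- .ease(rise_threshold, peak, k_hp, q = q)
  v[k_hp:k_ff] <- .ease(peak, valley, k_ff - k_hp + 1L)
  v[k_ff:k_tp] <- .ease(valley, peak, k_tp - k_ff + 1L)
  v[k_tp:m] <- .ease(peak, rise_threshold, m - k_tp + 1L, q = q)

  # AP: braking lobe up to the mid-stance knot, propulsion after; the
  # propulsion amplitude is scaled so the sampled impulses cancel exactly.
  ap <- numeric(n)
  brake <- sin(pi * seq(0, 1, length.out = k_ff))^2
  prop <- sin(pi * seq(0, 1, length.out = m - k_ff + 1L))^2
  amp_b <- 0.18 * W
  amp_p <- amp_b * sum(brake) / sum(prop)
  ap[1:k_ff] <- -amp_b * brake
  ap[k_ff:m] <- ap[k_ff:m] + amp_p * prop

  ml <- numeric(n)
  ml[1:m] <- 0.05 * W * sin(pi * seq(0, 1, length.out = m))^2

  ff <- if (depth > 0) k_ff else as.integer(round((k_hp + k_tp) / 2))
  grf <- rbind(ap = ap, ml = ml, v = v)
  list(grf = grf,
       events = c(hs = 1L, hp = k_hp, ff = ff, tp = k_tp, to = m),
       n = n, n_stance = m)
}

# Per-location accelerometer shape parameters.  `imp` is the impact-pulse
# amplitude (m/s^2) at heel strike, `w` its Gaussian width (s), `snr` a
# relative measurement signal-to-noise factor, `coupling` the fraction of
# the waveform that is locked to the gait cycle (the remainder is
# cycle-independent distractor oscillation: proximal segments' acceleration
# reflects the foot-ground interaction less directly), `osc` harmonic
# amplitudes per axis, `phase0` a location phase offset so waveform shapes
# differ between locations.  Top-of-shoe (TS) is constructed as the most
# informative location: sharpest impacts, highest coupling and SNR.
.gait_loc_params <- list(
  TS  = list(imp = 35, w = 0.015, snr = 3.0, coupling = 0.95, phase0 = 0.0,
             osc = list(ap = c(3.0, 1.5, 0.8), ml = c(1.0, 0.6, 0.3),
                        v = c(4.0, 2.0, 1.0))),
  H   = list(imp = 30, w = 0.020, snr = 1.5, coupling = 0.80, phase0 = 0.7,
             osc = list(ap = c(2.5, 1.2, 0.6), ml = c(1.2, 0.5, 0.3),
                        v = c(3.5, 1.5, 0.8))),
  MM  = list(imp = 20, w = 0.025, snr = 1.2, coupling = 0.75, phase0 = 1.4,
             osc = list(ap = c(2.0, 1.0, 0.5), ml = c(1.5, 0.7, 0.4),
                        v = c(3.0, 1.2, 0.6))),
  MFT = list(imp = 14, w = 0.030, snr = 1.0, coupling = 0.70, phase0 = 2.1,
             osc = list(ap = c(1.8, 0.9, 0.5), ml = c(1.2, 0.8, 0.4),
                        v = c(2.5, 1.0, 0.5))),
  MK  = list(imp = 9,  w = 0.040, snr = 0.8, coupling = 0.60, phase0 = 2.8,
             osc = list(ap = c(1.5, 0.8, 0.4), ml = c(1.0, 0.7, 0.5),
                        v = c(2.0, 0.9, 0.5)))
)

#' Generate a continuous GRF record from a sequence of cycle durations
#'
#' Concatenates [generate_gait_cycle()] outputs after a zero-force lead-in,
#' truncating to `duration`.  Only cycles that fit entirely in the record
#' carry truth events.
#'
#' @param profile a [gait_profile()].
#' @param cycle_durations vector of cycle durations (s); each is quantized so
#'   cycles start on a shared IMU/GRF sample grid.
#' @param body_weight newtons.
#' @param fs_grf GRF sampling rate (Hz).
#' @param duration record duration (s).
#' @param lead_in zero-force lead-in before the first heel strike (s).
#' @param fs_imu IMU sampling rate (Hz); used only to quantize cycle starts
#'   onto the common clock grid.
#' @param rise_threshold contact threshold (N).
#' @return list with `grf` (3 x T_grf), `cycles` (data.frame of per-cycle
#'   start sample, duration and absolute truth event indices on the GRF
#'   clock, with a `complete` flag), `fs_grf`, `duration`.
#' @export
generate_grf_record <- function(profile, cycle_durations, body_weight,
                                fs_grf = 1000, duration = NULL,
                                lead_in = 0.3, fs_imu = 200,
                                rise_threshold = DEFAULT_RISE_THRESHOLD) {
  L <- fs_grf / fs_imu
  if (abs(L - round(L)) > 1e-9)
    stop_invalid("fs_grf must be an integer multiple of fs_imu")
  L <- as.integer(round(L))
  n_cyc <- pmax(20L, as.integer(round(cycle_durations * fs_grf / L)) * L)
  if (is.null(duration)) duration <- lead_in + sum(n_cyc) / fs_grf
  T_grf <- as.integer(round(duration * fs_grf))
  grf <- matrix(0, 3L, T_grf, dimnames = list(c("ap", "ml", "v"), NULL))
  off <- as.integer(round(lead_in * fs_grf / L)) * L
  rows <- vector("list", length(n_cyc))
  for (j in seq_along(n_cyc)) {
    if (off >= T_grf) break
    cyc <- generate_gait_cycle(profile, n_cyc[j] / fs_grf, body_weight,
                               fs_grf, rise_threshold)
    keep <- min(cyc$n, T_grf - off)
    grf[, off + seq_len(keep)] <- cyc$grf[, seq_len(keep), drop = FALSE]
    rows[[j]] <- data.frame(
      start = off + 1L, n = cyc$n,
      duration = cyc$n / fs_grf,
      hs = off + cyc$events[["hs"]], hp = off + cyc$events[["hp"]],
      ff = off + cyc$events[["ff"]], tp = off + cyc$events[["tp"]],
      to = off + cyc$events[["to"]],
      # a cycle is labellable when its stance and at least one zero sample
      # after toe off fit in the record (the falling edge is confirmed even
      # if the trailing swing is truncated)
      complete = (off + cyc$events[["to"]]) < T_grf
    )
    off <- off + cyc$n
  }
  cycles <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  list(grf = grf, cycles = cycles, fs_grf = fs_grf, duration = duration)
}

#' Generate tri-axial accelerometer signals for one sensor location
#'
#' Produces a 3 x T_imu acceleration array (rows AP, ML, V) deterministically
#' coupled to the gait cycle described by `cycle_seq`: a location-specific
#' harmonic series of the cycle phase plus Gaussian impact transients locked
#' to the true heel-strike and toe-off times, with additive Gaussian noise
#' scaled by `profile$noise_sd` and the location's signal-to-noise factor.
#' With `noise_sd = 0` the output is a deterministic function of the cycle
#' sequence.
#'
#' @param cycle_seq the list returned by [generate_grf_record()].
#' @param profile a [gait_profile()].
#' @param location one of `"TS"`, `"H"`, `"MM"`, `"MFT"`, `"MK"`.
#' @param fs_imu IMU sampling rate (Hz).
#' @param noise_sd overrides `profile$noise_sd` when not `NULL`.
#' @return 3 x T_imu matrix with rows `ap`, `ml`, `v` (m/s^2).
#' @export
generate_imu_signals <- function(cycle_seq, profile, location, fs_imu = 200,
                                 noise_sd = NULL) {
  if (!location %in% names(.gait_loc_params))
    stop_invalid("unknown sensor location '", location,
                 "'; expected one of ", paste(GAIT_LOCATIONS, collapse = ", "))
  lp <- .gait_loc_params[[location]]
  noise_sd <- noise_sd %||% profile$noise_sd
  fs_grf <- cycle_seq$fs_grf
  T_imu <- as.integer(round(cycle_seq$duration * fs_imu))
  t <- (seq_len(T_imu) - 1) / fs_imu
  cyc <- cycle_seq$cycles
  starts_t <- (cyc$start - 1) / fs_grf
  j <- findInterval(t, starts_t)
  j[j < 1L] <- 1L
  j[j > nrow(cyc)] <- nrow(cyc)
  phase <- ((t - starts_t[j]) / cyc$duration[j]) %% 1

  axis_off <- c(ap = 0, ml = 1.0, v = 2.0)
  out <- matrix(0, 3L, T_imu, dimnames = list(c("ap", "ml", "v"), NULL))
  sharp <- profile$impact_sharpness
  for (ax in c("ap", "ml", "v")) {
    a <- lp$osc[[ax]]
    sig <- numeric(T_imu)
    for (k in seq_along(a))
      sig <- sig + a[k] * cos(2 * pi * k * phase + lp$phase0 + 0.9 * k +
                                axis_off[[ax]])
    out[ax, ] <- sig
  }
  # impact transients on AP and V at heel strike, a softer one at toe off
  hs_t <- (cyc$hs - 1) / fs_grf
  to_t <- (cyc$to - 1) / fs_grf
  w <- lp$w
  for (i in seq_len(nrow(cyc))) {
    for (spec in list(c(hs_t[i], 1), c(to_t[i], 0.5))) {
      win <- which(abs(t - spec[1]) < 5 * w)
      if (!length(win)) next
      pulse <- lp$imp * sharp * spec[2] *
        exp(-(t[win] - spec[1])^2 / (2 * w^2))
      out["ap", win] <- out["ap", win] + pulse
      out["v", win] <- out["v", win] - pulse
    }
  }
  # mix with cycle-independent distractor oscillation: only a location's
  # `coupling` fraction of the waveform is locked to the gait cycle, the
  # rest reflects motion unrelated to foot-ground interaction (random
  # phases per record and channel)
  for (ax in c("ap", "ml", "v")) {
    scale <- stats::sd(out[ax, ])
    ph <- stats::runif(2, 0, 2 * pi)
    distract <- scale * (0.8 * sin(2 * pi * 1.3 * t + ph[1]) +
                           0.6 * sin(2 * pi * 2.9 * t + ph[2]))
    out[ax, ] <- lp$coupling * out[ax, ] + (1 - lp$coupling) * distract
  }
  out["v", ] <- out["v", ] + 9.81
  if (noise_sd > 0) {
    for (ax in c("ap", "ml", "v")) {
      scale <- stats::sd(out[ax, ])
      out[ax, ] <- out[ax, ] +
        stats::rnorm(T_imu, 0, noise_sd * scale / lp$snr)
    }
  }
  out
}

.draw_truncnorm <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a seeded synthetic gait dataset
#'
#' Emulates the study design: `n_healthy` + `n_mkoa` participants each walk
#' at up to three speed conditions (self-selected, 20% faster, 20% slower),
#' yielding one continuous record per condition.  Per participant a
#' self-selected speed and a body weight are drawn from the group profile;
#' cycle duration scales inversely with condition speed, so every
#' participant's fast record has shorter cycles than the self-selected one,
#' which is shorter than the slow one.  GRF is generated at `fs_grf`
#' (noise-free, with exact swing-phase zeros) and the five accelerometer
#' signals at `fs_imu`; both clocks share t = 0.
#'
#' The default 27 + 18 participants x 3 speeds reproduce the study's 135
#' continuous records.
#'
#' @param n_healthy,n_mkoa participant counts (>= 0, at least one total).
#' @param speeds_per_participant 1–3 conditions, in the order self-selected,
#'   fast, slow.
#' @param duration record duration in seconds (must hold at least 3 complete
#'   cycles at the slowest condition).
#' @param profiles named list with elements `healthy` and `mkoa`
#'   ([gait_profile()] objects).
#' @param seed integer; regeneration with the same seed and configuration is
#'   bit-identical.
#' @param fs_imu,fs_grf sampling rates (Hz); `fs_grf` must be an integer
#'   multiple of `fs_imu`.
#' @param lead_in zero-force lead-in (s) before the first heel strike.
#' @param rise_threshold contact threshold (N) defining true HS/TO.
#' @return object of class `gait_dataset`: list of `gait_record`s plus the
#'   generating configuration.  Each record carries the generator's truth
#'   (`$truth$cycles`): per-cycle absolute sample indices of the five events
#'   on the GRF clock.
#' @examples
#' ds <- generate_dataset(n_healthy = 2, n_mkoa = 1, duration = 10, seed = 1)
#' ds
#' @export
generate_dataset <- function(n_healthy = 27, n_mkoa = 18,
                             speeds_per_participant = 3,
                             duration = 30,
                             profiles = list(healthy = gait_profile("healthy"),
                                             mkoa = gait_profile("mkoa")),
                             seed = 1,
                             fs_imu = 200, fs_grf = 1000,
                             lead_in = 0.3,
                             rise_threshold = DEFAULT_RISE_THRESHOLD) {
  if (n_healthy < 0 || n_mkoa < 0 || n_healthy + n_mkoa < 1)
    stop_invalid("need at least one participant")
  if (!speeds_per_participant %in% 1:3)
    stop_invalid("speeds_per_participant must be 1, 2 or 3")
  check_scalar_num(duration, "duration", lower = 0, strict_lower = TRUE)
  conditions <- c("self_selected", "fast", "slow")[seq_len(speeds_per_participant)]
  factors <- c(self_selected = 1, fast = 1.2, slow = 0.8)

  records <- list()
  with_seed(seed, {
    for (group in c("healthy", "mkoa")) {
      n_p <- if (group == "healthy") n_healthy else n_mkoa
      if (n_p == 0) next
      prof <- profiles[[group]]
      for (p in seq_len(n_p)) {
        pid <- sprintf("%s%02d", if (group == "healthy") "H" else "K", p)
        v_ss <- .draw_truncnorm(1, prof$mean_speed, prof$speed_sd, 0.25)
        mass <- .draw_truncnorm(1, prof$body_mass_mean, prof$body_mass_sd, 40)
        bw <- mass * 9.81
        for (cond in conditions) {
          base_cycle <- prof$cycle_duration_mean * prof$mean_speed /
            (v_ss * factors[[cond]])
          n_cycles <- as.integer(ceiling((duration - lead_in) / base_cycle)) + 2L
          durs <- stats::rnorm(n_cycles, base_cycle,
                               prof$cycle_duration_cv * base_cycle)
          durs <- pmin(pmax(durs, 0.6 * base_cycle), 1.4 * base_cycle)
          seq_grf <- generate_grf_record(prof, durs, bw, fs_grf,
                                         duration = duration,
                                         lead_in = lead_in, fs_imu = fs_imu,
                                         rise_threshold = rise_threshold)
          if (sum(seq_grf$cycles$complete) < 3L)
            stop_invalid("duration ", duration,
                         " s is too short for 3 complete cycles at the ",
                         cond, " speed of participant ", pid)
          acc <- lapply(stats::setNames(GAIT_LOCATIONS, GAIT_LOCATIONS),
                        function(loc)
                          generate_imu_signals(seq_grf, prof, loc, fs_imu))
          rec <- structure(list(
            record_id = paste0(pid, "_", cond),
            participant_id = pid,
            group = group,
            speed_condition = cond,
            speed = v_ss * factors[[cond]],
            body_weight = bw,
            acc = acc,
            grf = seq_grf$grf,
            fs_imu = fs_imu,
            fs_grf = fs_grf,
            duration = duration,
            truth = list(cycles = seq_grf$cycles[seq_grf$cycles$complete, ,
                                                 drop = FALSE])
          ), class = "gait_record")
          records[[rec$record_id]] <- rec
        }
      }
    }
  })
  structure(list(
    records = records,
    seed = seed,
    config = list(n_healthy = n_healthy, n_mkoa = n_mkoa,
                  speeds_per_participant = speeds_per_participant,
                  duration = duration, profiles = profiles,
                  fs_imu = fs_imu, fs_grf = fs_grf, lead_in = lead_in,
                  rise_threshold = rise_threshold)
  ), class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  groups <- vapply(x$records, function(r) r$group, character(1))
  cat(sprintf("<gait_dataset: %d records (%d healthy, %d mkoa), seed %d>\n",
              length(x$records), sum(groups == "healthy"),
              sum(groups == "mkoa"), x$seed))
  cat(sprintf("  %g s per record, IMU %g Hz, GRF %g Hz\n",
              x$config$duration, x$config$fs_imu, x$config$fs_grf))
  invisible(x)
}

#' @export
print.gait_record <- function(x, ...) {
  cat(sprintf("<gait_record %s: %s/%s, %g s, %.0f N, %d labelled cycles>\n",
              x$record_id, x$group, x$speed_condition, x$duration,
              x$body_weight, nrow(x$truth$cycles)))
  invisible(x)
}
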