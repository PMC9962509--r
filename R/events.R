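# Labelling the five stance-phase events from the measured vertical GRF,
# building the binary event target and the weight-normalized force target,
# and deriving temporal gait parameters.

#' Detect the five stance events from a vertical GRF trace
#'
#' Stance bouts are delimited by threshold crossings of the vertical force:
#' HS is the first sample at or above `rise_threshold` after a sub-threshold
#' interval (the rising edge) and TO the last such sample before the force
#' falls back below it (the falling edge).  Within each bout, HP is the
#' first local maximum after HS and TP the last local maximum before TO;
#' FF is the global interior minimum strictly between HP and TP, or the
#' rounded HP–TP midpoint when no interior minimum exists (the flat-valley
#' pattern of slow and knee-osteoarthritis gait).  Flat-topped extrema are
#' assigned their centre sample; when a single maximal plateau spans the
#' whole mid-stance (the flat-valley case), its first and last samples serve
#' as HP and TP, i.e. the ends of the rising and falling edges.
#'
#' Bouts touching the record edges are dropped: their rising or falling edge
#' cannot be confirmed.
#'
#' @param vgrf numeric vector, vertical GRF in newtons (non-negative).
#' @param fs sampling rate in Hz.
#' @param rise_threshold edge-detection threshold in newtons.
#' @return object of class `event_set`: list with `cycles` (list of named
#'   integer vectors `hs`, `hp`, `ff`, `tp`, `to`) and `fs`.  Empty (with a
#'   warning) when no complete stance bout exists.
#' @examples
#' cyc <- generate_gait_cycle(gait_profile("healthy"), 1.0, 700, 1000)
#' v <- c(numeric(100), rep(cyc$grf["v", ], 3), numeric(100))
#' ev <- detect_events_from_vgrf(v, 1000)
#' ev$cycles[[1]]
#' @export
detect_events_from_vgrf <- function(vgrf, fs,
                                    rise_threshold = DEFAULT_RISE_THRESHOLD) {
  if (!is.numeric(vgrf)) stop_invalid("'vgrf' must be numeric")
  check_scalar_num(fs, "fs", lower = 0, strict_lower = TRUE)
  check_scalar_num(rise_threshold, "rise_threshold", lower = 0,
                   strict_lower = TRUE)
  if (any(vgrf < -1e-9))
    stop_invalid("'vgrf' has negative samples; vertical GRF must be non-negative")
  T <- length(vgrf)
  above <- vgrf >= rise_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bouts <- which(r$values)
  cycles <- list()
  for (b in bouts) {
    s <- starts[b]; e <- ends[b]
    if (s == 1L || e == T) next  # incomplete bout at a record edge
    seg <- vgrf[s:e]
    ex <- local_extrema_runs(seg)
    mx <- ex$maxima
    if (nrow(mx) == 0L) {
      # monotone or edge-peaked bout: no interior maximum to anchor HP/TP
      next
    }
    if (nrow(mx) == 1L && (mx$end[1] - mx$start[1]) >= 1L) {
      # one maximal plateau spanning mid-stance: ends act as HP and TP
      hp <- mx$start[1]; tp <- mx$end[1]
    } else {
      hp <- mx$centre[1]
      tp <- mx$centre[nrow(mx)]
    }
    if (hp <= 1L || tp >= length(seg) || hp >= tp) next
    mn <- ex$minima
    mn <- mn[mn$centre > hp & mn$centre < tp, , drop = FALSE]
    ff <- if (nrow(mn) > 0L) mn$centre[which.min(mn$value)]
          else as.integer(round((hp + tp) / 2))
    cycles[[length(cycles) + 1L]] <-
      c(hs = s, hp = s - 1L + as.integer(hp), ff = s - 1L + as.integer(ff),
        tp = s - 1L + as.integer(tp), to = e)
  }
  if (length(cycles) == 0L)
    warning("no complete stance bout found; returning an empty event set")
  structure(list(cycles = cycles, fs = fs), class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set: %d cycles at %g Hz>\n", length(x$cycles), x$fs))
  invisible(x)
}

#' Convert an event set to another sampling clock
#'
#' Maps every event index to the nearest sample on the target clock (used to
#' carry force-plate-derived labels onto the IMU clock).
#'
#' @param events an `event_set`.
#' @param fs_to target sampling rate (Hz).
#' @return an `event_set` on the target clock.
#' @export
events_to_clock <- function(events, fs_to) {
  stopifnot(inherits(events, "event_set"))
  cycles <- lapply(events$cycles, function(ev) {
    out <- map_index_to_clock(ev, events$fs, fs_to)
    names(out) <- names(ev)
    out
  })
  structure(list(cycles = cycles, fs = fs_to), class = "event_set")
}

#' Build the 5 x T binary gait-event target
#'
#' One row per event (HS, HP, FF, TP, TO); each labelled cycle contributes
#' exactly one 1 per row, all other entries are 0.
#'
#' @param events an `event_set` on the target clock.
#' @param T number of samples.
#' @return 5 x T binary matrix with rownames `hs`, `hp`, `ff`, `tp`, `to`.
#' @export
build_ged_target <- function(events, T) {
  stopifnot(inherits(events, "event_set"))
  T <- as.integer(T)
  y <- matrix(0, 5L, T, dimnames = list(c("hs", "hp", "ff", "tp", "to"), NULL))
  for (ev in events$cycles) {
    if (any(ev > T) || any(ev < 1L))
      stop_invalid("event index outside [1, T]")
    for (nm in rownames(y)) y[nm, ev[[nm]]] <- 1
  }
  y
}

#' Build the weight-normalized GRF target
#'
#' Divides the 3 x T force array elementwise by the participant's body
#' weight so targets are unitless multiples of body weight.
#'
#' @param grf 3 x T numeric matrix (rows AP, ML, V) in newtons.
#' @param body_weight body weight in newtons (> 0).
#' @return 3 x T matrix with rownames `ap`, `ml`, `v`.
#' @export
build_grf_target <- function(grf, body_weight) {
  if (!is.matrix(grf) || nrow(grf) != 3L)
    stop_invalid("'grf' must be a 3 x T matrix")
  check_scalar_num(body_weight, "body_weight", lower = 0, strict_lower = TRUE)
  out <- grf / body_weight
  rownames(out) <- c("ap", "ml", "v")
  out
}

#' Temporal gait parameters from labelled events
#'
#' Per cycle i (needing the next cycle's HS): cycle duration
#' (HS[i+1] − HS[i]) / fs, stance duration (TO[i] − HS[i]) / fs by the
#' conventional HS-to-TO stance definition (`stance_rule = "hs_ff"` instead
#' measures HS to FF), and their ratio, plus record means.
#'
#' @param events an `event_set` with at least 2 cycles.
#' @param stance_rule `"hs_to"` (default) or `"hs_ff"`.
#' @return list of class `temporal_parameters`: `per_cycle` data.frame with
#'   columns `cycle_duration`, `stance_duration`, `stance_proportion` (s /
#'   s / unitless) and the record means `mean_cycle_duration`,
#'   `mean_stance_duration`, `mean_stance_proportion`.
#' @export
compute_temporal_parameters <- function(events,
                                        stance_rule = c("hs_to", "hs_ff")) {
  stopifnot(inherits(events, "event_set"))
  stance_rule <- match.arg(stance_rule)
  n <- length(events$cycles)
  if (n < 2L)
    stop_invalid("need at least 2 labelled cycles to measure cycle duration")
  hs <- vapply(events$cycles, function(x) as.numeric(x[["hs"]]), numeric(1))
  end_ev <- if (stance_rule == "hs_to") "to" else "ff"
  stance_end <- vapply(events$cycles, function(x) as.numeric(x[[end_ev]]), numeric(1))
  fs <- events$fs
  cd <- diff(hs) / fs
  sd_ <- (stance_end[-n] - hs[-n]) / fs
  per <- data.frame(cycle = seq_len(n - 1L),
                    cycle_duration = cd,
                    stance_duration = sd_,
                    stance_proportion = sd_ / cd)
  structure(list(per_cycle = per,
                 mean_cycle_duration = mean(cd),
                 mean_stance_duration = mean(sd_),
                 mean_stance_proportion = mean(sd_ / cd)),
            class = "temporal_parameters")
}

#' @export
print.temporal_parameters <- function(x, ...) {
  cat(sprintf(paste0("<temporal_parameters: %d cycles; cycle %.3f s, ",
                     "stance %.3f s (%.1f%%)>\n"),
              nrow(x$per_cycle), x$mean_cycle_duration,
              x$mean_stance_duration, 100 * x$mean_stance_proportion))
  invisible(x)
}

#' Anti-alias filter and decimate a signal onto the IMU clock
#'
#' Applies a zero-phase windowed-sinc (Blackman) low-pass FIR with cutoff at
#' 90% of the target Nyquist frequency, then keeps every
#' `fs_from / fs_to`-th sample.  Edges are reflection-padded; the first and
#' last half filter length carry the usual edge transient.
#'
#' @param x numeric vector or k x T matrix.
#' @param fs_from,fs_to source and target sampling rates (Hz); `fs_from`
#'   must be a positive integer multiple of `fs_to`.
#' @return vector or k x T_out matrix on the target clock.
#' @export
resample_to_imu_clock <- function(x, fs_from, fs_to) {
  check_scalar_num(fs_from, "fs_from", lower = 0, strict_lower = TRUE)
  check_scalar_num(fs_to, "fs_to", lower = 0, strict_lower = TRUE)
  if (fs_from < fs_to) stop_invalid("fs_from must be >= fs_to")
  L <- fs_from / fs_to
  if (abs(L - round(L)) > 1e-9)
    stop_invalid("fs_from / fs_to must be an integer decimation factor")
  L <- as.integer(round(L))
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, resample_to_imu_clock, fs_from = fs_from,
                   fs_to = fs_to))
    rownames(out) <- rownames(x)
    return(out)
  }
  if (L == 1L) return(x)
  T <- length(x)
  M <- 15L * L  # half filter length
  k <- (-M):M
  fc <- 0.45 / L  # cycles per input sample
  h <- 2 * fc * sinc(2 * fc * k)
  # Blackman window
  wq <- (k + M) / (2 * M)
  h <- h * (0.42 - 0.5 * cos(2 * pi * wq) + 0.08 * cos(4 * pi * wq))
  h <- h / sum(h)
  if (T <= M)
    stop_invalid("signal too short to decimate (need more than ", M, " samples)")
  pad_l <- x[pmin(M + 1L, T):2L]
  pad_r <- x[(T - 1L):max(1L, T - M)]
  xp <- c(pad_l, x, pad_r)
  y <- stats::filter(xp, h, method = "convolution", sides = 2L)
  y <- as.numeric(y[(length(pad_l) + 1L):(length(pad_l) + T)])
  y[seq(1L, T, by = L)]
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
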