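# Scoring: peak detection on readout outputs, one-to-one event matching,
# record-weighted mean absolute error for events (ms) and forces (body
# weight fractions), and gait-cycle percentage zones.

# The evaluation zones: whole cycle, weight-acceptance (passive) peak and
# push-off (active) peak windows, in percent of the gait cycle.
#' @export
DEFAULT_ZONES <- list("(0,100)" = c(0, 100),
                      "(10,18)" = c(10, 18),
                      "(44,52)" = c(44, 52))

#' Detect event peaks in a readout output row
#'
#' Returns local maxima (plateau centres) whose height reaches
#' `relative_height_floor` times the row maximum, thinned so surviving
#' peaks are at least `min_peak_distance` apart; when two candidates are
#' closer, the higher one survives.  A `min_peak_distance` of 0 returns all
#' local maxima above the floor.
#'
#' @param y_row numeric vector (one event type's readout output).
#' @param fs sampling rate (Hz).
#' @param min_peak_distance minimum peak separation in seconds; derived per
#'   group as 0.7 x the mean training-set gait-cycle duration (see
#'   [peak_distance_for_group()]).
#' @param relative_height_floor fraction of the row maximum below which
#'   candidates are ignored.
#' @return integer vector of peak indices, sorted increasing (possibly
#'   empty).
#' @export
detect_predicted_events <- function(y_row, fs, min_peak_distance,
                                    relative_height_floor = 0.3) {
  if (length(y_row) < 2L) stop_invalid("need at least 2 samples")
  check_scalar_num(fs, "fs", lower = 0, strict_lower = TRUE)
  check_scalar_num(min_peak_distance, "min_peak_distance", lower = 0)
  top <- max(y_row)
  if (!is.finite(top) || top <= 0) return(integer(0))
  ex <- local_extrema_runs(y_row)
  mx <- ex$maxima[ex$maxima$value >= relative_height_floor * top, ,
                  drop = FALSE]
  if (nrow(mx) == 0L) return(integer(0))
  min_sep <- min_peak_distance * fs
  ord <- order(-mx$value, mx$centre)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(mx$centre[i] - kept) >= min_sep))
      kept <- c(kept, mx$centre[i])
  }
  sort(as.integer(kept))
}

#' Per-group peak-finder separation window
#'
#' 0.7 times the mean gait-cycle duration of the group's training records —
#' the rule that yields 1.06 s for healthy and 1.09 s for knee-OA walkers
#' at those groups' mean cadences.
#'
#' @param mean_cycle_duration mean training-set cycle duration (s).
#' @return minimum peak separation in seconds.
#' @export
peak_distance_for_group <- function(mean_cycle_duration) {
  check_scalar_num(mean_cycle_duration, "mean_cycle_duration", lower = 0,
                   strict_lower = TRUE)
  0.7 * mean_cycle_duration
}

#' Match target events to predicted peaks
#'
#' One-to-one greedy matching by increasing absolute distance: each target
#' index is paired with its closest available predicted peak.  Unmatched
#' targets (no peaks left) are counted and excluded from error statistics.
#'
#' @param target_indices,predicted_indices sorted integer sample indices.
#' @param fs sampling rate (Hz).
#' @return list of class `event_match`: `pairs` data.frame
#'   (`target`, `predicted`, `error_ms`), `n_unmatched`, `mae_ms` (NA when
#'   nothing matched).
#' @export
match_events <- function(target_indices, predicted_indices, fs) {
  check_scalar_num(fs, "fs", lower = 0, strict_lower = TRUE)
  nt <- length(target_indices)
  np <- length(predicted_indices)
  if (nt == 0L)
    return(structure(list(pairs = data.frame(target = integer(0),
                                             predicted = integer(0),
                                             error_ms = numeric(0)),
                          n_unmatched = 0L, mae_ms = NA_real_),
                     class = "event_match"))
  if (np == 0L)
    return(structure(list(pairs = data.frame(target = integer(0),
                                             predicted = integer(0),
                                             error_ms = numeric(0)),
                          n_unmatched = nt, mae_ms = NA_real_),
                     class = "event_match"))
  d <- abs(outer(target_indices, predicted_indices, `-`))
  ord <- order(d)
  used_t <- logical(nt)
  used_p <- logical(np)
  ti <- pi_ <- err <- integer(0)
  for (idx in ord) {
    i <- (idx - 1L) %% nt + 1L
    j <- (idx - 1L) %/% nt + 1L
    if (used_t[i] || used_p[j]) next
    used_t[i] <- TRUE
    used_p[j] <- TRUE
    ti <- c(ti, target_indices[i])
    pi_ <- c(pi_, predicted_indices[j])
    err <- c(err, d[i, j])
    if (all(used_t) || all(used_p)) break
  }
  o <- order(ti)
  pairs <- data.frame(target = ti[o], predicted = pi_[o],
                      error_ms = err[o] / fs * 1000)
  structure(list(pairs = pairs, n_unmatched = sum(!used_t),
                 mae_ms = mean(pairs$error_ms)),
            class = "event_match")
}

#' Record-weighted event MAE
#'
#' The error metric is the mean over records of the per-record mean
#' absolute error — every record counts equally regardless of how many
#' cycles it contains (not a pooled pair-weighted mean).
#'
#' @param reports data.frame with columns `record`, `event`, `error_ms`
#'   (one row per matched pair), plus optionally `n_unmatched` bookkeeping
#'   passed through `unmatched`.
#' @param unmatched optional named vector of unmatched-target counts per
#'   event type.
#' @return data.frame with columns `event`, `mae_ms` (NA when an event type
#'   has no matches), `n_records`, `n_unmatched`.
#' @export
compute_event_mae <- function(reports, unmatched = NULL) {
  stopifnot(is.data.frame(reports),
            all(c("record", "event", "error_ms") %in% names(reports)))
  events <- unique(reports$event)
  out <- lapply(events, function(ev) {
    sub <- reports[reports$event == ev, , drop = FALSE]
    per_rec <- tapply(sub$error_ms, sub$record, mean)
    data.frame(event = ev, mae_ms = mean(per_rec),
               n_records = length(per_rec),
               n_unmatched = if (is.null(unmatched)) 0L
                             else unmatched[[ev]] %||% 0L)
  })
  do.call(rbind, out)
}

#' Boolean gait-cycle zone mask
#'
#' For each pair of consecutive heel strikes `[HS_i, HS_{i+1})` in `events`,
#' samples whose cycle-phase percentage lies in `[lo, hi)` are marked TRUE.
#' The `(0, 100)` zone therefore covers exactly the samples inside complete
#' cycles.
#'
#' @param events an `event_set` on the clock of the masked signal.
#' @param zone numeric `c(lo, hi)` in percent, `0 <= lo < hi <= 100`.
#' @param T number of samples.
#' @return logical vector of length `T`.
#' @export
zone_mask <- function(events, zone, T) {
  stopifnot(inherits(events, "event_set"), length(zone) == 2L)
  if (!(zone[1] >= 0 && zone[1] < zone[2] && zone[2] <= 100))
    stop_invalid("zone must satisfy 0 <= lo < hi <= 100")
  mask <- logical(T)
  hs <- vapply(events$cycles, function(x) as.numeric(x[["hs"]]), numeric(1))
  if (length(hs) < 2L) return(mask)
  for (i in seq_len(length(hs) - 1L)) {
    s <- hs[i]; e <- hs[i + 1L]
    idx <- s:(e - 1L)
    idx <- idx[idx >= 1L & idx <= T]
    phase <- (idx - s) / (e - s) * 100
    mask[idx[phase >= zone[1] & phase < zone[2]]] <- TRUE
  }
  mask
}

#' Record-weighted GRF MAE per axis
#'
#' For each record and axis, the mean absolute prediction error over the
#' masked samples (in body-weight fractions), then the mean over records.
#'
#' @param preds,targets lists of 3 x T matrices (rows `ap`, `ml`, `v`), one
#'   per record.
#' @param masks list of logical vectors, one per record.
#' @return data.frame with columns `axis`, `mae`, `n_records`; `mae` is NA
#'   when every record's mask is empty.
#' @export
compute_grf_mae <- function(preds, targets, masks) {
  stopifnot(length(preds) == length(targets),
            length(preds) == length(masks))
  axes <- c("ap", "ml", "v")
  per_rec <- matrix(NA_real_, length(preds), 3L,
                    dimnames = list(NULL, axes))
  for (p in seq_along(preds)) {
    if (!identical(dim(preds[[p]]), dim(targets[[p]])))
      stop_invalid("record ", p, ": prediction and target shapes differ")
    m <- masks[[p]]
    if (!any(m)) next
    per_rec[p, ] <- rowMeans(abs(preds[[p]][, m, drop = FALSE] -
                                   targets[[p]][, m, drop = FALSE]))
  }
  ok <- stats::complete.cases(per_rec)
  data.frame(axis = axes,
             mae = if (any(ok)) colMeans(per_rec[ok, , drop = FALSE])
                   else rep(NA_real_, 3L),
             n_records = sum(ok))
}
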