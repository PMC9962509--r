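# End-to-end fitting: one shared reservoir trajectory per record feeds two
# linear readouts (gait events and ground reaction force), trained by
# standard or temporal-parameter-kernel ridge regression on the first part
# of every record and scored on the held-out remainder.

.parse_axes <- function(axes) {
  if (!axes %in% GAIT_AXES)
    stop_invalid("unknown axes token '", axes, "'; expected one of ",
                 paste(GAIT_AXES, collapse = ", "))
  tolower(strsplit(axes, "-", fixed = TRUE)[[1]])
}

#' Build the reservoir input sequence for one record
#'
#' Row 1 is the constant bias 1; the remaining rows are the selected
#' acceleration axes of the chosen sensor location, in AP, ML, V order.
#'
#' @param record a `gait_record`.
#' @param location sensor location (`"TS"`, `"H"`, `"MM"`, `"MFT"`, `"MK"`).
#' @param axes axis-combination token (one of `"AP"`, `"ML"`, `"V"`,
#'   `"AP-ML"`, `"ML-V"`, `"AP-V"`, `"AP-ML-V"`).
#' @return (1 + n_axes) x T_imu matrix.
#' @export
build_input_vector <- function(record, location, axes) {
  stopifnot(inherits(record, "gait_record"))
  if (!location %in% names(record$acc))
    stop_invalid("location '", location, "' not present in record")
  rows <- .parse_axes(axes)
  rbind(bias = 1, record$acc[[location]][rows, , drop = FALSE])
}

#' Split a record into contiguous training and testing segments
#'
#' The training segment is the first `round(train_fraction * T_imu)` IMU
#' samples; the GRF channel is cut at the same time point.  Truth events are
#' retained for cycles falling entirely inside a segment (test-segment
#' indices are re-based to the segment start).
#'
#' @param record a `gait_record`.
#' @param train_fraction fraction in (0, 1).
#' @return list with elements `train` and `test`, both `gait_record`s.
#' @export
split_record <- function(record, train_fraction = 0.7) {
  stopifnot(inherits(record, "gait_record"))
  check_scalar_num(train_fraction, "train_fraction", lower = 0, upper = 1,
                   strict_lower = TRUE, strict_upper = TRUE)
  L <- as.integer(round(record$fs_grf / record$fs_imu))
  T_imu <- ncol(record$acc[[1]])
  T_tr <- as.integer(round(train_fraction * T_imu))
  cut_grf <- T_tr * L
  slice <- function(cols_imu, cols_grf, shift_grf) {
    r <- record
    r$acc <- lapply(record$acc, function(a) a[, cols_imu, drop = FALSE])
    r$grf <- record$grf[, cols_grf, drop = FALSE]
    r$duration <- length(cols_imu) / record$fs_imu
    cyc <- record$truth$cycles
    keep <- cyc$hs >= min(cols_grf) & (cyc$start + cyc$n - 1L) <= max(cols_grf)
    cyc <- cyc[keep, , drop = FALSE]
    for (col in c("start", "hs", "hp", "ff", "tp", "to"))
      cyc[[col]] <- cyc[[col]] - shift_grf
    r$truth$cycles <- cyc
    r
  }
  T_grf <- ncol(record$grf)
  list(train = slice(seq_len(T_tr), seq_len(cut_grf), 0L),
       test = slice((T_tr + 1L):T_imu, (cut_grf + 1L):T_grf, cut_grf))
}

# filter an event_set to cycles fully inside [lo, hi], shifting indices
# so the segment starts at sample 1
.events_window <- function(events, lo, hi) {
  keep <- Filter(function(ev) all(ev >= lo & ev <= hi), events$cycles)
  cycles <- lapply(keep, function(ev) ev - lo + 1L)
  structure(list(cycles = cycles, fs = events$fs), class = "event_set")
}

# widen binary spike rows with a triangular pulse of half-width w samples
.widen_ged <- function(y, w) {
  if (w <= 0) return(y)
  ker <- 1 - abs(seq(-w, w)) / (w + 1)
  for (r in seq_len(nrow(y))) {
    idx <- which(y[r, ] == 1)
    row <- numeric(ncol(y))
    for (i in idx) {
      at <- (i - w):(i + w)
      ok <- at >= 1 & at <= ncol(y)
      row[at[ok]] <- pmax(row[at[ok]], ker[ok])
    }
    y[r, ] <- row
  }
  y
}

# temporal parameters from detected HS/TO peak indices on the test output
.params_from_peaks <- function(hs, to, fs) {
  if (length(hs) < 2L) return(NULL)
  cycle <- mean(diff(hs)) / fs
  stance <- numeric(0)
  for (i in seq_len(length(hs) - 1L)) {
    cand <- to[to > hs[i] & to < hs[i + 1L]]
    if (length(cand)) stance <- c(stance, (cand[1] - hs[i]) / fs)
  }
  if (!length(stance)) return(list(cycle_duration = cycle))
  list(cycle_duration = cycle,
       stance_duration = mean(stance),
       stance_proportion = mean(stance) / cycle)
}

.solve_from_grams <- function(Gs, Hs, w, gamma) {
  A <- Reduce(`+`, Map(`*`, Gs, w))
  B <- Reduce(`+`, Map(`*`, Hs, w))
  ne <- structure(list(XXT = A, YXT = B,
                       n_samples = NA_integer_, total_weight = sum(w)),
                  class = "normal_equations")
  solve_ridge(ne, gamma)
}

# The shared work-horse behind gait_esn() and run_sweep().  `methods` is a
# character vector drawn from "standard", "kernel:cycle_duration",
# "kernel:stance_proportion", "kernel:stance_duration".
.esn_pipeline <- function(records, location, axes, hp,
                          methods = "standard",
                          train_fraction = 0.7, washout = 200L,
                          rise_threshold = DEFAULT_RISE_THRESHOLD,
                          gamma = hp$regularization,
                          n_centers = 5L, width = NULL,
                          zones = DEFAULT_ZONES,
                          leak_variant = "convex",
                          ged_pulse_halfwidth = 0L,
                          reservoir = NULL,
                          relative_height_floor = 0.3) {
  stopifnot(length(records) >= 1L)
  kern_vars <- sub("^kernel:", "", grep("^kernel:", methods, value = TRUE))
  bad <- setdiff(methods, c("standard", paste0("kernel:", c(
    "cycle_duration", "stance_proportion", "stance_duration"))))
  if (length(bad)) stop_invalid("unknown method(s): ",
                                paste(bad, collapse = ", "))
  n_in <- 1L + length(.parse_axes(axes))
  if (is.null(reservoir)) reservoir <- build_reservoir(hp, n_in)

  fs_imu <- records[[1]]$fs_imu
  fs_grf <- records[[1]]$fs_grf
  L <- as.integer(round(fs_grf / fs_imu))

  # pass 1: training-split channel statistics for standardization
  n_ch <- n_in - 1L
  s1 <- numeric(n_ch); s2 <- numeric(n_ch); n_tot <- 0
  U_list <- vector("list", length(records))
  Ttr_list <- integer(length(records))
  for (p in seq_along(records)) {
    U <- build_input_vector(records[[p]], location, axes)
    T_imu <- ncol(U)
    T_tr <- as.integer(round(train_fraction * T_imu))
    if (T_tr <= washout + 10L || T_imu - T_tr < 10L)
      stop_invalid("record ", records[[p]]$record_id,
                   " is too short for the requested split and washout")
    ch <- U[-1L, seq_len(T_tr), drop = FALSE]
    s1 <- s1 + rowSums(ch)
    s2 <- s2 + rowSums(ch^2)
    n_tot <- n_tot + T_tr
    U_list[[p]] <- U
    Ttr_list[p] <- T_tr
  }
  mu <- s1 / n_tot
  sd_ <- sqrt(pmax(s2 / n_tot - mu^2, 0))
  sd_[sd_ < 1e-12] <- 1

  # pass 2: states, per-record normal-equation blocks, targets, events
  n_rec <- length(records)
  Gs <- vector("list", n_rec)
  H_ged <- vector("list", n_rec)
  H_grf <- vector("list", n_rec)
  X_te <- vector("list", n_rec)
  ged_te <- vector("list", n_rec)
  grf_te <- vector("list", n_rec)
  ev_te <- vector("list", n_rec)
  tparams <- vector("list", n_rec)
  mean_cycles <- rep(NA_real_, n_rec)
  all_train_cycles <- numeric(0)
  for (p in seq_along(records)) {
    rec <- records[[p]]
    U <- U_list[[p]]
    U[-1L, ] <- (U[-1L, , drop = FALSE] - mu) / sd_
    T_imu <- ncol(U)
    T_tr <- Ttr_list[p]
    X <- run_reservoir(reservoir, U, leak_variant = leak_variant)
    tr <- (washout + 1L):T_tr
    te <- (T_tr + 1L):T_imu

    ev_grf <- suppressWarnings(
      detect_events_from_vgrf(rec$grf["v", ], fs_grf, rise_threshold))
    ev_imu <- .events_window(events_to_clock(ev_grf, fs_imu), 1L, T_imu)
    ged <- .widen_ged(build_ged_target(ev_imu, T_imu), ged_pulse_halfwidth)
    grf_imu <- build_grf_target(
      resample_to_imu_clock(rec$grf, fs_grf, fs_imu), rec$body_weight)

    Xtr <- X[, tr, drop = FALSE]
    Gs[[p]] <- tcrossprod(Xtr)
    H_ged[[p]] <- tcrossprod(ged[, tr, drop = FALSE], Xtr)
    H_grf[[p]] <- tcrossprod(grf_imu[, tr, drop = FALSE], Xtr)
    X_te[[p]] <- X[, te, drop = FALSE]
    ged_te[[p]] <- ged[, te, drop = FALSE]
    grf_te[[p]] <- grf_imu[, te, drop = FALSE]
    ev_te[[p]] <- .events_window(ev_imu, T_tr + 1L, T_imu)

    ev_train <- .events_window(ev_imu, 1L, T_tr)
    if (length(ev_train$cycles) >= 2L) {
      tp <- compute_temporal_parameters(ev_train)
      tparams[[p]] <- list(cycle_duration = tp$mean_cycle_duration,
                           stance_duration = tp$mean_stance_duration,
                           stance_proportion = tp$mean_stance_proportion)
      mean_cycles[p] <- tp$mean_cycle_duration
      all_train_cycles <- c(all_train_cycles, tp$per_cycle$cycle_duration)
    }
    U_list[p] <- list(NULL)
  }
  if (all(is.na(mean_cycles)))
    stop_invalid("no record has 2 labelled training cycles; records are too short")
  mean_cycle <- mean(mean_cycles, na.rm = TRUE)
  peak_dist <- peak_distance_for_group(mean_cycle)
  # temporal-parameter estimation must resolve the fastest cadences the
  # kernel bank is meant to cover, so its peak separation is anchored to
  # the short end (5th percentile) of the training cycle durations rather
  # than to the group mean used for event scoring
  param_peak_dist <- 0.7 * stats::quantile(all_train_cycles, 0.05,
                                           names = FALSE)
  train_param_means <- list(
    cycle_duration = mean(vapply(tparams, function(x)
      x$cycle_duration %||% NA_real_, numeric(1)), na.rm = TRUE),
    stance_duration = mean(vapply(tparams, function(x)
      x$stance_duration %||% NA_real_, numeric(1)), na.rm = TRUE),
    stance_proportion = mean(vapply(tparams, function(x)
      x$stance_proportion %||% NA_real_, numeric(1)), na.rm = TRUE))

  unit <- rep(1, n_rec)
  W_ged_std <- .solve_from_grams(Gs, H_ged, unit, gamma)
  W_grf_std <- .solve_from_grams(Gs, H_grf, unit, gamma)

  # kernel banks per requested temporal parameter, for both tasks
  banks <- list()
  for (v in kern_vars) {
    vals <- vapply(tparams, function(x)
      (if (is.null(x)) NULL else x[[v]]) %||% NA_real_, numeric(1))
    if (anyNA(vals)) {
      warning("some records lack training-split temporal parameters; ",
              "using the group mean for those records")
      vals[is.na(vals)] <- mean(vals, na.rm = TRUE)
    }
    ctr <- NULL
    if (is.null(ctr)) {
      rng <- stats::quantile(vals, c(0.05, 0.95), names = FALSE)
      if (diff(rng) <= 0) rng <- range(vals) + c(-1e-6, 1e-6)
      ctr <- seq(rng[1], rng[2], length.out = max(2L, n_centers))
    }
    wdt <- width %||% (diff(ctr[1:2]) / 2)
    mk_bank <- function(Hs) {
      readouts <- vector("list", length(ctr))
      usable <- logical(length(ctr))
      for (k in seq_along(ctr)) {
        imp <- kernel_importance(vals, ctr[k], wdt)
        if (sum(imp) <= .Machine$double.xmin * n_rec) {
          usable[k] <- FALSE
        } else {
          readouts[[k]] <- .solve_from_grams(Gs, Hs, imp, gamma)
          usable[k] <- TRUE
        }
      }
      structure(list(mode = "kernel", variable = v, centers = ctr,
                     width = wdt, readouts = readouts, usable = usable,
                     gamma = gamma, n_records = n_rec),
                class = "esn_kernel_bank")
    }
    banks[[v]] <- list(ged = mk_bank(H_ged), grf = mk_bank(H_grf))
  }

  # --- test-split predictions and scores ------------------------------
  event_names <- c("hs", "hp", "ff", "tp", "to")
  pred_params <- vector("list", n_rec)
  grf_preds <- list()  # method -> list of 3 x T_te matrices
  for (m in methods) grf_preds[[m]] <- vector("list", n_rec)
  ged_peaks <- list()  # method -> list of per-event peak lists
  for (m in methods) ged_peaks[[m]] <- vector("list", n_rec)

  for (p in seq_len(n_rec)) {
    y_ged_std <- W_ged_std %*% X_te[[p]]
    rownames(y_ged_std) <- event_names
    peaks_std <- lapply(stats::setNames(event_names, event_names),
                        function(ev)
                          detect_predicted_events(y_ged_std[ev, ], fs_imu,
                                                  peak_dist,
                                                  relative_height_floor))
    pp <- .params_from_peaks(
      detect_predicted_events(y_ged_std["hs", ], fs_imu, param_peak_dist,
                              relative_height_floor),
      detect_predicted_events(y_ged_std["to", ], fs_imu, param_peak_dist,
                              relative_height_floor),
      fs_imu)
    pred_params[[p]] <- pp

    for (m in methods) {
      if (m == "standard") {
        grf_preds[[m]][[p]] <- W_grf_std %*% X_te[[p]]
        ged_peaks[[m]][[p]] <- peaks_std
      } else {
        v <- sub("^kernel:", "", m)
        par_val <- (if (is.null(pp)) NULL else pp[[v]]) %||%
          train_param_means[[v]]
        Wg <- select_kernel(banks[[v]]$grf, par_val)
        grf_preds[[m]][[p]] <- Wg %*% X_te[[p]]
        We <- select_kernel(banks[[v]]$ged, par_val)
        y_k <- We %*% X_te[[p]]
        rownames(y_k) <- event_names
        ged_peaks[[m]][[p]] <- lapply(
          stats::setNames(event_names, event_names),
          function(ev) detect_predicted_events(y_k[ev, ], fs_imu, peak_dist,
                                               relative_height_floor))
      }
    }
  }

  # GED scores
  ged_score <- list()
  for (m in methods) {
    rows <- list(); unm <- stats::setNames(rep(0L, 5L), event_names)
    for (p in seq_len(n_rec)) {
      cyc <- ev_te[[p]]$cycles
      if (!length(cyc)) next
      for (ev in event_names) {
        tgt <- vapply(cyc, function(x) as.numeric(x[[ev]]), numeric(1))
        mm <- match_events(tgt, ged_peaks[[m]][[p]][[ev]], fs_imu)
        unm[ev] <- unm[ev] + mm$n_unmatched
        if (nrow(mm$pairs))
          rows[[length(rows) + 1L]] <-
            data.frame(record = p, event = ev, error_ms = mm$pairs$error_ms)
      }
    }
    sc <- if (length(rows)) compute_event_mae(do.call(rbind, rows), unm)
          else data.frame(event = event_names, mae_ms = NA_real_,
                          n_records = 0L, n_unmatched = as.integer(unm))
    sc$method <- m
    ged_score[[m]] <- sc
  }
  ged_score <- do.call(rbind, ged_score)
  rownames(ged_score) <- NULL

  # GRF scores per zone
  grf_score <- list()
  for (m in methods) {
    for (z in names(zones)) {
      masks <- lapply(seq_len(n_rec), function(p)
        zone_mask(ev_te[[p]], zones[[z]], ncol(X_te[[p]])))
      sc <- compute_grf_mae(grf_preds[[m]], grf_te, masks)
      sc$zone <- z
      sc$method <- m
      grf_score[[paste(m, z)]] <- sc
    }
  }
  grf_score <- do.call(rbind, grf_score)
  rownames(grf_score) <- NULL

  list(reservoir = reservoir,
       standardization = list(mu = mu, sd = sd_),
       location = location, axes = axes,
       W_ged_standard = W_ged_std, W_grf_standard = W_grf_std,
       kernel_banks = banks,
       peak_distance = peak_dist,
       param_peak_distance = param_peak_dist,
       mean_cycle_duration = mean_cycle,
       train_param_means = train_param_means,
       pred_params = pred_params,
       settings = list(train_fraction = train_fraction, washout = washout,
                       rise_threshold = rise_threshold, gamma = gamma,
                       zones = zones, leak_variant = leak_variant,
                       ged_pulse_halfwidth = ged_pulse_halfwidth,
                       relative_height_floor = relative_height_floor,
                       methods = methods),
       record_ids = vapply(records, function(r) r$record_id, character(1)),
       groups = vapply(records, function(r) r$group, character(1)),
       scores = list(ged = ged_score, grf = grf_score))
}

#' Fit an echo-state-network gait model
#'
#' Trains the two linear readouts of a leaky echo state network on the
#' accelerations of one sensor location / axis combination: a 5-row
#' gait-event readout (binary heel strike, heel push, foot flat, toe push,
#' toe off targets) and a 3-row ground-reaction-force readout (body-weight
#' normalized AP, ML, V forces).  Inputs are z-scored with training-split
#' statistics, one shared reservoir trajectory per record feeds both tasks,
#' and training uses the first `train_fraction` of every record (after a
#' `washout` of initial samples); the remainder is the held-out test split
#' on which `summary()` reports scores.
#'
#' With `method = "kernel"`, a bank of readouts is fitted, each one a ridge
#' solution in which records are weighted by the Gaussian proximity of
#' their temporal parameter (`kernel_variable`) to the bank centre; at
#' prediction time the readout nearest the record's parameter — measured
#' from the event readout's own predicted heel strikes and toe offs — is
#' selected per record.
#'
#' @param dataset a `gait_dataset` (or list of `gait_record`s).
#' @param location sensor location, one of `"TS"`, `"H"`, `"MM"`, `"MFT"`,
#'   `"MK"`.
#' @param axes axis combination token (see [build_input_vector()]).
#' @param group `"healthy"`, `"mkoa"` or `"pooled"` record selection.
#' @param method `"standard"` or `"kernel"` readout training for scoring;
#'   the standard readouts are always fitted (the kernel method needs the
#'   standard event readout to estimate temporal parameters).
#' @param kernel_variable temporal parameter the kernel bank specializes
#'   on.
#' @param hp [esn_hyperparameters()].
#' @param train_fraction contiguous training prefix fraction per record.
#' @param washout initial reservoir samples excluded from the training
#'   normal equations (default 200 samples = 1 s at 200 Hz; set 0 to
#'   disable).
#' @param rise_threshold VGRF contact threshold (N) for labelling.
#' @param gamma ridge regularization; defaults to `hp$regularization`.
#' @param n_centers,width kernel bank layout (see [train_kernel()]).
#' @param zones named list of gait-cycle percentage zones for force
#'   scoring.
#' @param leak_variant see [run_reservoir()].
#' @param ged_pulse_halfwidth optional half-width (samples) of a triangular
#'   widening of the binary event targets; 0 (default) keeps the literal
#'   single-sample spikes.
#' @return an object of class `gait_esn`.
#' @examples
#' \donttest{
#' ds <- generate_dataset(n_healthy = 2, n_mkoa = 0, duration = 12, seed = 1)
#' fit <- gait_esn(ds, location = "TS", axes = "AP",
#'                 hp = esn_hyperparameters(n_nodes = 30))
#' summary(fit)
#' }
#' @export
gait_esn <- function(dataset, location = "TS", axes = "AP",
                     group = c("pooled", "healthy", "mkoa"),
                     method = c("standard", "kernel"),
                     kernel_variable = c("cycle_duration",
                                         "stance_proportion",
                                         "stance_duration"),
                     hp = esn_hyperparameters(),
                     train_fraction = 0.7, washout = 200L,
                     rise_threshold = DEFAULT_RISE_THRESHOLD,
                     gamma = hp$regularization,
                     n_centers = 5L, width = NULL,
                     zones = DEFAULT_ZONES,
                     leak_variant = c("convex", "printed"),
                     ged_pulse_halfwidth = 0L) {
  group <- match.arg(group)
  method <- match.arg(method)
  kernel_variable <- match.arg(kernel_variable)
  leak_variant <- match.arg(leak_variant)
  records <- if (inherits(dataset, "gait_dataset")) dataset$records
             else dataset
  if (group != "pooled")
    records <- Filter(function(r) r$group == group, records)
  if (!length(records)) stop_invalid("no records in group '", group, "'")
  methods <- if (method == "standard") "standard"
             else c("standard", paste0("kernel:", kernel_variable))
  fit <- .esn_pipeline(records, location, axes, hp, methods = methods,
                       train_fraction = train_fraction, washout = washout,
                       rise_threshold = rise_threshold, gamma = gamma,
                       n_centers = n_centers, width = width, zones = zones,
                       leak_variant = leak_variant,
                       ged_pulse_halfwidth = ged_pulse_halfwidth)
  fit$call <- match.call()
  fit$group <- group
  fit$method <- method
  fit$kernel_variable <- if (method == "kernel") kernel_variable else NULL
  fit$hp <- hp
  class(fit) <- "gait_esn"
  fit
}

#' @export
print.gait_esn <- function(x, ...) {
  cat("Echo-state-network gait model\n")
  cat(sprintf("  input    : %s accelerations, axes %s (+bias)\n",
              x$location, x$axes))
  cat(sprintf("  records  : %d (%s)\n", length(x$record_ids), x$group))
  cat(sprintf("  reservoir: N=%d, leak=%.4f, radius=%.4f\n",
              x$hp$n_nodes, x$hp$leak_rate, x$hp$spectral_radius))
  cat(sprintf("  method   : %s%s\n", x$method,
              if (!is.null(x$kernel_variable))
                paste0(" (", x$kernel_variable, ")") else ""))
  cat(sprintf("  peak sep : %.2f s (0.7 x %.2f s mean cycle)\n",
              x$peak_distance, x$mean_cycle_duration))
  invisible(x)
}

#' @export
summary.gait_esn <- function(object, ...) {
  structure(list(fit = object), class = "summary.gait_esn")
}

#' @export
print.summary.gait_esn <- function(x, ...) {
  print(x$fit)
  cat("\nHeld-out test scores\n")
  cat("  Gait events (MAE, ms):\n")
  print(x$fit$scores$ged, row.names = FALSE, digits = 4)
  cat("  GRF (MAE, body-weight fractions):\n")
  print(x$fit$scores$grf, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Extract readout coefficients
#'
#' @param object a `gait_esn` fit.
#' @param task `"grf"` or `"ged"`.
#' @param ... unused.
#' @return the standard readout matrix for the task (for kernel fits, the
#'   kernel bank is in `object$kernel_banks`).
#' @export
coef.gait_esn <- function(object, task = c("grf", "ged"), ...) {
  task <- match.arg(task)
  if (task == "grf") object$W_grf_standard else object$W_ged_standard
}

#' Predict forces and events for gait records
#'
#' Re-runs the fitted reservoir over each requested record and applies the
#' fitted readouts.  For kernel fits the per-record readout is selected by
#' the temporal parameter estimated from the event readout's predicted
#' heel strikes / toe offs on the scored segment.
#'
#' @param object a `gait_esn` fit.
#' @param newdata a `gait_dataset` or list of `gait_record`s.
#' @param split `"test"` (default; score segment matching the fit's
#'   train/test cut), `"all"` or `"train"`.
#' @param ... unused.
#' @return list with one element per record: `grf` (3 x T body-weight
#'   fractions), `ged` (5 x T readout outputs), `events` (detected peak
#'   indices per event type, segment-relative), `target_grf`,
#'   `target_events`.
#' @export
predict.gait_esn <- function(object, newdata,
                             split = c("test", "all", "train"), ...) {
  split <- match.arg(split)
  records <- if (inherits(newdata, "gait_dataset")) newdata$records
             else newdata
  st <- object$settings
  event_names <- c("hs", "hp", "ff", "tp", "to")
  out <- lapply(records, function(rec) {
    U <- build_input_vector(rec, object$location, object$axes)
    U[-1L, ] <- (U[-1L, , drop = FALSE] - object$standardization$mu) /
      object$standardization$sd
    X <- run_reservoir(object$reservoir, U,
                       leak_variant = st$leak_variant)
    T_imu <- ncol(X)
    T_tr <- as.integer(round(st$train_fraction * T_imu))
    cols <- switch(split, all = seq_len(T_imu), train = seq_len(T_tr),
                   test = (T_tr + 1L):T_imu)
    Xs <- X[, cols, drop = FALSE]
    y_ged <- object$W_ged_standard %*% Xs
    rownames(y_ged) <- event_names
    peaks <- lapply(stats::setNames(event_names, event_names), function(ev)
      detect_predicted_events(y_ged[ev, ], rec$fs_imu, object$peak_distance,
                              st$relative_height_floor))
    if (object$method == "kernel") {
      v <- object$kernel_variable
      pp <- .params_from_peaks(
        detect_predicted_events(y_ged["hs", ], rec$fs_imu,
                                object$param_peak_distance,
                                st$relative_height_floor),
        detect_predicted_events(y_ged["to", ], rec$fs_imu,
                                object$param_peak_distance,
                                st$relative_height_floor),
        rec$fs_imu)
      par_val <- (if (is.null(pp)) NULL else pp[[v]]) %||%
        object$train_param_means[[v]]
      Wg <- select_kernel(object$kernel_banks[[v]]$grf, par_val)
    } else {
      Wg <- object$W_grf_standard
    }
    y_grf <- Wg %*% Xs
    rownames(y_grf) <- c("ap", "ml", "v")
    ev_grf <- suppressWarnings(detect_events_from_vgrf(
      rec$grf["v", ], rec$fs_grf, st$rise_threshold))
    ev_imu <- events_to_clock(ev_grf, rec$fs_imu)
    ev_seg <- .events_window(ev_imu, min(cols), max(cols))
    tgt <- build_grf_target(
      resample_to_imu_clock(rec$grf, rec$fs_grf, rec$fs_imu),
      rec$body_weight)[, cols, drop = FALSE]
    list(grf = y_grf, ged = y_ged, events = peaks,
         target_grf = tgt, target_events = ev_seg)
  })
  names(out) <- vapply(records, function(r) r$record_id, character(1))
  out
}

#' Test-split force residuals
#'
#' @param object a `gait_esn` fit.
#' @param newdata dataset to score (typically the one the model was fitted
#'   on).
#' @param ... passed to [predict.gait_esn()].
#' @return list of 3 x T residual matrices (predicted minus target,
#'   body-weight fractions), one per record.
#' @export
residuals.gait_esn <- function(object, newdata, ...) {
  pr <- predict(object, newdata, ...)
  lapply(pr, function(p) p$grf - p$target_grf)
}

#' Plot predicted against measured vertical GRF
#'
#' @param x a `gait_esn` fit.
#' @param newdata dataset containing the record to display.
#' @param record record index or id.
#' @param ... passed to [predict.gait_esn()].
#' @return invisibly, the prediction list for the record.
#' @export
plot.gait_esn <- function(x, newdata, record = 1L, ...) {
  pr <- predict(x, newdata, ...)
  p <- if (is.character(record)) pr[[record]] else pr[[record]]
  t <- seq_len(ncol(p$grf)) / (if (inherits(newdata, "gait_dataset"))
    newdata$config$fs_imu else 200)
  graphics::plot(t, p$target_grf["v", ], type = "l", col = "grey40",
                 xlab = "time (s)", ylab = "vertical GRF (BW)",
                 main = sprintf("%s %s: vertical GRF, held-out segment",
                                x$location, x$axes))
  graphics::lines(t, p$grf["v", ], col = "firebrick")
  graphics::legend("topright", c("measured", "predicted"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(p)
}
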