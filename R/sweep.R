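# The sensor-location x axis-combination sweep: 5 locations x 7 axis
# combinations = 35 input configurations per group, each scored for both
# tasks under every requested training method, plus the best-configuration
# summaries (sigma-distance of the minimum MAE and best-location
# frequencies).

#' Configuration of a location/axes sweep
#'
#' @param locations sensor locations to sweep (default all five).
#' @param axes axis-combination tokens (default all seven, giving the full
#'   35-configuration sweep).
#' @param methods training methods: a subset of `"standard"`,
#'   `"kernel:cycle_duration"`, `"kernel:stance_proportion"`,
#'   `"kernel:stance_duration"`.
#' @param tasks `"GED"`, `"GRF"` or both.
#' @param groups record groups to fit separately; `"pooled"` fits all
#'   records together.
#' @param hp [esn_hyperparameters()]; the reservoir seed is shared across
#'   configurations of equal input size, so location/axes comparisons are
#'   not confounded by reservoir resampling.
#' @param train_fraction,washout,rise_threshold,gamma,zones,n_centers,width
#'   see [gait_esn()].
#' @return list of class `sweep_config`.
#' @export
sweep_config <- function(locations = GAIT_LOCATIONS,
                         axes = GAIT_AXES,
                         methods = c("standard", "kernel:cycle_duration",
                                     "kernel:stance_proportion",
                                     "kernel:stance_duration"),
                         tasks = c("GED", "GRF"),
                         groups = c("healthy", "mkoa"),
                         hp = esn_hyperparameters(),
                         train_fraction = 0.7, washout = 200L,
                         rise_threshold = DEFAULT_RISE_THRESHOLD,
                         gamma = hp$regularization,
                         zones = DEFAULT_ZONES,
                         n_centers = 5L, width = NULL) {
  stopifnot(all(locations %in% GAIT_LOCATIONS), all(axes %in% GAIT_AXES),
            all(tasks %in% c("GED", "GRF")))
  check_scalar_num(train_fraction, "train_fraction", lower = 0, upper = 1,
                   strict_lower = TRUE, strict_upper = TRUE)
  structure(list(locations = locations, axes = axes, methods = methods,
                 tasks = tasks, groups = groups, hp = hp,
                 train_fraction = train_fraction, washout = washout,
                 rise_threshold = rise_threshold, gamma = gamma,
                 zones = zones, n_centers = n_centers, width = width),
            class = "sweep_config")
}

#' Run a sensor-location / axis-combination sweep
#'
#' For every group and every (location, axes) configuration, fits the
#' reservoir readouts under each requested training method and scores the
#' held-out split: gait events per event type (MAE in ms) and forces per
#' axis and gait-cycle zone (MAE in body-weight fractions).  One reservoir
#' is built per input size and reused across configurations, so rows differ
#' only in their input signals.  A configuration that fails is recorded
#' with `NA` scores and the sweep continues.
#'
#' @param dataset a `gait_dataset`.
#' @param config a [sweep_config()].
#' @param verbose log per-configuration progress to stderr.
#' @return data.frame of class `sweep_results` with columns `group`,
#'   `task`, `location`, `axes`, `method`, `measure` (event type or force
#'   axis), `zone` (`NA` for events), `mae`, `n_records`.
#' @export
run_sweep <- function(dataset, config = sweep_config(), verbose = FALSE) {
  stopifnot(inherits(dataset, "gait_dataset"),
            inherits(config, "sweep_config"))
  reservoirs <- list()  # cache per input size
  rows <- list()
  for (group in config$groups) {
    records <- if (group == "pooled") dataset$records
               else Filter(function(r) r$group == group, dataset$records)
    if (!length(records)) next
    for (loc in config$locations) {
      for (ax in config$axes) {
        n_in <- 1L + length(.parse_axes(ax))
        key <- as.character(n_in)
        if (is.null(reservoirs[[key]]))
          reservoirs[[key]] <- build_reservoir(config$hp, n_in)
        if (verbose)
          message(sprintf("[sweep] %s %s/%s", group, loc, ax))
        t0 <- proc.time()[["elapsed"]]
        fit <- tryCatch(
          .esn_pipeline(records, loc, ax, config$hp,
                        methods = config$methods,
                        train_fraction = config$train_fraction,
                        washout = config$washout,
                        rise_threshold = config$rise_threshold,
                        gamma = config$gamma, n_centers = config$n_centers,
                        width = config$width, zones = config$zones,
                        reservoir = reservoirs[[key]]),
          error = function(e) e)
        if (inherits(fit, "error")) {
          warning(sprintf("configuration %s %s/%s failed: %s",
                          group, loc, ax, conditionMessage(fit)))
          for (m in config$methods)
            rows[[length(rows) + 1L]] <-
              data.frame(group = group, task = "GRF", location = loc,
                         axes = ax, method = m, measure = "v",
                         zone = NA_character_, mae = NA_real_,
                         n_records = 0L)
          next
        }
        if ("GED" %in% config$tasks) {
          g <- fit$scores$ged
          rows[[length(rows) + 1L]] <-
            data.frame(group = group, task = "GED", location = loc,
                       axes = ax, method = g$method, measure = g$event,
                       zone = NA_character_, mae = g$mae_ms,
                       n_records = g$n_records)
        }
        if ("GRF" %in% config$tasks) {
          g <- fit$scores$grf
          rows[[length(rows) + 1L]] <-
            data.frame(group = group, task = "GRF", location = loc,
                       axes = ax, method = g$method, measure = g$axis,
                       zone = g$zone, mae = g$mae, n_records = g$n_records)
        }
        if (verbose)
          message(sprintf("[sweep]   done in %.1f s",
                          proc.time()[["elapsed"]] - t0))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_results", class(out))
  out
}

#' Summarize a sweep: best configurations and location frequencies
#'
#' For every cell (group, task measure, zone, method), finds the
#' configuration with minimal MAE and its sigma-distance below the field:
#' `(min MAE - mean MAE) / sd(MAE)` over all configurations in the cell
#' (population sd; the swept configurations are the whole universe, not a
#' sample), a negative number by construction.  Additionally reports, per
#' group, the fraction of force cells (axis x zone x method) in which each
#' location hosts the minimum — the best-location frequency.
#'
#' @param results a `sweep_results` data.frame.
#' @return list of class `sweep_summary`: `best` (one row per cell with
#'   `best_location`, `best_axes`, `mae`, `distance`, `n_configs`) and
#'   `location_frequency` (`group`, `location`, `n_best`, `n_cells`,
#'   `frequency`).
#' @export
summarize_best <- function(results) {
  stopifnot(is.data.frame(results))
  res <- results[!is.na(results$mae), , drop = FALSE]
  key <- interaction(res$group, res$task, res$measure,
                     ifelse(is.na(res$zone), "", res$zone), res$method,
                     drop = TRUE)
  best <- lapply(split(res, key), function(cell) {
    if (nrow(cell) < 2L) return(NULL)
    mu <- mean(cell$mae)
    sdev <- sqrt(mean((cell$mae - mu)^2))
    i <- which.min(cell$mae)
    dist <- if (sdev > 0) (cell$mae[i] - mu) / sdev else {
      warning("degenerate cell with all-equal MAEs; distance set to 0")
      0
    }
    data.frame(group = cell$group[1], task = cell$task[1],
               measure = cell$measure[1], zone = cell$zone[1],
               method = cell$method[1], best_location = cell$location[i],
               best_axes = cell$axes[i], mae = cell$mae[i],
               distance = dist, n_configs = nrow(cell))
  })
  best <- do.call(rbind, best[!vapply(best, is.null, logical(1))])
  rownames(best) <- NULL

  freq <- NULL
  grf_best <- best[best$task == "GRF", , drop = FALSE]
  if (nrow(grf_best)) {
    locs <- sort(unique(results$location))
    freq <- do.call(rbind, lapply(split(grf_best, grf_best$group),
                                  function(g) {
      n_cells <- nrow(g)
      data.frame(group = g$group[1], location = locs,
                 n_best = as.integer(table(factor(g$best_location,
                                                  levels = locs))),
                 n_cells = n_cells,
                 frequency = as.numeric(table(factor(g$best_location,
                                                     levels = locs))) /
                   n_cells)
    }))
    rownames(freq) <- NULL
  }
  structure(list(best = best, location_frequency = freq),
            class = "sweep_summary")
}

#' @export
print.sweep_summary <- function(x, ...) {
  cat("Sweep summary: best configurations per cell\n")
  print(x$best, row.names = FALSE, digits = 4)
  if (!is.null(x$location_frequency)) {
    cat("\nBest-location frequency over force cells\n")
    print(x$location_frequency, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write sweep results as tidy CSV
#'
#' Uses the `zone_or_event` dialect: event type for the event-detection
#' task, `"axis zone"` for forces.
#'
#' @param results a `sweep_results` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_results <- function(results, path) {
  out <- data.frame(group = results$group, task = results$task,
                    location = results$location, axes = results$axes,
                    method = results$method,
                    zone_or_event = ifelse(is.na(results$zone),
                                           results$measure,
                                           paste(results$measure,
                                                 results$zone)),
                    mae = results$mae, n_records = results$n_records)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
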