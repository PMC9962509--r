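# Plain-text record store: one directory per dataset with a JSON manifest
# and per-record CSV files, so synthetic datasets can be inspected or
# consumed outside R.

#' Write a gait dataset to a directory of CSV files
#'
#' Creates `manifest.json` (ids, groups, weights, rates, seed and the
#' generating profiles) and, per record, `grf.csv` plus `acc_<LOC>.csv`
#' files with columns `time_s, ap, ml, v` (values at 9+ significant
#' digits), and `events_true.csv` with the generator's per-cycle truth.
#'
#' @param dataset a `gait_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_gait_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "gait_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    seed = dataset$seed,
    fs_imu = dataset$config$fs_imu,
    fs_grf = dataset$config$fs_grf,
    duration = dataset$config$duration,
    profiles = lapply(dataset$config$profiles, unclass),
    records = lapply(unname(dataset$records), function(r)
      list(record_id = r$record_id, participant_id = r$participant_id,
           group = r$group, speed_condition = r$speed_condition,
           body_weight = r$body_weight))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  fmt <- function(m, fs) {
    df <- data.frame(time_s = (seq_len(ncol(m)) - 1) / fs,
                     ap = m["ap", ], ml = m["ml", ], v = m["v", ])
    df[] <- lapply(df, function(x) formatC(x, digits = 10, format = "g"))
    df
  }
  for (r in dataset$records) {
    rd <- file.path(dir, r$record_id)
    dir.create(rd, showWarnings = FALSE)
    utils::write.csv(fmt(r$grf, r$fs_grf), file.path(rd, "grf.csv"),
                     row.names = FALSE, quote = FALSE)
    for (loc in names(r$acc))
      utils::write.csv(fmt(r$acc[[loc]], r$fs_imu),
                       file.path(rd, paste0("acc_", loc, ".csv")),
                       row.names = FALSE, quote = FALSE)
    cyc <- r$truth$cycles
    ev <- do.call(rbind, lapply(seq_len(nrow(cyc)), function(i)
      data.frame(cycle = i, event = c("hs", "hp", "ff", "tp", "to"),
                 sample_index = as.integer(cyc[i, c("hs", "hp", "ff",
                                                    "tp", "to")]),
                 time_s = (as.numeric(cyc[i, c("hs", "hp", "ff", "tp",
                                               "to")]) - 1) / r$fs_grf,
                 start = cyc$start[i], n = cyc$n[i])))
    utils::write.csv(ev, file.path(rd, "events_true.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a gait dataset written by [write_gait_dataset()]
#'
#' @param dir dataset directory.
#' @return a `gait_dataset` (truth cycles reconstructed from
#'   `events_true.csv`).
#' @export
read_gait_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  fs_imu <- manifest$fs_imu
  fs_grf <- manifest$fs_grf
  recs <- list()
  meta <- manifest$records
  for (i in seq_len(nrow(meta))) {
    rid <- meta$record_id[i]
    rd <- file.path(dir, rid)
    read_mat <- function(f) {
      df <- utils::read.csv(file.path(rd, f))
      t(as.matrix(df[, c("ap", "ml", "v")]))
    }
    grf <- read_mat("grf.csv")
    locs <- sub("^acc_(.*)\\.csv$", "\\1",
                list.files(rd, pattern = "^acc_.*\\.csv$"))
    acc <- lapply(stats::setNames(locs, locs),
                  function(l) read_mat(paste0("acc_", l, ".csv")))
    ev <- utils::read.csv(file.path(rd, "events_true.csv"))
    cyc <- do.call(rbind, lapply(split(ev, ev$cycle), function(e) {
      idx <- stats::setNames(e$sample_index, e$event)
      data.frame(start = e$start[1], n = e$n[1],
                 duration = e$n[1] / fs_grf,
                 hs = idx[["hs"]], hp = idx[["hp"]], ff = idx[["ff"]],
                 tp = idx[["tp"]], to = idx[["to"]], complete = TRUE)
    }))
    recs[[rid]] <- structure(list(
      record_id = rid, participant_id = meta$participant_id[i],
      group = meta$group[i], speed_condition = meta$speed_condition[i],
      body_weight = meta$body_weight[i], acc = acc, grf = grf,
      fs_imu = fs_imu, fs_grf = fs_grf,
      duration = ncol(acc[[1]]) / fs_imu,
      truth = list(cycles = cyc)), class = "gait_record")
  }
  structure(list(records = recs, seed = manifest$seed,
                 config = list(fs_imu = fs_imu, fs_grf = fs_grf,
                               duration = manifest$duration)),
            class = "gait_dataset")
}

#' Write labelled events as tidy CSV
#'
#' One row per event: `record_id, cycle, event, sample_index, time_s`.
#'
#' @param events an `event_set`.
#' @param record_id record identifier to stamp on every row.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, record_id, path) {
  stopifnot(inherits(events, "event_set"))
  rows <- do.call(rbind, lapply(seq_along(events$cycles), function(i) {
    ev <- events$cycles[[i]]
    data.frame(record_id = record_id, cycle = i, event = names(ev),
               sample_index = as.integer(ev),
               time_s = (as.integer(ev) - 1) / events$fs)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a fitted model bit-exactly
#'
#' Thin wrappers around R's native serialization so a trained model (with
#' its reservoir, standardization statistics and readouts) can be reloaded
#' exactly.
#'
#' @param object a `gait_esn` fit or `esn_reservoir`.
#' @param path file path.
#' @return [load_gait_esn()] returns the reloaded object.
#' @export
save_gait_esn <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_gait_esn
#' @export
load_gait_esn <- function(path) readRDS(path)
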