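test_that("input vectors follow the bias + axes layout", {
  rec <- tiny_dataset()$records[[1]]
  U <- build_input_vector(rec, "TS", "AP-V")
  expect_identical(nrow(U), 3L)
  expect_true(all(U[1, ] == 1))
  expect_equal(U[2, ], rec$acc$TS["ap", ], ignore_attr = TRUE)
  expect_equal(U[3, ], rec$acc$TS["v", ], ignore_attr = TRUE)
  expect_identical(nrow(build_input_vector(rec, "H", "AP-ML-V")), 4L)
  expect_identical(nrow(build_input_vector(rec, "MK", "ML")), 2L)
  expect_error(build_input_vector(rec, "TS", "XY"), "axes")
  expect_error(build_input_vector(rec, "nope", "AP"), "location")
})

test_that("record splitting is a contiguous prefix on both clocks", {
  rec <- tiny_dataset()$records[[1]]
  sp <- split_record(rec, 0.7)
  T_imu <- ncol(rec$acc$TS)
  expect_identical(ncol(sp$train$acc$TS), as.integer(round(0.7 * T_imu)))
  expect_identical(ncol(sp$train$acc$TS) + ncol(sp$test$acc$TS), T_imu)
  expect_identical(ncol(sp$train$grf), 5L * ncol(sp$train$acc$TS))
  # concatenating the segments reproduces the record
  expect_identical(cbind(sp$train$acc$TS, sp$test$acc$TS), rec$acc$TS)
  expect_identical(cbind(sp$train$grf, sp$test$grf), rec$grf)
  # truth cycles stay within their segments
  expect_true(all(sp$train$truth$cycles$to <= ncol(sp$train$grf)))
  expect_true(all(sp$test$truth$cycles$hs >= 1))
  # default training segments hold at least 2 complete cycles
  for (r in tiny_dataset()$records)
    expect_gte(nrow(split_record(r)$train$truth$cycles), 2L)
  expect_error(split_record(rec, 1.2), "train_fraction")
})

test_that("gait_esn returns a scored model object with working methods", {
  fit <- memo("fit_std", gait_esn(fit_dataset(), location = "TS",
                                  axes = "AP-V", group = "healthy",
                                  hp = small_hp(), washout = 100L))
  expect_s3_class(fit, "gait_esn")
  expect_identical(dim(coef(fit, "grf")), c(3L, 30L))
  expect_identical(dim(coef(fit, "ged")), c(5L, 30L))
  expect_output(print(fit), "Echo-state-network gait model")
  expect_output(print(summary(fit)), "Held-out test scores")
  g <- fit$scores$grf
  expect_identical(nrow(g), 9L)  # 3 axes x 3 zones, one method
  expect_true(all(g$mae >= 0))
  e <- fit$scores$ged
  expect_identical(sort(unique(e$event)), sort(c("hs", "hp", "ff", "tp", "to")))
})

test_that("predict returns aligned predictions, events and targets", {
  fit <- memo("fit_std", gait_esn(fit_dataset(), location = "TS",
                                  axes = "AP-V", group = "healthy",
                                  hp = small_hp(), washout = 100L))
  pr <- predict(fit, fit_dataset())
  expect_length(pr, length(fit$record_ids))
  p <- pr[[1]]
  expect_identical(rownames(p$grf), c("ap", "ml", "v"))
  expect_identical(ncol(p$grf), ncol(p$target_grf))
  expect_identical(names(p$events), c("hs", "hp", "ff", "tp", "to"))
  # residuals are prediction minus target
  res <- residuals(fit, fit_dataset())
  expect_equal(res[[1]], p$grf - p$target_grf)
  # the fitted model predicts vertical force far better than a constant
  v_err <- mean(abs(unlist(lapply(pr, function(q)
    q$grf["v", ] - q$target_grf["v", ]))))
  v_const <- mean(abs(unlist(lapply(pr, function(q)
    q$target_grf["v", ] - median(q$target_grf["v", ])))))
  expect_lt(v_err, 0.5 * v_const)
})

test_that("fits are deterministic given seeds", {
  f1 <- gait_esn(fit_dataset(), location = "H", axes = "V",
                 group = "healthy", hp = small_hp(3), washout = 100L)
  f2 <- gait_esn(fit_dataset(), location = "H", axes = "V",
                 group = "healthy", hp = small_hp(3), washout = 100L)
  expect_identical(f1$scores, f2$scores)
  expect_identical(f1$W_grf_standard, f2$W_grf_standard)
})

test_that("kernel fits select per-record readouts and score both methods", {
  fit <- gait_esn(fit_dataset(), location = "TS", axes = "AP",
                  group = "healthy", method = "kernel",
                  kernel_variable = "cycle_duration",
                  hp = small_hp(), washout = 100L)
  expect_identical(sort(unique(fit$scores$grf$method)),
                   c("kernel:cycle_duration", "standard"))
  bank <- fit$kernel_banks$cycle_duration$grf
  expect_s3_class(bank, "esn_kernel_bank")
  expect_length(bank$centers, 5L)
  expect_true(any(bank$usable))
  # a saved model reloads bit-exactly
  f <- tempfile(fileext = ".rds")
  save_gait_esn(fit, f)
  expect_identical(load_gait_esn(f), fit)
})

test_that("reduced sweeps have complete, deterministic row structure", {
  ds <- memo("sweep_ds", generate_dataset(n_healthy = 2, n_mkoa = 0,
                                          duration = 12, seed = 77))
  cfg <- sweep_config(locations = c("TS", "MK"), axes = c("AP", "V", "ML-V"),
                      methods = c("standard", "kernel:cycle_duration"),
                      groups = "healthy", hp = small_hp(), washout = 100L)
  res <- memo("sweep_res", run_sweep(ds, cfg))
  expect_s3_class(res, "sweep_results")
  # 6 (location, axes) pairs per (group, task, method)
  for (task in c("GED", "GRF")) for (m in cfg$methods) {
    sub <- res[res$task == task & res$method == m, ]
    expect_identical(nrow(unique(sub[, c("location", "axes")])), 6L)
  }
  # GED rows: 5 events per configuration; GRF rows: 3 axes x 3 zones
  expect_identical(nrow(res[res$task == "GED", ]), 6L * 5L * 2L)
  expect_identical(nrow(res[res$task == "GRF", ]), 6L * 9L * 2L)
  res2 <- run_sweep(ds, cfg)
  expect_identical(res, res2)
  # tidy CSV export uses the zone_or_event dialect
  f <- tempfile(fileext = ".csv")
  write_sweep_results(res, f)
  df <- read.csv(f)
  expect_identical(names(df), c("group", "task", "location", "axes",
                                "method", "zone_or_event", "mae",
                                "n_records"))
})

test_that("summaries compute sigma-distances and location frequencies", {
  # toy table with a known layout: MAEs 1..5 in one cell
  toy <- data.frame(group = "healthy", task = "GRF",
                    location = c("TS", "H", "MM", "MFT", "MK"),
                    axes = "AP", method = "standard", measure = "v",
                    zone = "(0,100)", mae = c(1, 2, 3, 4, 5),
                    n_records = 4L)
  sm <- summarize_best(toy)
  expect_identical(sm$best$best_location, "TS")
  expect_equal(sm$best$distance, (1 - 3) / sqrt(2), tolerance = 1e-12)
  # planted winner frequency on a two-cell table
  toy2 <- rbind(toy, transform(toy, zone = "(10,18)",
                               mae = c(5, 1, 3, 4, 2)))
  sm2 <- summarize_best(toy2)
  fr <- sm2$location_frequency
  expect_equal(fr$frequency[fr$location == "TS"], 0.5)
  expect_equal(fr$frequency[fr$location == "H"], 0.5)
  expect_equal(sum(fr$frequency), 1)
  # degenerate all-equal cell reports distance zero with a warning
  toy3 <- transform(toy, mae = 2)
  expect_warning(sm3 <- summarize_best(toy3), "degenerate")
  expect_equal(sm3$best$distance, 0)
})
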