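test_that("a hand-built two-bump stance is labelled at the exact indices", {
  v <- c(rep(0, 5), 30, 60, 100, 80, 60, 80, 120, 90, 30, rep(0, 5))
  ev <- detect_events_from_vgrf(v, 100, rise_threshold = 20)
  expect_length(ev$cycles, 1L)
  expect_identical(ev$cycles[[1]],
                   c(hs = 6L, hp = 8L, ff = 10L, tp = 12L, to = 14L))
})

test_that("a monotone plateau between the peaks triggers the midpoint fallback", {
  v <- c(0, 0, 30, 80, 100, 100, 100, 80, 30, 0, 0)
  ev <- detect_events_from_vgrf(v, 100, rise_threshold = 20)
  cyc <- ev$cycles[[1]]
  expect_identical(cyc[["hp"]], 5L)  # plateau start = end of rising edge
  expect_identical(cyc[["tp"]], 7L)  # plateau end = start of falling edge
  expect_identical(cyc[["ff"]], as.integer(round((5 + 7) / 2)))
})

test_that("event ordering HS < HP < FF < TP < TO holds on noisy inputs", {
  set.seed(21)
  for (i in 1:20) {
    base <- generate_gait_cycle(gait_profile("healthy"), 1.2, 700, 500)$grf["v", ]
    v <- pmax(c(rep(0, 50), rep(base, 3), rep(0, 50)) +
                abs(rnorm(50 + 3 * length(base) + 50, 0, 5)), 0)
    ev <- suppressWarnings(detect_events_from_vgrf(v, 500))
    for (cyc in ev$cycles)
      expect_true(all(diff(cyc[c("hs", "hp", "ff", "tp", "to")]) > 0))
  }
})

test_that("labelling noiseless synthetic records recovers generator truth exactly", {
  ds <- generate_dataset(n_healthy = 2, n_mkoa = 2, duration = 20, seed = 31)
  for (r in ds$records) {
    ev <- detect_events_from_vgrf(r$grf["v", ], r$fs_grf)
    tru <- as.matrix(r$truth$cycles[, c("hs", "hp", "ff", "tp", "to")])
    det <- t(vapply(ev$cycles, identity, integer(5)))
    expect_identical(nrow(det), nrow(tru))
    expect_true(all(det == tru))
  }
})

test_that("labeller input validation and edge cases behave", {
  expect_error(detect_events_from_vgrf(c(1, -5, 3), 100), "negative")
  expect_warning(ev <- detect_events_from_vgrf(rep(0, 100), 100), "no complete")
  expect_length(ev$cycles, 0L)
  # bout touching the record edge is dropped
  v <- c(rep(100, 10), rep(0, 10))
  expect_warning(ev2 <- detect_events_from_vgrf(v, 100), "no complete")
  expect_length(ev2$cycles, 0L)
})

test_that("binary event target has one spike per cycle and round-trips", {
  cycles <- list(c(hs = 3L, hp = 6L, ff = 9L, tp = 12L, to = 15L),
                 c(hs = 20L, hp = 23L, ff = 26L, tp = 29L, to = 32L),
                 c(hs = 40L, hp = 43L, ff = 46L, tp = 49L, to = 52L))
  ev <- structure(list(cycles = cycles, fs = 200), class = "event_set")
  y <- build_ged_target(ev, 60L)
  expect_identical(dim(y), c(5L, 60L))
  expect_true(all(rowSums(y) == 3))
  expect_true(all(y %in% c(0, 1)))
  # recover indices per row
  for (nm in rownames(y))
    expect_identical(which(y[nm, ] == 1),
                     vapply(cycles, function(c_) as.integer(c_[[nm]]),
                            integer(1)))
  # empty set -> zero matrix; out-of-range index -> error
  empty <- structure(list(cycles = list(), fs = 200), class = "event_set")
  expect_true(all(build_ged_target(empty, 10L) == 0))
  expect_error(build_ged_target(ev, 30L), "outside")
})

test_that("force target is an exact body-weight normalization", {
  grf <- rbind(ap = rnorm(50), ml = rnorm(50), v = runif(50, 0, 900))
  y <- build_grf_target(grf, 700)
  expect_equal(y * 700, grf, ignore_attr = TRUE)
  expect_true(all(build_grf_target(matrix(0, 3, 10), 700) == 0))
  const <- matrix(700, 3, 10)
  expect_true(all(build_grf_target(const, 700) == 1))
  expect_error(build_grf_target(grf, 0), "body_weight")
})

test_that("temporal parameters follow the HS/TO arithmetic", {
  ev <- structure(list(cycles = list(
    c(hs = 1L, hp = 60L, ff = 100L, tp = 140L, to = 181L),
    c(hs = 301L, hp = 360L, ff = 400L, tp = 440L, to = 481L)),
    fs = 200), class = "event_set")
  tp <- compute_temporal_parameters(ev)
  expect_equal(tp$per_cycle$cycle_duration, 1.5)
  expect_equal(tp$per_cycle$stance_duration, 0.9)
  expect_equal(tp$per_cycle$stance_proportion, 0.6)
  expect_equal(tp$mean_cycle_duration, 1.5)
  # HS -> FF variant measures to the foot-flat event instead
  tp2 <- compute_temporal_parameters(ev, stance_rule = "hs_ff")
  expect_equal(tp2$per_cycle$stance_duration, (100 - 1) / 200)
  ev1 <- structure(list(cycles = ev$cycles[1], fs = 200), class = "event_set")
  expect_error(compute_temporal_parameters(ev1), "2 labelled cycles")
})

test_that("measured stance proportion matches the generating profile", {
  ds <- tiny_dataset()
  for (grp in c("healthy", "mkoa")) {
    rs <- Filter(function(r) r$group == grp, ds$records)
    props <- unlist(lapply(rs, function(r) {
      ev <- detect_events_from_vgrf(r$grf["v", ], r$fs_grf)
      compute_temporal_parameters(ev)$mean_stance_proportion
    }))
    expect_lt(abs(mean(props) - gait_profile(grp)$stance_proportion), 0.02)
  }
})

test_that("decimation preserves constants, lengths and pure tones", {
  expect_equal(resample_to_imu_clock(rep(3.5, 1000), 1000, 200),
               rep(3.5, 200))
  expect_length(resample_to_imu_clock(rnorm(1000), 1000, 200), 200)
  # closed-form check on a 2 Hz tone, away from the edge transient
  t_in <- seq(0, 5, by = 1 / 1000)
  y <- resample_to_imu_clock(sin(2 * pi * 2 * t_in), 1000, 200)
  t_out <- seq(0, by = 1 / 200, length.out = length(y))
  err <- abs(y - sin(2 * pi * 2 * t_out))
  edge <- 20  # half filter length on the output clock
  expect_lt(max(err[(edge + 1):(length(err) - edge)]), 1e-3)
  # matrix input keeps row structure; identity when rates match
  m <- rbind(ap = rnorm(1000), ml = rnorm(1000), v = rnorm(1000))
  out <- resample_to_imu_clock(m, 1000, 200)
  expect_identical(dim(out), c(3L, 200L))
  expect_identical(resample_to_imu_clock(m, 200, 200), m)
  expect_error(resample_to_imu_clock(rnorm(100), 300, 200), "integer")
})

test_that("events written to CSV carry index and time columns", {
  ev <- structure(list(cycles = list(
    c(hs = 10L, hp = 20L, ff = 30L, tp = 40L, to = 50L)), fs = 200),
    class = "event_set")
  f <- tempfile(fileext = ".csv")
  write_events_csv(ev, "rec1", f)
  df <- read.csv(f)
  expect_identical(nrow(df), 5L)
  expect_equal(df$time_s, (df$sample_index - 1) / 200)
})
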