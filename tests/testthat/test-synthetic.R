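test_that("healthy gait cycle has the double-bump stance structure", {
  prof <- gait_profile("healthy")
  cyc <- generate_gait_cycle(prof, 1.0, 700, 200)
  v <- cyc$grf["v", ]
  m <- cyc$n_stance
  # exactly two strict local maxima and one interior minimum within stance
  interior <- 2:(m - 1)
  is_max <- vapply(interior, function(i)
    v[i] > v[i - 1] && v[i] > v[i + 1], logical(1))
  is_min <- vapply(interior, function(i)
    v[i] < v[i - 1] && v[i] < v[i + 1], logical(1))
  expect_identical(sum(is_max), 2L)
  expect_identical(sum(is_min), 1L)
  expect_identical(interior[is_max], unname(cyc$events[c("hp", "tp")]))
  expect_identical(interior[is_min], unname(cyc$events["ff"]))
  # peaks exceed body weight when a mid-stance valley is present
  expect_gt(max(v), 700)
  # swing phase exactly zero
  expect_true(all(v[(m + 1):cyc$n] == 0))
})

test_that("flat-valley profile yields a plateau with no interior minimum", {
  prof <- gait_profile("mkoa")   # vgrf_valley_depth = 0
  cyc <- generate_gait_cycle(prof, 1.2, 750, 200)
  v <- cyc$grf["v", ]
  hp <- cyc$events[["hp"]]; tp <- cyc$events[["tp"]]
  expect_true(all(v[hp:tp] == v[hp]))  # constant plateau
  inter <- (hp + 1):(tp - 1)
  is_min <- vapply(inter, function(i)
    v[i] < v[i - 1] && v[i] < v[i + 1], logical(1))
  expect_identical(sum(is_min), 0L)
  expect_identical(cyc$events[["ff"]], as.integer(round((hp + tp) / 2)))
})

test_that("AP braking and propulsion impulses cancel at steady speed", {
  for (grp in c("healthy", "mkoa")) {
    cyc <- generate_gait_cycle(gait_profile(grp), 1.1, 680, 1000)
    ap <- cyc$grf["ap", ]
    expect_lt(abs(sum(ap)), 0.02 * sum(abs(ap)))
    # braking (negative) lobe precedes propulsion (positive)
    expect_lt(which.min(ap), which.max(ap))
    # ML small relative to V
    expect_lt(max(abs(cyc$grf["ml", ])), 0.2 * max(cyc$grf["v", ]))
  }
})

test_that("cycle generator rejects invalid arguments", {
  prof <- gait_profile("healthy")
  expect_error(generate_gait_cycle(prof, -1, 700, 200), "cycle_duration")
  expect_error(generate_gait_cycle(prof, 1, 700, 0), "'fs'")
  expect_error(generate_gait_cycle(prof, 1, -5, 200), "body_weight")
})

test_that("IMU synthesis is deterministic and location-distinct", {
  prof <- gait_profile("healthy", noise_sd = 0)
  seq_grf <- generate_grf_record(prof, rep(1.1, 6), 700, duration = 8)
  set.seed(5); a1 <- generate_imu_signals(seq_grf, prof, "TS")
  set.seed(5); a2 <- generate_imu_signals(seq_grf, prof, "TS")
  expect_identical(a1, a2)
  set.seed(5); mk <- generate_imu_signals(seq_grf, prof, "MK")
  expect_lt(cor(a1["v", ], mk["v", ]), 0.999)
  expect_error(generate_imu_signals(seq_grf, prof, "XX"), "location")
})

test_that("top-of-shoe AP impact peak is locked to heel strike", {
  prof <- gait_profile("healthy")
  fs_imu <- 200
  set.seed(11)
  n_checked <- 0
  for (r in 1:10) {
    seq_grf <- generate_grf_record(prof, stats::rnorm(7, 1.3, 0.05), 720,
                                   duration = 9)
    acc <- generate_imu_signals(seq_grf, prof, "TS", fs_imu)
    cyc <- seq_grf$cycles[seq_grf$cycles$complete, ]
    for (i in seq_len(nrow(cyc))) {
      hs_imu <- round((cyc$hs[i] - 1) * fs_imu / 1000) + 1
      lo <- max(1, hs_imu - 20); hi <- min(ncol(acc), hs_imu + 20)
      peak <- lo - 1 + which.max(acc["ap", lo:hi])
      expect_lte(abs(peak - hs_imu), 5)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 50)
})

test_that("default study design yields 135 records and is seed-reproducible", {
  ds <- generate_dataset(n_healthy = 27, n_mkoa = 18,
                         speeds_per_participant = 3, duration = 22, seed = 3)
  expect_length(ds$records, 135L)
  groups <- vapply(ds$records, function(r) r$group, character(1))
  expect_identical(sum(groups == "healthy"), 81L)
  small1 <- generate_dataset(n_healthy = 2, n_mkoa = 1, duration = 20,
                             seed = 99)
  small2 <- generate_dataset(n_healthy = 2, n_mkoa = 1, duration = 20,
                             seed = 99)
  expect_identical(small1, small2)
  small3 <- generate_dataset(n_healthy = 2, n_mkoa = 1, duration = 20,
                             seed = 100)
  expect_false(identical(small1$records[[1]]$acc, small3$records[[1]]$acc))
})

test_that("participant speeds match the group means", {
  # the generator draws self-selected speed per participant from the group
  # profile via lower-truncated normals; over many participants the group
  # mean is recovered within 3 standard errors
  set.seed(1234)
  for (grp in c("healthy", "mkoa")) {
    prof <- gait_profile(grp)
    v <- gaitesn:::.draw_truncnorm(2000, prof$mean_speed, prof$speed_sd, 0.25)
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - prof$mean_speed), 3 * se + 0.015)
  }
  # and the per-record speed fields respect the condition factors
  ds <- tiny_dataset()
  for (pid in unique(vapply(ds$records, function(r) r$participant_id,
                            character(1)))) {
    rs <- Filter(function(r) r$participant_id == pid, ds$records)
    sp <- vapply(rs, function(r) r$speed, numeric(1))
    cond <- vapply(rs, function(r) r$speed_condition, character(1))
    expect_equal(unname(sp[cond == "fast"] / sp[cond == "self_selected"]),
                 1.2)
    expect_equal(unname(sp[cond == "slow"] / sp[cond == "self_selected"]),
                 0.8)
  }
})

test_that("cycle durations order fast < self-selected < slow per participant", {
  ds <- tiny_dataset()
  for (pid in unique(vapply(ds$records, function(r) r$participant_id,
                            character(1)))) {
    rs <- Filter(function(r) r$participant_id == pid, ds$records)
    cond <- vapply(rs, function(r) r$speed_condition, character(1))
    mc <- vapply(rs, function(r) mean(r$truth$cycles$duration), numeric(1))
    expect_lt(mc[cond == "fast"], mc[cond == "self_selected"])
    expect_lt(mc[cond == "self_selected"], mc[cond == "slow"])
  }
})

test_that("vertical GRF is exactly zero between toe off and next heel strike", {
  ds <- tiny_dataset()
  for (r in ds$records[1:4]) {
    cyc <- r$truth$cycles
    for (i in seq_len(nrow(cyc) - 1L)) {
      gap <- (cyc$to[i] + 1L):(cyc$hs[i + 1L] - 1L)
      expect_true(all(r$grf["v", gap] == 0))
    }
    expect_true(all(r$grf["v", ] >= 0))
  }
})

test_that("too-short records are rejected", {
  expect_error(generate_dataset(n_healthy = 1, n_mkoa = 0, duration = 3,
                                seed = 1),
               "too short")
  expect_error(generate_dataset(n_healthy = 0, n_mkoa = 0, seed = 1),
               "participant")
})

test_that("dataset round-trips through the CSV record store", {
  ds <- generate_dataset(n_healthy = 1, n_mkoa = 1,
                         speeds_per_participant = 1, duration = 16, seed = 5)
  dir <- tempfile("gaitstore")
  write_gait_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_gait_dataset(dir)
  expect_identical(names(back$records), names(ds$records))
  for (id in names(ds$records)) {
    a <- ds$records[[id]]; b <- back$records[[id]]
    expect_equal(b$grf, a$grf, tolerance = 1e-8)
    expect_equal(b$acc$TS, a$acc$TS, tolerance = 1e-8)
    expect_identical(b$group, a$group)
    expect_equal(b$body_weight, a$body_weight)
    expect_equal(as.integer(b$truth$cycles$hs), as.integer(a$truth$cycles$hs))
  }
})
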