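test_that("default configuration matches the acquisition setup", {
  cfg <- sim_config(duration = 30, seed = 1)
  rec <- generate_recording(cfg)$recording
  expect_equal(dim(rec$intensity)[2], 34)
  expect_equal(rec$sampling_rate, 10)
  expect_setequal(rec$wavelengths, c(780, 850))
  expect_true(all(is.finite(rec$intensity)))
})

test_that("perfect coupling with no noise gives SCI = 1 in every window", {
  cfg <- sim_config(n_channels = 4, duration = 60, coupling = 1,
                    noise_sd = 0, motion_rate = 0, cse_probability = 0,
                    response_amplitude = 0, seed = 3)
  rec <- generate_recording(cfg)$recording
  for (ch in 1:4) {
    q <- channel_quality(rec, ch, qt_config())
    expect_true(all(abs(q$sci - 1) < 1e-6))
  }
})

test_that("motion scheduling is exact and detectable at large amplitude", {
  # rate 2/min over 120 s schedules exactly 4 events
  cfg <- sim_config(duration = 120, motion_rate = 2, cse_probability = 0,
                    noise_sd = 0.003,
                    motion_amplitude_range = c(0.8, 1.2), seed = 5)
  out <- generate_recording(cfg)
  expect_equal(nrow(out$truth$motion_events), 4)
  expect_true(all(out$truth$motion_events$onset >= 0))
  expect_true(all(out$truth$motion_events$onset +
                    out$truth$motion_events$duration <= 120 + 1e-9))
  mask <- detect_motion(out$recording)
  g <- window_grid(n_samples <- 1200, 10, 3)
  dirty <- nrow(g) - length(clean_windows(mask, g)[[1]])
  expect_gte(dirty, 4)   # each event dirties at least one window
})

test_that("zero motion rate on quiet recordings flags nothing", {
  cfg <- sim_config(n_channels = 6, duration = 60, motion_rate = 0,
                    cse_probability = 0, noise_sd = 0.002,
                    wander_scale = 0, imbalance_prob = 0, seed = 7)
  out <- generate_recording(cfg)
  expect_equal(nrow(out$truth$motion_events), 0)
  mask <- detect_motion(out$recording)
  expect_equal(sum(mask), 0)
})

test_that("dead channels fall below the signal-extrema cutoff", {
  cfg <- sim_config(duration = 30, cse_probability = 0.5, seed = 9)
  out <- generate_recording(cfg)
  expect_gt(length(out$truth$cse_channels), 0)
  expect_setequal(find_cse(out$recording), out$truth$cse_channels)
})

test_that("coupling quality monotonically drives SCI and PSP", {
  levels <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  stats <- vapply(seq_along(levels), function(i) {
    cfg <- sim_config(n_channels = 50, duration = 30, coupling = levels[i],
                      motion_rate = 0, cse_probability = 0,
                      wander_scale = 0, seed = 100)
    rec <- generate_recording(cfg)$recording
    q <- evaluate_quality(rec, qt_config())
    c(mean(q$sci), mean(q$psp))
  }, numeric(2))
  expect_true(all(diff(stats[1, ]) > 0))
  expect_true(all(diff(stats[2, ]) > 0))
})

test_that("fixed seeds reproduce recordings bit-identically", {
  cfg <- sim_config(duration = 20, seed = 11)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$recording$intensity, b$recording$intensity)
  expect_identical(a$truth, b$truth)
})

test_that("cohort tables cross the design cells", {
  des <- cohort_design(ages = c(8, 18), cohorts = c("Gambia", "UK"),
                       tasks = "HaND", n_per_cell = 5)
  coh <- generate_cohort(des, sim_config(duration = 10, seed = 13))
  expect_equal(nrow(coh$participants), 20)
  expect_equal(length(coh$recordings), 20)
  expect_setequal(unique(coh$participants$age_months), c(8, 18))
  expect_error(cohort_design(n_per_cell = 0), "at least 1")
})

test_that("cohort subsets reproduce under the same master seed", {
  des_big <- cohort_design(ages = c(8, 18), cohorts = "Gambia",
                           tasks = "HaND", n_per_cell = 2)
  coh <- generate_cohort(des_big, sim_config(duration = 10, seed = 17))
  coh2 <- generate_cohort(des_big, sim_config(duration = 10, seed = 17))
  expect_identical(coh$recordings[[3]]$recording$intensity,
                   coh2$recordings[[3]]$recording$intensity)
})

test_that("null designs differ across cells only by sampling error", {
  des <- cohort_design(ages = c(5, 24), cohorts = "Gambia", tasks = "HaND",
                       n_per_cell = 12, coupling_sd = 0.05)
  coh <- generate_cohort(des, sim_config(duration = 10, seed = 19))
  m <- tapply(coh$participants$coupling_mean, coh$participants$age_months,
              mean)
  se <- sqrt(2) * 0.05 / sqrt(12)
  expect_lt(abs(m[1] - m[2]), 4 * se)
})

test_that("a negative motion-to-quality effect induces a negative PoM/SCI correlation", {
  des <- cohort_design(ages = c(8, 18), cohorts = "Gambia", tasks = "HaND",
                       n_per_cell = 6,
                       effects = list(motion_coupling = -0.12))
  coh <- generate_cohort(des, sim_config(duration = 60, seed = 23))
  g <- window_grid(600, 10, 3)
  vals <- vapply(seq_len(nrow(coh$participants)), function(p) {
    rec <- coh$recordings[[p]]$recording
    cse <- find_cse(rec)
    mask <- detect_motion(rec)
    acc <- setdiff(seq_len(34), cse)
    pom <- percent_motion(mask, g, acc)
    q <- evaluate_quality(rec, qt_config(), clean_windows(mask, g), acc)
    c(pom, mean(q$sci, na.rm = TRUE))
  }, numeric(2))
  expect_lt(cor(vals[1, ], vals[2, ]), 0)
})

test_that("recording files round-trip through the text format", {
  cfg <- sim_config(n_channels = 34, duration = 60, seed = 29)
  rec <- generate_recording(cfg, metadata = list(id = "P001",
                                                 age_months = 8,
                                                 cohort = "UK",
                                                 task = "SNS"))$recording
  f <- tempfile(fileext = ".nirs.json")
  on.exit(unlink(f))
  write_recording(rec, f)
  back <- read_recording(f)
  expect_identical(back$sampling_rate, rec$sampling_rate)
  expect_identical(back$wavelengths, rec$wavelengths)
  expect_equal(back$metadata, rec$metadata)
  expect_equal(back$intensity, rec$intensity, tolerance = 1e-12)
  # 34 channels x 2 wavelengths, 600 samples each
  doc <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(nrow(doc$measurement_list), 68)
  expect_equal(dim(doc$data), c(68L, 600L))
})

test_that("malformed recording files name the missing field", {
  f <- tempfile(fileext = ".nirs.json")
  on.exit(unlink(f))
  rec <- make_recording(matrix(1, 10, 1), matrix(2, 10, 1))
  write_recording(rec, f)
  doc <- jsonlite::read_json(f, simplifyVector = TRUE)
  doc$wavelengths <- NULL
  jsonlite::write_json(doc, f, auto_unbox = TRUE, digits = NA)
  expect_error(read_recording(f), "wavelengths")
  expect_error(read_recording(tempfile()), "no such file")
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(duration = 0), "duration")
  expect_error(sim_config(n_channels = 0), "channel")
  expect_error(sim_config(cardiac_band = c(1.3, 6)), "cardiac_band")
  expect_error(sim_config(trc_indices = 40), "trc_indices")
})
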