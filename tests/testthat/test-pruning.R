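test_that("CSE detection uses the minimum raw intensity across wavelengths", {
  w1 <- matrix(1, 100, 3)
  w2 <- matrix(1.2, 100, 3)
  w1[, 2] <- 2e-4                          # constant dead channel
  w2[50, 3] <- 2.9e-4                      # single dip governs
  rec <- make_recording(w1, w2)
  expect_equal(find_cse(rec), c(2, 3))
  # idempotent and independent of anything else
  expect_equal(find_cse(rec), find_cse(rec))
  rec_ok <- make_recording(matrix(1, 100, 2), matrix(1.2, 100, 2))
  expect_length(find_cse(rec_ok), 0)
})

test_that("CV pruning compares wavelength CVs with a strict 0.2 boundary", {
  n <- 300
  w_same <- matrix(signal_with_cv(1, 0.1, n), ncol = 1)
  rec_same <- make_recording(w_same, w_same)
  r <- prune_cv(rec_same)
  expect_equal(r$status, "retained")

  # CV 0.10 vs 0.35: difference 0.25 > 0.2 -> pruned
  rec_diff <- make_recording(matrix(signal_with_cv(1, 0.10, n), ncol = 1),
                             matrix(signal_with_cv(1, 0.35, n), ncol = 1))
  expect_equal(prune_cv(rec_diff)$status, "pruned_cv")

  # difference exactly 0.2 -> retained under the strict convention
  rec_edge <- make_recording(matrix(signal_with_cv(1, 0.10, n), ncol = 1),
                             matrix(signal_with_cv(1, 0.30, n), ncol = 1))
  expect_equal(prune_cv(rec_edge)$status, "retained")
  # and pruned under the inclusive reading
  expect_equal(prune_cv(rec_edge, config = cv_config(strict = FALSE))$status,
               "pruned_cv")
})

test_that("CV pruning runs on concatenated clean windows and flags empties", {
  n <- 300
  w <- matrix(rep(signal_with_cv(1, 0.05, 30), 10), ncol = 1)
  rec <- make_recording(w, w)
  r <- prune_cv(rec, clean = list(integer()))       # no clean windows
  expect_equal(r$status, "excluded_no_clean_windows")
  expect_equal(channels_retained(r), 0)
  r2 <- prune_cv(rec, clean = list(c(1, 3, 5)))
  expect_equal(r2$status, "retained")
})

test_that("quality-threshold pruning applies q_threshold to the good fraction", {
  # synthetic quality table: 20 clean windows, controllable good count
  mk_quality <- function(n_good, n_total = 20) {
    data.frame(channel = 1L, window = seq_len(n_total),
               sci = c(rep(0.95, n_good), rep(0.05, n_total - n_good)),
               psp = c(rep(0.30, n_good), rep(0.001, n_total - n_good)))
  }
  rec <- make_recording(cardiac_matrix(600, 1), cardiac_matrix(600, 1))
  cfg <- qt_config(sci_threshold = 0.6, psp_threshold = 0.045)
  r15 <- prune_qtnirs(rec, config = cfg, quality = mk_quality(15),
                      n_clean = 20L)
  expect_equal(r15$status, "retained")            # 15/20 = 0.75 retained
  r14 <- prune_qtnirs(rec, config = cfg, quality = mk_quality(14),
                      n_clean = 20L)
  expect_equal(r14$status, "pruned_qt")           # 14/20 = 0.70 pruned
})

test_that("vacuous thresholds retain any channel with evaluable windows", {
  set.seed(31)
  cfg <- sim_config(n_channels = 4, duration = 60, motion_rate = 0,
                    cse_probability = 0, seed = 17)
  rec <- generate_recording(cfg)$recording
  r <- prune_qtnirs(rec, config = qt_config(0, 0))
  expect_true(all(r$status == "retained"))
  # zero clean windows is pruned, not ignored
  r0 <- prune_qtnirs(rec, clean = rep(list(integer()), 4),
                     config = qt_config(0, 0))
  expect_true(all(r0$status == "excluded_no_clean_windows"))
  expect_equal(channels_retained(r0), 0)
})

test_that("SCI-only pruning equals the full method at psp_threshold 0", {
  set.seed(32)
  cfg <- sim_config(n_channels = 6, duration = 60, motion_rate = 1,
                    cse_probability = 0, seed = 23)
  rec <- generate_recording(cfg)$recording
  mask <- detect_motion(rec)
  cw <- clean_windows(mask, window_grid(600, 10, 3))
  qc <- qt_config(sci_threshold = 0.6, psp_threshold = 0)
  a <- prune_qtnirs(rec, cw, qc)
  b <- prune_sci_only(rec, cw, qt_config(sci_threshold = 0.6,
                                         psp_threshold = 0.08))
  expect_equal(a$status, b$status)
  expect_equal(attr(b, "method"), "sci_only")
})

test_that("the PSP conjunct can only prune more channels", {
  set.seed(33)
  cfg <- sim_config(n_channels = 12, duration = 90, motion_rate = 1,
                    cse_probability = 0, seed = 29)
  rec <- generate_recording(cfg)$recording
  mask <- detect_motion(rec)
  cw <- clean_windows(mask, window_grid(900, 10, 3))
  for (s in c(0.2, 0.5, 0.8)) {
    so <- prune_sci_only(rec, cw, qt_config(s, 0.9))
    for (p in c(0.02, 0.05, 0.09)) {
      qt <- prune_qtnirs(rec, cw, qt_config(s, p))
      expect_gte(channels_retained(so), channels_retained(qt))
    }
  }
})

test_that("a correlated broadband channel passes SCI-only but fails full QT", {
  # both wavelengths share identical broadband (non-cardiac-like) in-band
  # noise: SCI = 1 every window, PSP stays low
  set.seed(34)
  shared <- 1 + 0.05 * bandpass_cardiac(rnorm(600), 10)
  rec <- make_recording(matrix(shared, ncol = 1),
                        matrix(1.2 * shared, ncol = 1))
  q <- channel_quality(rec, 1, qt_config())
  expect_true(all(q$sci > 0.9))
  so <- prune_sci_only(rec, config = qt_config(0.9, 0))
  expect_equal(so$status, "retained")
  qt <- prune_qtnirs(rec, config = qt_config(0.9, max(q$psp) + 1e-6))
  expect_equal(qt$status, "pruned_qt")
})

test_that("channels retained is non-increasing along both threshold grids", {
  set.seed(35)
  cfg <- sim_config(n_channels = 16, duration = 90, motion_rate = 1,
                    cse_probability = 0.05, seed = 37)
  rec <- generate_recording(cfg)$recording
  cse <- find_cse(rec)
  mask <- detect_motion(rec)
  cw <- clean_windows(mask, window_grid(900, 10, 3))
  sci_grid <- seq(0.1, 0.9, by = 0.2)
  psp_grid <- seq(0.01, 0.09, by = 0.02)
  cr <- matrix(NA_integer_, length(sci_grid), length(psp_grid))
  for (i in seq_along(sci_grid)) for (j in seq_along(psp_grid))
    cr[i, j] <- channels_retained(
      prune_qtnirs(rec, cw, qt_config(sci_grid[i], psp_grid[j]), cse))
  expect_true(all(apply(cr, 2, function(v) all(diff(v) <= 0))))
  expect_true(all(apply(cr, 1, function(v) all(diff(v) <= 0))))
  # and in q_threshold
  crq <- vapply(c(0.25, 0.5, 0.75, 1), function(q) {
    channels_retained(prune_qtnirs(rec, cw, qt_config(0.5, 0.04,
                                                      q_threshold = q), cse))
  }, integer(1))
  expect_true(all(diff(crq) <= 0))
})

test_that("bimodal coupling is classified by the recommended minima", {
  set.seed(36)
  agree <- replicate(3, {
    cfg <- sim_config(duration = 120, motion_rate = 0, cse_probability = 0,
                      coupling = function(n) sample(c(0.1, 0.9), n, TRUE),
                      seed = sample.int(1e6, 1))
    out <- generate_recording(cfg)
    r <- prune_qtnirs(out$recording, config = qt_config(0.6, 0.045))
    mean((r$status == "retained") == (out$truth$coupling > 0.5))
  })
  expect_gte(mean(agree), 0.95)
})
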