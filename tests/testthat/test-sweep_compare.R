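# two-channel recording with prescribed per-channel SNR on every window
snr_recording <- function(snrs_db, ns = 300) {
  mats <- lapply(snrs_db, function(s) {
    cv <- 10^(-s / 20)                     # sigma/mu for the target SNR
    matrix(signal_with_cv(1, cv, ns), ncol = 1)
  })
  w <- do.call(cbind, mats)
  make_recording(w, w)
}

retained_result <- function(nc, retained) {
  status <- ifelse(seq_len(nc) %in% retained, "retained", "pruned_qt")
  r <- nirsprune:::.pruning_result(status, "qt", NULL)
  r
}

test_that("TRC SNR averages retained task-relevant channels", {
  rec <- snr_recording(c(20, 40, 30))
  expect_equal(trc_snr(rec, retained_result(3, 1), trc_set = 1), 20,
               tolerance = 1e-9)
  expect_equal(trc_snr(rec, retained_result(3, 1:2), trc_set = 1:2), 30,
               tolerance = 1e-9)
  # all TRCs pruned -> undefined
  expect_true(is.na(trc_snr(rec, retained_result(3, 3), trc_set = 1:2)))
  expect_error(trc_snr(rec, retained_result(3, 1), trc_set = integer()),
               "empty")
})

test_that("the participant exclusion rule uses 60% of acceptable channels", {
  expect_false(exclusion_rule(21, 34))   # 61.8%
  expect_true(exclusion_rule(20, 34))    # 58.8%
  expect_false(exclusion_rule(34, 34))
  expect_true(exclusion_rule(0, 0))
  expect_true(exclusion_rule(10, 34, frac = 0.5))
})

test_that("the sweep emits one row per participant, method and grid point", {
  des <- cohort_design(ages = 8, cohorts = "Gambia", tasks = "HaND",
                       n_per_cell = 2)
  coh <- generate_cohort(des, sim_config(duration = 60, seed = 41))
  grid <- sweep_grid(sci = c(0.3, 0.6), psp = c(0.02, 0.05, 0.08))
  sw <- run_sweep(coh, grid)
  # per participant: 1 cv + 2 sci_only + 6 qt rows
  expect_equal(nrow(sw), 2 * (1 + 2 + 6))
  expect_equal(sum(sw$method == "qt"), 12)
  # default grids: 18 x 20 combinations
  expect_equal(length(sweep_grid()$sci) * length(sweep_grid()$psp), 360)
  # a one-point grid equals a direct pruning call
  sw1 <- run_sweep(coh, sweep_grid(sci = 0.6, psp = 0.05))
  rec <- coh$recordings[[1]]$recording
  cse <- find_cse(rec)
  mask <- detect_motion(rec)
  cw <- clean_windows(mask, window_grid(600, 10, 3))
  direct <- channels_retained(prune_qtnirs(rec, cw, qt_config(0.6, 0.05),
                                           cse))
  expect_equal(sw1$cr[sw1$method == "qt" &
                        sw1$id == coh$participants$id[1]], direct)
})

test_that("cohort-mean CR is non-increasing along either grid axis", {
  des <- cohort_design(ages = c(8, 18), cohorts = "Gambia", tasks = "HaND",
                       n_per_cell = 2)
  coh <- generate_cohort(des, sim_config(duration = 60, seed = 43))
  grid <- sweep_grid(sci = seq(0.1, 0.9, 0.2), psp = seq(0.01, 0.09, 0.02))
  sw <- run_sweep(coh, grid)
  qt <- sw[sw$method == "qt", ]
  agg <- tapply(qt$cr, list(qt$sci_thr, qt$psp_thr), mean)
  expect_true(all(apply(agg, 2, function(v) all(diff(v) <= 1e-9))))
  expect_true(all(apply(agg, 1, function(v) all(diff(v) <= 1e-9))))
})

# hand-built sweep table: 2 participants, 3 grid points
toy_sweep <- function() {
  rows <- expand.grid(id = c("A", "B"),
                      sci_thr = c(0.2, 0.5, 0.8), psp_thr = 0.05)
  rows$method <- "qt"
  rows$cr <- c(30, 32, 25, 27, 10, 12)     # means: 31, 26, 11
  rows$excluded <- rows$cr < 0.6 * 34
  rows$trc_snr <- c(20, 21, 24, 25, 26, 27)
  rows$age_months <- 8; rows$cohort <- "Gambia"; rows$task <- "HaND"
  rows$pom <- 10; rows$cse_count <- 0; rows$acceptable <- 34
  cv <- data.frame(id = c("A", "B"), sci_thr = NA, psp_thr = NA,
                   method = "cv", cr = c(25, 29), excluded = FALSE,
                   trc_snr = c(22, 23), age_months = 8, cohort = "Gambia",
                   task = "HaND", pom = 10, cse_count = 0, acceptable = 34)
  rbind(rows, cv)
}

test_that("retention matching equals brute-force enumeration", {
  sw <- toy_sweep()
  m <- match_to_cv(sw, "qt")
  # brute force: mean CV CR 27, exclusions 0
  # d1: |31-27|=4, |26-27|=1, |11-27|=16 ; d2: 0, 0, 2
  # ranks d1: 2,1,3 ; ranks d2: 1.5,1.5,3 ; combined: 3.5, 2.5, 6
  expect_equal(m$cv_mean_cr, 27)
  expect_equal(m$selected$sci_thr, 0.5)
  expect_equal(m$table$rank_combined, c(3.5, 2.5, 6))
  # permuting row order does not change the selection
  sw2 <- sw[rev(seq_len(nrow(sw))), ]
  m2 <- match_to_cv(sw2, "qt")
  expect_equal(m2$selected, m$selected)
  # exact match is selected outright
  sw3 <- sw
  sw3$cr[sw3$method == "qt" & sw3$sci_thr == 0.2] <- c(25, 29)
  m3 <- match_to_cv(sw3, "qt")
  expect_equal(m3$selected$sci_thr, 0.2)
  expect_error(match_to_cv(sw[0, ], "qt"), "empty")
})

test_that("rank-sum ties break toward lower thresholds", {
  sw <- toy_sweep()
  # make the two extreme points symmetric around the cv mean
  sw$cr[sw$method == "qt" & sw$sci_thr == 0.2] <- c(31, 33)  # mean 32
  sw$cr[sw$method == "qt" & sw$sci_thr == 0.5] <- c(21, 23)  # mean 22
  sw$cr[sw$method == "qt" & sw$sci_thr == 0.8] <- c(1, 3)
  sw$excluded <- sw$cr < 0.6 * 34
  sw$excluded[sw$method == "cv"] <- FALSE
  m <- match_to_cv(sw, "qt")
  # 0.2 and 0.5 tie on |d_cr| = 5; exclusion breaks in favour of 0.2,
  # which also happens to be the lower threshold
  expect_equal(m$selected$sci_thr, 0.2)
})

test_that("the trade-off trend flags points above a monotone cloud", {
  sw <- toy_sweep()
  tr <- tradeoff_trend(sw)
  expect_equal(nrow(tr$table), 3)
  # displaced point: +2 dB above an otherwise linear quality/retention line
  sw2 <- toy_sweep()
  sw2$trc_snr[sw2$method == "qt"] <-
    c(20, 20, 22, 22, 24, 24) + c(0, 0, 2, 2, 0, 0)
  tr2 <- tradeoff_trend(sw2)
  expect_equal(tr2$recommended$sci_thr, 0.5)
  expect_gt(max(tr2$table$residual), 1)
  # rows reordered: same recommendation
  tr3 <- tradeoff_trend(sw2[rev(seq_len(nrow(sw2))), ])
  expect_equal(tr3$recommended, tr2$recommended)
  # collinear cloud (snr exactly linear in cr): retention-preferring fallback
  sw3 <- toy_sweep()
  sw3$trc_snr[sw3$method == "qt"] <- c(19.5, 20.5, 20.5, 21.5, 23.5, 24.5)
  tr4 <- tradeoff_trend(sw3)
  expect_equal(tr4$recommended$mean_cr, max(tr4$table$mean_cr))
  expect_error(tradeoff_trend(sw3[sw3$sci_thr %in% 0.2, ]), "3 grid points")
})
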