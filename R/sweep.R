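#' Threshold sweep grid
#'
#' The default grids cover SCI thresholds 0.05 to 0.9 in steps of 0.05
#' (18 values) and PSP thresholds 0.005 to 0.1 in steps of 0.005
#' (20 values): the full range below the adult reference values
#' (SCI 0.8, PSP 0.1), which infant data frequently undershoots.
#'
#' @param sci increasing SCI threshold values in \code{[0, 1]}.
#' @param psp increasing non-negative PSP threshold values.
#' @return An object of class \code{sweep_grid}.
#' @export
sweep_grid <- function(sci = seq(0.05, 0.9, by = 0.05),
                       psp = seq(0.005, 0.1, by = 0.005)) {
  stopifnot(length(sci) >= 1, length(psp) >= 1,
            all(diff(sci) > 0), all(diff(psp) > 0),
            min(sci) >= 0, max(sci) <= 1, min(psp) >= 0)
  structure(list(sci = sci, psp = psp), class = "sweep_grid")
}

#' Mean SNR over retained task-relevant channels
#'
#' The per-channel SNR is \code{snr_db} on the concatenation of the
#' channel's clean-window samples, averaged over the two wavelengths; the
#' TRC SNR is its arithmetic mean over the retained task-relevant
#' channels.
#'
#' @param rec a [raw_recording()].
#' @param pruning a \code{pruning_result}.
#' @param trc_set non-empty integer vector of task-relevant channel
#'   indices.
#' @param clean clean-window index list; \code{NULL} uses all windows.
#' @param window_s window length for the grid (default 3 s).
#' @return Mean SNR in dB, or \code{NA} if no TRC is retained.
#' @export
trc_snr <- function(rec, pruning, trc_set, clean = NULL, window_s = 3) {
  if (length(trc_set) == 0L) stop("trc_set must not be empty")
  stopifnot(inherits(pruning, "pruning_result"))
  retained <- pruning$channel[pruning$status == "retained"]
  keep <- intersect(trc_set, retained)
  if (length(keep) == 0L) return(NA_real_)
  grid <- window_grid(n_samples(rec), rec$sampling_rate, window_s)
  vals <- vapply(keep, function(ch) .channel_snr(rec, ch, clean, grid),
                 numeric(1))
  mean(vals)
}

.channel_snr <- function(rec, ch, clean, grid) {
  idx <- if (is.null(clean)) grid$window else intersect(clean[[ch]], grid$window)
  if (length(idx) == 0L) return(NA_real_)
  samp <- unlist(lapply(idx, function(wi) grid$start[wi]:grid$end[wi]))
  mean(c(snr_db(rec$intensity[samp, ch, 1]),
         snr_db(rec$intensity[samp, ch, 2])))
}

# precompute everything threshold-independent for one participant
.participant_prep <- function(rec, qt_base, motion_cfg, trc_set) {
  nc <- n_channels(rec)
  cse <- find_cse(rec)
  grid <- window_grid(n_samples(rec), rec$sampling_rate, qt_base$window_s)
  mask <- detect_motion(rec, motion_cfg)
  clean <- clean_windows(mask, grid)
  acceptable <- setdiff(seq_len(nc), cse)
  pom <- if (length(acceptable)) percent_motion(mask, grid, acceptable) else NA_real_
  quality <- evaluate_quality(rec, qt_base, clean, acceptable)
  n_clean <- vapply(seq_len(nc), function(ch) length(clean[[ch]]), integer(1))
  snr_ch <- rep(NA_real_, nc)
  for (ch in acceptable)
    snr_ch[ch] <- .channel_snr(rec, ch, clean, grid)
  list(cse = cse, grid = grid, clean = clean, pom = pom,
       quality = quality, n_clean = n_clean, snr_ch = snr_ch,
       acceptable = acceptable, rec = rec)
}

# retained channel set at one (sci, psp) threshold pair, from the
# precomputed quality table
.retained_at <- function(prep, sci_thr, psp_thr, q_threshold) {
  q <- prep$quality
  good <- !is.na(q$sci) & !is.na(q$psp) &
    (sci_thr <= 0 | q$sci > sci_thr) & (psp_thr <= 0 | q$psp > psp_thr)
  ngood <- tapply(good, factor(q$channel, levels = seq_along(prep$n_clean)),
                  sum, default = 0L)
  frac <- ifelse(prep$n_clean > 0, as.numeric(ngood) / prep$n_clean, NA)
  ok <- !is.na(frac) & frac >= q_threshold
  setdiff(which(ok), prep$cse)
}

#' Participant-level exclusion rule
#'
#' A participant is excluded from downstream analysis of a pruning
#' configuration when fewer than \code{frac} (default 60\%) of their
#' acceptable (non-CSE) channels survive pruning.
#'
#' @param cr channels retained.
#' @param acceptable_channel_count number of non-CSE channels.
#' @param frac exclusion fraction (default 0.6).
#' @return Logical: \code{TRUE} when excluded.
#' @export
exclusion_rule <- function(cr, acceptable_channel_count, frac = 0.6) {
  if (acceptable_channel_count == 0) return(TRUE)
  cr < frac * acceptable_channel_count
}

#' Run the full threshold sweep over a cohort
#'
#' For every participant, motion masks, clean windows, per-window SCI/PSP
#' and per-channel SNR are computed once; each grid point then only
#' re-counts windows against its thresholds. Emits one row per
#' participant for CV pruning (\code{method = "cv"}), one per SCI value
#' for the SCI-only variant (\code{method = "sci_only"},
#' \code{psp_thr = 0}) and one per grid point for the full procedure
#' (\code{method = "qt"}).
#'
#' @param cohort output of [generate_cohort()], or a list with elements
#'   \code{participants} (data.frame with id/age_months/cohort/task) and
#'   \code{recordings} (list of \code{list(recording, ...)}).
#' @param grid a [sweep_grid()].
#' @param qt_base a [qt_config()] carrying window length, band and
#'   \code{q_threshold}.
#' @param motion_cfg a [motion_config()].
#' @param cv_cfg a [cv_config()].
#' @param trc_set task-relevant channel indices.
#' @param exclusion_frac participant-exclusion fraction (default 0.6).
#' @return data.frame of sweep rows: \code{id, age_months, cohort, task,
#'   method, sci_thr, psp_thr, cr, trc_snr, excluded, pom, cse_count,
#'   acceptable}.
#' @export
run_sweep <- function(cohort, grid = sweep_grid(), qt_base = qt_config(),
                      motion_cfg = motion_config(), cv_cfg = cv_config(),
                      trc_set = c(8:10, 25:27), exclusion_frac = 0.6) {
  stopifnot(inherits(grid, "sweep_grid"))
  ptab <- cohort$participants
  rows <- vector("list", nrow(ptab))
  for (p in seq_len(nrow(ptab))) {
    rec <- cohort$recordings[[p]]$recording
    prep <- .participant_prep(rec, qt_base, motion_cfg, trc_set)
    nacc <- length(prep$acceptable)
    meta <- ptab[p, c("id", "age_months", "cohort", "task")]

    row_of <- function(method, sci_thr, psp_thr, retained_set) {
      cr <- length(retained_set)
      keep <- intersect(trc_set, retained_set)
      snr <- if (length(keep)) mean(prep$snr_ch[keep]) else NA_real_
      data.frame(meta, method = method, sci_thr = sci_thr,
                 psp_thr = psp_thr, cr = cr, trc_snr = snr,
                 excluded = exclusion_rule(cr, nacc, exclusion_frac),
                 pom = prep$pom, cse_count = length(prep$cse),
                 acceptable = nacc, row.names = NULL)
    }

    cvres <- prune_cv(rec, prep$clean, cv_cfg, prep$cse, qt_base$window_s)
    out <- list(row_of("cv", NA_real_, NA_real_,
                       cvres$channel[cvres$status == "retained"]))
    for (s in grid$sci)
      out[[length(out) + 1L]] <-
        row_of("sci_only", s, 0, .retained_at(prep, s, 0, qt_base$q_threshold))
    for (s in grid$sci) for (pp in grid$psp)
      out[[length(out) + 1L]] <-
        row_of("qt", s, pp, .retained_at(prep, s, pp, qt_base$q_threshold))
    rows[[p]] <- do.call(rbind, out)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Retention-matched parameter selection against CV pruning
#'
#' Ranks every grid point of a sweep method by (i) the absolute
#' difference between its cohort-mean channels retained and CV pruning's,
#' and (ii) the absolute difference in the number of excluded
#' participants; ranks (average ties) are summed and the grid point with
#' the minimal rank sum is selected. Rank-sum ties are broken toward
#' lower thresholds (SCI first, then PSP), consistent with recommending
#' the least aggressive matching configuration.
#'
#' @param sweep a [run_sweep()] table.
#' @param method \code{"qt"} or \code{"sci_only"}.
#' @return list with \code{table} (one row per grid point: mean CR,
#'   exclusions, distances, ranks) and \code{selected} (the chosen row).
#' @export
match_to_cv <- function(sweep, method = c("qt", "sci_only")) {
  method <- match.arg(method)
  if (nrow(sweep) == 0L) stop("empty sweep table")
  cv <- sweep[sweep$method == "cv", , drop = FALSE]
  if (nrow(cv) == 0L) stop("sweep table has no CV rows")
  mcv <- mean(cv$cr)
  ecv <- sum(cv$excluded)
  qt <- sweep[sweep$method == method, , drop = FALSE]
  if (nrow(qt) == 0L) stop("sweep table has no '", method, "' rows")
  key <- interaction(qt$sci_thr, qt$psp_thr, drop = TRUE)
  agg <- data.frame(
    sci_thr = tapply(qt$sci_thr, key, `[`, 1),
    psp_thr = tapply(qt$psp_thr, key, `[`, 1),
    mean_cr = as.numeric(tapply(qt$cr, key, mean)),
    n_excluded = as.numeric(tapply(qt$excluded, key, sum)))
  agg$d_cr <- abs(agg$mean_cr - mcv)
  agg$d_excl <- abs(agg$n_excluded - ecv)
  agg$rank_cr <- rank(agg$d_cr, ties.method = "average")
  agg$rank_excl <- rank(agg$d_excl, ties.method = "average")
  agg$rank_combined <- agg$rank_cr + agg$rank_excl
  agg <- agg[order(agg$sci_thr, agg$psp_thr), , drop = FALSE]
  rownames(agg) <- NULL
  sel <- which(agg$rank_combined == min(agg$rank_combined))[1L]
  list(table = agg, selected = agg[sel, , drop = FALSE],
       cv_mean_cr = mcv, cv_n_excluded = ecv)
}

#' Quality/retention trade-off trend
#'
#' Fits a monotone non-increasing trend of the grid-point mean TRC SNR
#' against the grid-point mean channels retained -- a least-squares line
#' with its slope constrained to be non-positive (quality cannot
#' improve with laxer retention along the trend) -- and scores each grid
#' point by its residual above the trend. An unconstrained pointwise
#' monotone fit would interpolate any already-monotone cloud exactly and
#' make every residual zero, so the smooth constrained line is what
#' makes "above the trend at comparable retention" detectable.
#' Recommended combinations are those with the maximal positive
#' residual; when the cloud is effectively on the trend (residual range
#' below \code{tol}), the recommendation falls back to the
#' retention-preferring choice (highest mean CR, then lowest
#' thresholds).
#'
#' @param sweep a [run_sweep()] table (rows with \code{method = "qt"}).
#' @param tol residual range under which the trend is considered exact.
#' @return list with \code{table} (grid point, mean CR, mean TRC SNR,
#'   trend, residual) and \code{recommended} (single row).
#' @export
tradeoff_trend <- function(sweep, tol = 1e-8) {
  qt <- sweep[sweep$method == "qt" & !is.na(sweep$trc_snr), , drop = FALSE]
  key <- interaction(qt$sci_thr, qt$psp_thr, drop = TRUE)
  agg <- data.frame(
    sci_thr = as.numeric(tapply(qt$sci_thr, key, `[`, 1)),
    psp_thr = as.numeric(tapply(qt$psp_thr, key, `[`, 1)),
    mean_cr = as.numeric(tapply(qt$cr, key, mean)),
    mean_snr = as.numeric(tapply(qt$trc_snr, key, mean)))
  if (nrow(agg) < 3L) stop("need at least 3 grid points with defined TRC SNR")
  vx <- stats::var(agg$mean_cr)
  b <- if (vx > 0) min(0, stats::cov(agg$mean_cr, agg$mean_snr) / vx) else 0
  a <- mean(agg$mean_snr) - b * mean(agg$mean_cr)
  agg$trend <- a + b * agg$mean_cr
  agg$residual <- agg$mean_snr - agg$trend
  rownames(agg) <- NULL
  if (diff(range(agg$residual)) < tol) {
    cand <- agg[order(-agg$mean_cr, agg$sci_thr, agg$psp_thr), , drop = FALSE]
  } else {
    best <- agg$residual > max(agg$residual) - tol
    cand <- agg[best, , drop = FALSE]
    cand <- cand[order(-cand$mean_cr, cand$sci_thr, cand$psp_thr), ,
                 drop = FALSE]
  }
  list(table = agg, recommended = cand[1L, , drop = FALSE])
}
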