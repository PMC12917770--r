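#' Motion-artifact detection parameters
#'
#' Amplitude/deviation artifact detection on optical-density changes with
#' the infant-preprocessing defaults: a 1-s sliding detection window
#' (\code{tMotion}), a 1-s mask dilation on each side of a detection
#' (\code{tMask}), a deviation multiplier of 15 on the whole-series
#' standard deviation of the sample-to-sample differences
#' (\code{stdev_thresh}), and an absolute amplitude criterion of 0.4
#' optical-density units (\code{amp_thresh}).
#'
#' @param tMotion detection window, seconds.
#' @param tMask mask dilation on each side of a detection, seconds.
#' @param stdev_thresh multiplier on the standard deviation of
#'   \code{diff(dOD)}.
#' @param amp_thresh amplitude (range) criterion in dOD units.
#' @return An object of class \code{motion_config}.
#' @export
motion_config <- function(tMotion = 1, tMask = 1, stdev_thresh = 15,
                          amp_thresh = 0.4) {
  stopifnot(tMotion > 0, tMask > 0, stdev_thresh > 0, amp_thresh > 0)
  structure(list(tMotion = tMotion, tMask = tMask,
                 stdev_thresh = stdev_thresh, amp_thresh = amp_thresh),
            class = "motion_config")
}

# flag samples of one dOD series: a sample is flagged when any
# tMotion-window covering it has range > amp_thresh or
# range > stdev_thresh * sd(diff(d)); flags then dilated +/- tMask s,
# truncated at the recording edges (no wraparound)
.detect_series <- function(d, fs, config) {
  n <- length(d)
  w <- round(config$tMotion * fs)
  if (w < 2) stop("tMotion must span at least 2 samples")
  if (n < w) return(rep(FALSE, n))
  dd <- diff(d)
  sd_diff <- sqrt(mean((dd - mean(dd))^2))
  thr <- min(config$amp_thresh, config$stdev_thresh * sd_diff)
  em <- stats::embed(d, w)                 # rows: windows ending at w..n
  rng <- do.call(pmax, as.data.frame(em)) - do.call(pmin, as.data.frame(em))
  bad_start <- which(rng > thr)            # window i covers samples i..i+w-1
  flag <- rep(FALSE, n)
  if (length(bad_start)) {
    delta <- integer(n + 1L)
    delta[bad_start] <- delta[bad_start] + 1L
    delta[bad_start + w] <- delta[bad_start + w] - 1L
    flag <- cumsum(delta[seq_len(n)]) > 0L
    # dilate runs by tMask seconds each side
    m <- round(config$tMask * fs)
    if (m > 0) {
      r <- rle(flag)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      delta2 <- integer(n + 2L)
      for (j in which(r$values)) {
        a <- max(1L, starts[j] - m)
        b <- min(n, ends[j] + m)
        delta2[a] <- delta2[a] + 1L
        delta2[b + 1L] <- delta2[b + 1L] - 1L
      }
      flag <- cumsum(delta2[seq_len(n)]) > 0L
    }
  }
  flag
}

#' Detect motion artifacts per channel
#'
#' Converts the recording to optical-density changes, runs the sliding
#' range detector on each wavelength separately, and combines wavelengths
#' by union: an artifact on either wavelength flags the channel at that
#' sample. The deviation criterion is anchored on the whole-series
#' standard deviation of the first-difference series (population
#' convention), so a brief large excursion is judged against the typical
#' sample-to-sample variability of the channel.
#'
#' Note that when \code{stdev_thresh * sd(diff(dOD))} is smaller than
#' \code{amp_thresh} the deviation criterion governs: detection uses the
#' stricter (smaller) of the two range cuts, matching an OR of the two
#' exceedance tests.
#'
#' @param rec a [raw_recording()].
#' @param config a [motion_config()].
#' @param channels channel indices (default all).
#' @return Logical matrix \code{[n_samples, n_channels]} of artifact
#'   flags, class \code{motion_mask}, with the window grid parameters kept
#'   as attributes.
#' @export
detect_motion <- function(rec, config = motion_config(),
                          channels = seq_len(n_channels(rec))) {
  stopifnot(inherits(rec, "nirs_recording"),
            inherits(config, "motion_config"))
  dod <- optical_density(rec)
  fs <- rec$sampling_rate
  mask <- matrix(FALSE, n_samples(rec), n_channels(rec))
  for (ch in channels) {
    f <- .detect_series(dod[, ch, 1], fs, config)
    for (wl in seq_len(dim(dod)[3])[-1])
      f <- f | .detect_series(dod[, ch, wl], fs, config)
    mask[, ch] <- f
  }
  structure(mask, class = c("motion_mask", "matrix"))
}

#' Clean-window index sets
#'
#' A window is clean for a channel iff no flagged sample (at either
#' wavelength, already combined in the mask) falls inside it.
#'
#' @param mask a [detect_motion()] mask.
#' @param grid a [window_grid()].
#' @return List (one element per channel) of integer vectors of clean
#'   window indices.
#' @export
clean_windows <- function(mask, grid) {
  lapply(seq_len(ncol(mask)), function(ch) {
    dirty <- vapply(seq_len(nrow(grid)), function(wi) {
      any(mask[grid$start[wi]:grid$end[wi], ch])
    }, logical(1))
    grid$window[!dirty]
  })
}

#' Percentage of motion (PoM)
#'
#' Cross-channel mean of the percentage of windows per channel containing
#' detected motion. Computed over the supplied channels (conventionally
#' the non-CSE channels).
#'
#' @param mask a [detect_motion()] mask.
#' @param grid a [window_grid()].
#' @param channels channel indices to include (default all).
#' @return Scalar percentage in \code{[0, 100]}.
#' @export
percent_motion <- function(mask, grid, channels = seq_len(ncol(mask))) {
  if (nrow(grid) == 0L) stop("window grid is empty")
  if (length(channels) == 0L) stop("no channels supplied")
  per_channel <- vapply(channels, function(ch) {
    dirty <- vapply(seq_len(nrow(grid)), function(wi) {
      any(mask[grid$start[wi]:grid$end[wi], ch])
    }, logical(1))
    100 * sum(dirty) / nrow(grid)
  }, numeric(1))
  mean(per_channel)
}

#' Export a motion mask as interval lists
#'
#' @param mask a [detect_motion()] mask.
#' @param sampling_rate Hz.
#' @return data.frame with columns \code{channel}, \code{onset_s},
#'   \code{offset_s} (half-open, seconds from recording start).
#' @export
motion_intervals <- function(mask, sampling_rate) {
  out <- lapply(seq_len(ncol(mask)), function(ch) {
    r <- rle(as.logical(mask[, ch]))
    if (!any(r$values)) return(NULL)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(channel = ch,
               onset_s = (starts[keep] - 1L) / sampling_rate,
               offset_s = ends[keep] / sampling_rate)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(channel = integer(), onset_s = numeric(),
                      offset_s = numeric())
  out
}
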