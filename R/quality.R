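#' Coefficient of variation of an intensity signal
#'
#' \eqn{CV = \sigma / |\mu|} with the population standard deviation
#' (denominator \eqn{n}). The package uses the population convention for
#' every signal-level moment; the statistics stage uses the sample
#' convention for variable scaling (see [scale_center()]).
#'
#' @param x numeric vector, non-empty and finite.
#' @return Non-negative scalar; \code{Inf} when the mean is exactly zero.
#' @export
coefficient_of_variation <- function(x) {
  if (length(x) == 0L) stop("empty signal")
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  mu <- mean(x)
  sd_pop <- sqrt(mean((x - mu)^2))
  if (mu == 0) return(Inf)
  sd_pop / abs(mu)
}

#' Signal-to-noise ratio in decibels
#'
#' \eqn{SNR = 20 \log_{10}(\mu/\sigma)} with population \eqn{\sigma}.
#' Defined for intensity-like signals with a positive mean.
#'
#' @param x numeric vector with \code{mean(x) > 0}.
#' @return SNR in dB; \code{Inf} for a noiseless (constant) signal.
#' @export
snr_db <- function(x) {
  if (length(x) == 0L) stop("empty signal")
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  mu <- mean(x)
  if (mu <= 0) stop("snr_db requires a positive-mean (intensity) signal")
  sd_pop <- sqrt(mean((x - mu)^2))
  if (sd_pop == 0) return(Inf)
  20 * log10(mu / sd_pop)
}

#' Cardiac band-pass filter
#'
#' Zero-phase (forward-backward) Butterworth band-pass restricted to the
#' infant cardiac band, 1.3 to 3.2 Hz by default. Order 3 per pass; the
#' forward-backward application doubles the effective order and cancels the
#' phase, which keeps the two wavelengths' cardiac components aligned for
#' the zero-lag correlation.
#'
#' @param x numeric vector.
#' @param sampling_rate Hz.
#' @param band length-2 numeric, Hz; must lie strictly inside
#'   \code{(0, sampling_rate/2)}.
#' @return Filtered vector, same length as \code{x}.
#' @export
bandpass_cardiac <- function(x, sampling_rate, band = c(1.3, 3.2)) {
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stop("'band' must be an increasing positive pair (Hz)")
  nyq <- sampling_rate / 2
  if (band[2] >= nyq) stop("upper band edge must be below the Nyquist frequency")
  bf <- signal::butter(3, band / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' QT-style quality-threshold configuration
#'
#' Parameters of the windowed SCI/PSP assessment: the two per-window
#' thresholds, the minimum fraction of good windows a channel needs
#' (\code{q_threshold}, default 0.75), the window length (default 3 s) and
#' the cardiac band.
#'
#' @param sci_threshold per-window SCI cut, in \code{[0, 1]}.
#' @param psp_threshold per-window PSP cut, non-negative.
#' @param q_threshold minimum good-window fraction for retention.
#' @param window_s window length, seconds.
#' @param cardiac_band Hz interval for [bandpass_cardiac()].
#' @return An object of class \code{qt_config}.
#' @export
qt_config <- function(sci_threshold = 0.6, psp_threshold = 0.045,
                      q_threshold = 0.75, window_s = 3,
                      cardiac_band = c(1.3, 3.2)) {
  stopifnot(sci_threshold >= 0, sci_threshold <= 1,
            psp_threshold >= 0,
            q_threshold >= 0, q_threshold <= 1,
            window_s > 0,
            length(cardiac_band) == 2L, cardiac_band[1] > 0,
            cardiac_band[2] > cardiac_band[1])
  structure(list(sci_threshold = sci_threshold,
                 psp_threshold = psp_threshold,
                 q_threshold = q_threshold,
                 window_s = window_s,
                 cardiac_band = cardiac_band),
            class = "qt_config")
}

#' Non-overlapping window partition
#'
#' Partitions \code{n_samples} into consecutive, non-overlapping windows of
#' \code{round(window_s * sampling_rate)} samples starting at the first
#' sample; a trailing partial window is discarded. Windows are returned as
#' 1-based inclusive sample ranges; the underlying convention is half-open
#' (a sample on the boundary belongs to the later window).
#'
#' @param n_samples recording length in samples.
#' @param sampling_rate Hz.
#' @param window_s window length in seconds (default 3).
#' @return data.frame with columns \code{window}, \code{start}, \code{end}.
#' @export
window_grid <- function(n_samples, sampling_rate, window_s = 3) {
  w <- round(window_s * sampling_rate)
  if (w < 2) stop("window must span at least 2 samples")
  k <- n_samples %/% w
  if (k == 0L)
    return(data.frame(window = integer(), start = integer(), end = integer()))
  start <- (seq_len(k) - 1L) * w + 1L
  data.frame(window = seq_len(k), start = start, end = start + w - 1L)
}

# population z-scoring of a window signal; NULL flags a degenerate
# (zero-variance) window
.normalize_window <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0 || !is.finite(s)) return(NULL)
  (x - mu) / s
}

#' Scalp coupling index of one window
#'
#' Zero-lag cross-correlation of the two wavelengths' normalized,
#' cardiac-band-filtered window signals; identical to the Pearson
#' correlation of the filtered window samples. High when the cardiac pulse
#' is present coherently in both wavelengths.
#'
#' @param x1,x2 band-pass-filtered window signals of equal length.
#' @return Scalar in \code{[-1, 1]}; \code{NA} for a degenerate
#'   (zero-variance) window, which downstream counts as a failing window.
#' @export
sci_window <- function(x1, x2) {
  stopifnot(length(x1) == length(x2), length(x1) >= 2L)
  z1 <- .normalize_window(x1)
  z2 <- .normalize_window(x2)
  if (is.null(z1) || is.null(z2)) return(NA_real_)
  mean(z1 * z2)
}

#' Peak spectral power of one window
#'
#' Cross-wavelength spectral coherence measure: the unbiased lagged
#' cross-correlation sequence of the two normalized window signals is
#' computed over all lags, and PSP is the maximum of its one-sided
#' normalized power spectrum (DC excluded). A perfectly coherent pure
#' sinusoid pair scores about 0.24 at the default 3-s window; independent
#' broadband noise scores about 0.02. The discrete formula is the
#' contract: a brute-force lag-domain oracle reproduces it exactly.
#'
#' @param x1,x2 band-pass-filtered window signals of equal length.
#' @param sampling_rate Hz (kept for interface symmetry; the maximum is
#'   taken over the full one-sided spectrum and does not depend on the
#'   frequency axis labelling).
#' @return Non-negative scalar; \code{NA} for a degenerate window.
#' @export
psp_window <- function(x1, x2, sampling_rate = NULL) {
  stopifnot(length(x1) == length(x2), length(x1) >= 2L)
  z1 <- .normalize_window(x1)
  z2 <- .normalize_window(x2)
  if (is.null(z1) || is.null(z2)) return(NA_real_)
  N <- length(z1)
  cc <- .xcorr_unbiased(z1, z2)
  M <- length(cc)                       # 2N - 1
  P <- 2 * Mod(stats::fft(cc))^2 / M^2  # one-sided normalized power
  max(P[2:(M %/% 2 + 1L)])
}

# unbiased lagged cross-correlation c_k = sum(z1[n] z2[n+k]) / (N - |k|),
# lags -(N-1) .. (N-1)
.xcorr_unbiased <- function(z1, z2) {
  N <- length(z1)
  lags <- -(N - 1L):(N - 1L)
  vapply(lags, function(k) {
    if (k >= 0) sum(z1[1:(N - k)] * z2[(1 + k):N]) / (N - k)
    else        sum(z1[(1 - k):N] * z2[1:(N + k)]) / (N + k)
  }, numeric(1))
}

#' Windowed quality of one channel
#'
#' Band-pass-filters both wavelengths of one channel over the whole
#' recording, then computes SCI and PSP in every motion-free window.
#' Degenerate windows yield \code{NA} metrics and count as failing (flat
#' data is bad data), but remain in the clean-window denominator.
#'
#' @param rec a [raw_recording()].
#' @param channel channel index.
#' @param config a [qt_config()].
#' @param clean_idx integer vector of clean window indices for this channel
#'   (from [clean_windows()]); \code{NULL} means all windows.
#' @return data.frame with columns \code{window}, \code{sci}, \code{psp},
#'   one row per clean window; attribute \code{n_clean}.
#' @export
channel_quality <- function(rec, channel, config = qt_config(),
                            clean_idx = NULL) {
  stopifnot(inherits(rec, "nirs_recording"), inherits(config, "qt_config"))
  fs <- rec$sampling_rate
  grid <- window_grid(n_samples(rec), fs, config$window_s)
  if (is.null(clean_idx)) clean_idx <- grid$window
  clean_idx <- sort(intersect(clean_idx, grid$window))
  f1 <- bandpass_cardiac(rec$intensity[, channel, 1], fs, config$cardiac_band)
  f2 <- bandpass_cardiac(rec$intensity[, channel, 2], fs, config$cardiac_band)
  res <- lapply(clean_idx, function(wi) {
    s <- grid$start[wi]; e <- grid$end[wi]
    c(sci = sci_window(f1[s:e], f2[s:e]),
      psp = psp_window(f1[s:e], f2[s:e]))
  })
  out <- data.frame(window = clean_idx,
                    sci = vapply(res, `[[`, numeric(1), "sci"),
                    psp = vapply(res, `[[`, numeric(1), "psp"))
  attr(out, "n_clean") <- length(clean_idx)
  out
}

#' Fraction of windows passing both quality thresholds
#'
#' \code{(number of clean windows with SCI > sci_thr and PSP > psp_thr) /
#' (number of clean windows)}. \code{NA} metrics (degenerate windows) fail
#' the test but stay in the denominator, so the fraction is jointly
#' non-increasing in both thresholds. A threshold of zero (or below)
#' disables its conjunct entirely -- this is how the SCI-only variant is
#' constructed, and it makes the \code{(0, 0)} configuration vacuous for
#' every non-degenerate window.
#'
#' @param quality output of [channel_quality()].
#' @param sci_thr,psp_thr per-window thresholds (strict \code{>}).
#' @return Fraction in \code{[0, 1]}; \code{NA} if there are no clean
#'   windows.
#' @export
good_fraction <- function(quality, sci_thr, psp_thr) {
  n <- attr(quality, "n_clean")
  if (is.null(n)) n <- nrow(quality)
  if (n == 0L) return(NA_real_)
  good <- !is.na(quality$sci) & !is.na(quality$psp) &
    (sci_thr <= 0 | quality$sci > sci_thr) &
    (psp_thr <= 0 | quality$psp > psp_thr)
  sum(good) / n
}

#' Per-window quality table for all channels
#'
#' Convenience wrapper over [channel_quality()]: one long table for the
#' whole array, suitable for CSV export and for the threshold sweep (the
#' per-window metrics do not depend on the thresholds, so a full grid
#' sweep only re-counts rows of this table).
#'
#' @param rec a [raw_recording()].
#' @param config a [qt_config()].
#' @param clean list of clean-window index vectors per channel (from
#'   [clean_windows()]); \code{NULL} means all windows for every channel.
#' @param channels channel indices to evaluate (default all).
#' @return data.frame with columns \code{channel}, \code{window},
#'   \code{sci}, \code{psp}.
#' @export
evaluate_quality <- function(rec, config = qt_config(), clean = NULL,
                             channels = seq_len(n_channels(rec))) {
  out <- lapply(channels, function(ch) {
    ci <- if (is.null(clean)) NULL else clean[[ch]]
    q <- channel_quality(rec, ch, config, ci)
    if (nrow(q) == 0L) return(NULL)
    cbind(channel = ch, q)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(channel = integer(), window = integer(),
                      sci = numeric(), psp = numeric())
  out
}
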