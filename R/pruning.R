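#' CV-difference pruning parameters
#'
#' @param diff_threshold maximum allowed absolute difference between the
#'   two wavelengths' coefficients of variation (default 0.2).
#' @param strict if \code{TRUE} (default) a channel is pruned only when the
#'   difference strictly exceeds the threshold; set \code{FALSE} for the
#'   "differs by the threshold or more" reading.
#' @return An object of class \code{cv_config}.
#' @export
cv_config <- function(diff_threshold = 0.2, strict = TRUE) {
  stopifnot(diff_threshold > 0)
  structure(list(diff_threshold = diff_threshold, strict = strict),
            class = "cv_config")
}

#' Channels with signal extrema (CSE)
#'
#' Flags channels whose minimum raw light intensity, over all samples and
#' both wavelengths, falls below \code{min_intensity} (default
#' \code{3e-4}): implausibly low intensities indicate a dead or decoupled
#' channel and are excluded before any other analysis. The check uses raw
#' intensities and is independent of motion masks; it is idempotent.
#'
#' @param rec a [raw_recording()].
#' @param min_intensity detector-units cutoff.
#' @return Integer vector of CSE channel indices (possibly empty).
#' @export
find_cse <- function(rec, min_intensity = 3e-4) {
  stopifnot(inherits(rec, "nirs_recording"))
  mins <- apply(rec$intensity, 2, min)
  which(mins < min_intensity)
}

.pruning_result <- function(status, method, params) {
  stopifnot(all(status %in% c("retained", "pruned_cv", "pruned_qt",
                              "excluded_cse", "excluded_no_clean_windows")))
  structure(
    data.frame(channel = seq_along(status), status = status,
               stringsAsFactors = FALSE),
    method = method, params = params,
    class = c("pruning_result", "data.frame"))
}

#' Channels retained (CR)
#'
#' @param result a pruning result from [prune_cv()], [prune_qtnirs()] or
#'   [prune_sci_only()].
#' @return Count of channels with status \code{retained}.
#' @export
channels_retained <- function(result) {
  stopifnot(inherits(result, "pruning_result"))
  sum(result$status == "retained")
}

#' @export
print.pruning_result <- function(x, ...) {
  cat(sprintf("<pruning_result> method=%s, %d/%d channels retained\n",
              attr(x, "method"), sum(x$status == "retained"), nrow(x)))
  print(table(x$status))
  invisible(x)
}

#' CV-difference channel pruning
#'
#' For each channel, the coefficient of variation is computed per
#' wavelength on the motion-free data (the concatenation of the clean
#' windows' samples); the channel is pruned when the two wavelengths'
#' CVs differ by more than \code{diff_threshold}. A channel with no clean
#' windows cannot be certified and is excluded.
#'
#' @param rec a [raw_recording()].
#' @param clean list of clean window indices per channel
#'   ([clean_windows()]); \code{NULL} uses all windows.
#' @param config a [cv_config()].
#' @param cse CSE channel indices ([find_cse()]); these are marked
#'   \code{excluded_cse} and skip the CV test.
#' @param window_s window length used for the grid (default 3 s).
#' @return A \code{pruning_result}.
#' @export
prune_cv <- function(rec, clean = NULL, config = cv_config(),
                     cse = integer(), window_s = 3) {
  stopifnot(inherits(rec, "nirs_recording"), inherits(config, "cv_config"))
  grid <- window_grid(n_samples(rec), rec$sampling_rate, window_s)
  nc <- n_channels(rec)
  status <- character(nc)
  for (ch in seq_len(nc)) {
    if (ch %in% cse) { status[ch] <- "excluded_cse"; next }
    idx <- if (is.null(clean)) grid$window else intersect(clean[[ch]], grid$window)
    if (length(idx) == 0L) { status[ch] <- "excluded_no_clean_windows"; next }
    samp <- unlist(lapply(idx, function(wi) grid$start[wi]:grid$end[wi]))
    cvd <- abs(coefficient_of_variation(rec$intensity[samp, ch, 1]) -
               coefficient_of_variation(rec$intensity[samp, ch, 2]))
    exceeded <- if (config$strict) cvd > config$diff_threshold
                else cvd >= config$diff_threshold
    status[ch] <- if (exceeded) "pruned_cv" else "retained"
  }
  .pruning_result(status, "cv", config)
}

#' Windowed SCI/PSP channel pruning
#'
#' The quality-threshold procedure: each channel's clean windows are scored
#' with SCI and PSP in the cardiac band; a channel is retained iff the
#' fraction of windows passing both per-window thresholds is at least
#' \code{q_threshold} (default 0.75). Channels with no clean windows are
#' excluded (and count as not retained).
#'
#' @param rec a [raw_recording()].
#' @param clean clean-window index list ([clean_windows()]); \code{NULL}
#'   uses all windows.
#' @param config a [qt_config()].
#' @param cse CSE channel indices.
#' @param quality optional precomputed [evaluate_quality()] table for this
#'   recording (columns channel/window/sci/psp restricted to clean
#'   windows); supplying it avoids re-filtering when sweeping thresholds.
#' @param n_clean optional integer vector of clean-window counts per
#'   channel, required when \code{quality} is supplied.
#' @return A \code{pruning_result}.
#' @export
prune_qtnirs <- function(rec, clean = NULL, config = qt_config(),
                         cse = integer(), quality = NULL, n_clean = NULL) {
  stopifnot(inherits(rec, "nirs_recording"), inherits(config, "qt_config"))
  nc <- n_channels(rec)
  grid <- window_grid(n_samples(rec), rec$sampling_rate, config$window_s)
  if (is.null(quality)) {
    channels <- setdiff(seq_len(nc), cse)
    quality <- evaluate_quality(rec, config, clean, channels)
    n_clean <- vapply(seq_len(nc), function(ch) {
      if (is.null(clean)) nrow(grid)
      else length(intersect(clean[[ch]], grid$window))
    }, integer(1))
  }
  if (is.null(n_clean))
    stop("'n_clean' must accompany a precomputed 'quality' table")
  status <- character(nc)
  for (ch in seq_len(nc)) {
    if (ch %in% cse) { status[ch] <- "excluded_cse"; next }
    if (n_clean[ch] == 0L) { status[ch] <- "excluded_no_clean_windows"; next }
    q <- quality[quality$channel == ch, , drop = FALSE]
    attr(q, "n_clean") <- n_clean[ch]
    gf <- good_fraction(q, config$sci_threshold, config$psp_threshold)
    status[ch] <- if (!is.na(gf) && gf >= config$q_threshold) "retained"
                  else "pruned_qt"
  }
  .pruning_result(status, "qt", config)
}

#' SCI-only pruning variant
#'
#' [prune_qtnirs()] with the PSP test made vacuous by forcing
#' \code{psp_threshold = 0} (PSP is non-negative and must strictly exceed
#' 0, which any non-degenerate window does).
#'
#' @inheritParams prune_qtnirs
#' @return A \code{pruning_result} with method tag \code{"sci_only"}.
#' @export
prune_sci_only <- function(rec, clean = NULL, config = qt_config(),
                           cse = integer(), quality = NULL, n_clean = NULL) {
  config$psp_threshold <- 0
  out <- prune_qtnirs(rec, clean, config, cse, quality, n_clean)
  attr(out, "method") <- "sci_only"
  out
}
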