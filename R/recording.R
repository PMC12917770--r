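#' Two-wavelength raw intensity recording
#'
#' Container for a multi-channel fNIRS recording: raw light intensities for
#' every channel at two source wavelengths, plus the sampling rate and
#' free-form participant metadata. This is the universal input of the
#' package: the motion detector, the quality metrics and every pruning
#' method consume it.
#'
#' @param intensity numeric array of dimension
#'   \code{c(n_samples, n_channels, n_wavelengths)}; raw detector units,
#'   strictly positive for physically plausible data (near-zero values are
#'   how dead channels present, and are handled by [find_cse()]).
#' @param sampling_rate sampling frequency in Hz (scalar, > 0).
#' @param wavelengths numeric vector of source wavelengths in nm, one per
#'   slice of the third array dimension (default \code{c(780, 850)}).
#' @param metadata named list of participant-level fields (e.g. \code{id},
#'   \code{age_months}, \code{cohort}, \code{task}); stored verbatim.
#'
#' @return An object of class \code{nirs_recording}: a list with elements
#'   \code{intensity}, \code{sampling_rate}, \code{wavelengths},
#'   \code{metadata}.
#' @export
raw_recording <- function(intensity, sampling_rate,
                          wavelengths = c(780, 850), metadata = list()) {
  if (!is.array(intensity) || length(dim(intensity)) != 3L)
    stop("'intensity' must be a 3-d array [samples x channels x wavelengths]")
  d <- dim(intensity)
  if (d[1] < 1L || d[2] < 1L)
    stop("recording must contain at least one sample and one channel")
  if (length(wavelengths) != d[3])
    stop("length(wavelengths) must equal dim(intensity)[3]")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("'sampling_rate' must be a positive scalar (Hz)")
  if (!all(is.finite(intensity)))
    stop("intensity values must all be finite")
  structure(
    list(intensity = intensity,
         sampling_rate = as.numeric(sampling_rate),
         wavelengths = as.numeric(wavelengths),
         metadata = metadata),
    class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<nirs_recording> %d channels x %d wavelengths (%s nm), %d samples @ %g Hz (%.1f s)\n",
              d[2], d[3], paste(x$wavelengths, collapse = "/"),
              d[1], x$sampling_rate, d[1] / x$sampling_rate))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

n_channels <- function(rec) dim(rec$intensity)[2]
n_samples <- function(rec) dim(rec$intensity)[1]

#' Optical-density change series
#'
#' Converts raw intensities to optical-density changes
#' \eqn{\Delta OD(t) = -\ln(I(t)/\bar I)}, the working space of the motion
#' detector. The reference is the per-channel, per-wavelength mean
#' intensity.
#'
#' @param rec a [raw_recording()].
#' @return Array with the dimensions of \code{rec$intensity}.
#' @export
optical_density <- function(rec) {
  stopifnot(inherits(rec, "nirs_recording"))
  I <- rec$intensity
  if (any(I <= 0))
    I[I <= 0] <- .Machine$double.eps   # dead channels: clamp, they are CSE anyway
  m <- apply(I, c(2, 3), mean)
  sweep_ref <- aperm(array(m, dim = c(dim(I)[2], dim(I)[3], dim(I)[1])),
                     c(3, 1, 2))
  -log(I / sweep_ref)
}
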