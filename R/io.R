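#' Write a recording to a portable text file
#'
#' Serializes a recording to a structured JSON document mirroring the
#' layout of the shared NIRS format: probe wavelengths, sampling rate, a
#' measurement list (one entry per channel x wavelength) and the
#' intensity time series, plus the participant metadata. Values are
#' written at full double precision, so a round trip is lossless for
#' metadata and exact to storage precision for the data.
#'
#' @param rec a [raw_recording()].
#' @param path output file path (conventionally \code{.nirs.json}).
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "nirs_recording"))
  d <- dim(rec$intensity)
  meas <- expand.grid(channel = seq_len(d[2]), wavelength_index = seq_len(d[3]))
  doc <- list(
    format = "nirsprune-recording",
    version = 1L,
    sampling_rate = rec$sampling_rate,
    wavelengths = rec$wavelengths,
    n_samples = d[1],
    n_channels = d[2],
    metadata = rec$metadata,
    measurement_list = meas,
    data = lapply(seq_len(nrow(meas)), function(i) {
      rec$intensity[, meas$channel[i], meas$wavelength_index[i]]
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       always_decimal = FALSE)
  invisible(path)
}

.require_field <- function(doc, field) {
  if (is.null(doc[[field]]))
    stop(sprintf("malformed recording file: missing field '%s'", field))
  doc[[field]]
}

#' Read a recording written by [write_recording()]
#'
#' @param path file path.
#' @return A [raw_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  fmt <- .require_field(doc, "format")
  if (!identical(fmt, "nirsprune-recording"))
    stop("malformed recording file: unrecognized format tag '", fmt, "'")
  fs <- .require_field(doc, "sampling_rate")
  wl <- .require_field(doc, "wavelengths")
  ns <- .require_field(doc, "n_samples")
  nc <- .require_field(doc, "n_channels")
  meas <- .require_field(doc, "measurement_list")
  dat <- .require_field(doc, "data")
  if (is.matrix(dat)) dat <- lapply(seq_len(nrow(dat)), function(i) dat[i, ])
  if (length(dat) != nrow(meas))
    stop("malformed recording file: data block does not match measurement_list")
  I <- array(NA_real_, dim = c(ns, nc, length(wl)))
  for (i in seq_len(nrow(meas))) {
    series <- as.numeric(dat[[i]])
    if (length(series) != ns)
      stop("malformed recording file: measurement ", i, " has wrong length")
    I[, meas$channel[i], meas$wavelength_index[i]] <- series
  }
  md <- doc$metadata
  if (is.null(md)) md <- list()
  raw_recording(I, fs, wl, as.list(md))
}
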