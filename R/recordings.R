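#' Uniformly sampled single-channel recording
#'
#' Container for one uniformly sampled channel: skin conductance in
#' microsiemens, or a single acceleration axis in m/s^2. Sample `n`
#' (1-based) is implicitly timestamped `start_epoch + (n - 1) / fs`.
#'
#' @param samples Numeric vector of samples, finite, length >= 1.
#' @param fs Sampling frequency in Hz (> 0).
#' @param start_epoch Session start, seconds since the Unix epoch.
#' @param units One of `"uS"`, `"m_s2"`, `"raw"`.
#'
#' @return An object of class `sc_recording`.
#' @examples
#' rec <- sc_recording(c(0.50, 0.52, 0.51), fs = 4)
#' rec
#' @export
sc_recording <- function(samples, fs, start_epoch = 0,
                         units = c("uS", "m_s2", "raw")) {
  units <- match.arg(units)
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  if (length(samples) < 1L) {
    abort("empty channel: a recording needs at least one sample.")
  }
  if (!all(is.finite(samples))) {
    abort("samples must all be finite.")
  }
  structure(
    list(samples = samples, fs = as.numeric(fs),
         start_epoch = as.numeric(start_epoch), units = units),
    class = "sc_recording"
  )
}

#' Triaxial accelerometer recording
#'
#' @param x,y,z Equal-length numeric vectors, one per axis, in m/s^2.
#' @param fs Sampling frequency in Hz (> 0).
#' @param start_epoch Session start, seconds since the Unix epoch.
#'
#' @return An object of class `triaxial_recording`.
#' @export
triaxial_recording <- function(x, y, z, fs, start_epoch = 0) {
  if (length(x) != length(y) || length(y) != length(z)) {
    abort("the three acceleration axes must have equal length.")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  if (length(x) < 1L) abort("empty recording.")
  structure(
    list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
         fs = as.numeric(fs), start_epoch = as.numeric(start_epoch),
         units = "m_s2"),
    class = "triaxial_recording"
  )
}

#' @export
print.sc_recording <- function(x, ...) {
  cat(sprintf("<sc_recording> %d samples @ %g Hz (%.1f s), units %s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$units))
  invisible(x)
}

#' @export
print.triaxial_recording <- function(x, ...) {
  cat(sprintf("<triaxial_recording> %d samples/axis @ %g Hz (%.1f s)\n",
              length(x$x), x$fs, length(x$x) / x$fs))
  invisible(x)
}

#' @export
length.sc_recording <- function(x) length(x$samples)

#' Sample timestamps of a recording
#'
#' @param rec An `sc_recording` or `triaxial_recording`.
#' @param relative If `TRUE` (default), seconds since session start;
#'   otherwise seconds since the Unix epoch.
#' @return Numeric vector of per-sample times.
#' @export
recording_times <- function(rec, relative = TRUE) {
  n <- if (inherits(rec, "triaxial_recording")) length(rec$x) else length(rec$samples)
  t <- (seq_len(n) - 1) / rec$fs
  if (relative) t else t + rec$start_epoch
}

#' @export
#' @method as_tibble sc_recording
as_tibble.sc_recording <- function(x, ...) {
  tibble::tibble(time_s = recording_times(x), value = x$samples)
}

#' @export
#' @method as_tibble triaxial_recording
as_tibble.triaxial_recording <- function(x, ...) {
  tibble::tibble(time_s = recording_times(x), x = x$x, y = x$y, z = x$z)
}
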