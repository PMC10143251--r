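#' Linearly oversample a recording onto a denser grid
#'
#' Raises the sampling frequency by an integer factor with linear
#' interpolation between neighbouring samples (the wrist device's 4 Hz SC
#' stream is typically raised to the benchtop DAQ's 256 Hz before
#' filtering). Original sample instants are reproduced exactly; the output
#' spans the same interval, so it has `(n - 1) * ratio + 1` samples.
#'
#' @param rec An [sc_recording()].
#' @param target_fs Target sampling frequency; must be an integer multiple
#'   of `rec$fs`.
#' @return An [sc_recording()] at `target_fs`.
#' @examples
#' oversample_linear(sc_recording(c(0, 1), fs = 1), 4)$samples
#' @export
oversample_linear <- function(rec, target_fs) {
  ratio <- target_fs / rec$fs
  if (target_fs < rec$fs || abs(ratio - round(ratio)) > 1e-9) {
    abort("`target_fs` must be an integer multiple of the input fs.")
  }
  ratio <- round(ratio)
  if (ratio == 1) return(rec)
  n <- length(rec$samples)
  t_in <- (seq_len(n) - 1) / rec$fs
  t_out <- (seq_len((n - 1) * ratio + 1) - 1) / target_fs
  y <- approx(t_in, rec$samples, xout = t_out, method = "linear")$y
  sc_recording(y, fs = target_fs, start_epoch = rec$start_epoch,
               units = rec$units)
}

#' Decompose skin conductance into tonic (SCL) and phasic (SCR) parts
#'
#' The tonic level is estimated with a zero-phase low-pass (Butterworth,
#' applied forward and backward so it introduces no lag); the phasic
#' component is the residual, so `sc = scl + scr` holds exactly by
#' construction.
#'
#' @param rec An [sc_recording()] at least 10 s long.
#' @param cutoff Tonic cutoff frequency in Hz (default 0.05, the
#'   conventional boundary between SCL drift and SCR transients).
#' @param order Butterworth order (default 1).
#' @return A list of class `decomposed_sc`: `sc`, `scl`, `scr`
#'   (equal-length numeric vectors), `fs`, `start_epoch`.
#' @export
decompose_scl_scr <- function(rec, cutoff = 0.05, order = 1) {
  n <- length(rec$samples)
  if (n < 10 * rec$fs) {
    abort("signal too short to decompose: need at least 10 s of samples.")
  }
  if (cutoff <= 0 || cutoff >= rec$fs / 2) {
    abort("`cutoff` must lie in (0, fs/2).")
  }
  bf <- signal::butter(order, 2 * cutoff / rec$fs, type = "low")
  ## odd-reflection padding absorbs the forward/backward startup transients
  pad <- min(n - 1, ceiling(3 * rec$fs / cutoff))
  x <- rec$samples
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  scl <- as.numeric(signal::filtfilt(bf, c(left, x, right)))[(pad + 1):(pad + n)]
  structure(list(sc = rec$samples, scl = scl, scr = rec$samples - scl,
                 fs = rec$fs, start_epoch = rec$start_epoch),
            class = "decomposed_sc")
}

#' @export
print.decomposed_sc <- function(x, ...) {
  cat(sprintf("<decomposed_sc> %d samples @ %g Hz; SCL range [%.3f, %.3f] uS\n",
              length(x$sc), x$fs, min(x$scl), max(x$scl)))
  invisible(x)
}

#' Cut a decomposed signal into fixed-length windows
#'
#' Consecutive non-overlapping windows of `window_s` seconds (default 15,
#' i.e. 60 samples at the wrist device's 4 Hz). A trailing partial window
#' is dropped and reported via message.
#'
#' @param d A `decomposed_sc` from [decompose_scl_scr()].
#' @param window_s Window length in seconds; `window_s * fs` must be an
#'   integer.
#' @return A tibble with one row per window: `index`, `start_s`, and
#'   list-columns `sc`, `scl`, `scr` holding the window's samples.
#' @export
window_segments <- function(d, window_s = 15) {
  stopifnot(inherits(d, "decomposed_sc"))
  len <- window_s * d$fs
  if (abs(len - round(len)) > 1e-9) {
    abort("`window_s * fs` must be an integer number of samples.")
  }
  len <- as.integer(round(len))
  n <- length(d$sc)
  k <- n %/% len
  if (n %% len > 0) {
    inform(sprintf("dropping a trailing partial window of %d samples.", n %% len))
  }
  slice <- function(v, i) v[((i - 1) * len + 1):(i * len)]
  tibble::tibble(
    index = seq_len(k),
    start_s = (seq_len(k) - 1) * window_s,
    sc = purrr::map(seq_len(k), ~ slice(d$sc, .x)),
    scl = purrr::map(seq_len(k), ~ slice(d$scl, .x)),
    scr = purrr::map(seq_len(k), ~ slice(d$scr, .x))
  )
}

#' Group a KSS score into the three drowsiness classes
#'
#' Scores 1-5 are class 1 (alert), 6-7 class 2 (slightly drowsy),
#' 8-9 class 3 (drowsy).
#'
#' @param score Integer KSS score(s) in 1..9.
#' @return Integer class label(s) in 1..3.
#' @examples
#' kss_to_class(c(5, 6, 9))
#' @export
kss_to_class <- function(score) {
  if (any(score < 1 | score > 9 | score != round(score))) {
    abort("KSS scores must be integers in 1..9.")
  }
  ifelse(score <= 5, 1L, ifelse(score <= 7, 2L, 3L))
}

#' Attach KSS labels to windows
#'
#' Every window inside a KSS reporting interval receives that interval's
#' score. An entry at time `t` covering the prior `p` seconds labels
#' windows whose start falls in `[t - p, t]`; when a window start lies on
#' a boundary shared by two intervals, the earlier entry wins.
#'
#' @param windows Window tibble from [window_segments()].
#' @param kss KSS tibble ([read_kss_log()] / [kss_log()]).
#' @return `windows` with added columns `kss_score` and `class` (1..3).
#' @export
assign_labels <- function(windows, kss) {
  if (!nrow(kss)) abort("cannot label windows: the KSS log is empty.")
  score_of <- function(start_s) {
    hit <- which(start_s >= kss$time_s - kss$covers_prior_s &
                   start_s <= kss$time_s)
    if (!length(hit)) return(NA_integer_)
    kss$score[hit[1]]
  }
  scores <- vapply(windows$start_s, score_of, integer(1))
  if (anyNA(scores)) {
    abort(sprintf("windows not covered by any KSS interval: %s",
                  paste(windows$index[is.na(scores)], collapse = ", ")))
  }
  dplyr::mutate(windows, kss_score = scores, class = kss_to_class(scores))
}
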