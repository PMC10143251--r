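#' Wavelet decomposition level for a sampling frequency
#'
#' The decomposition depth is tied to the sampling frequency by
#' `j = log2(fs) + 2`: 4 Hz wrist-device signals use 4 levels, 256 Hz
#' benchtop signals use 10. For a non-power-of-two `fs` the log is rounded
#' to the nearest integer with a warning.
#'
#' @param fs Sampling frequency in Hz, `fs >= 1`.
#' @return Integer decomposition level.
#' @examples
#' decomposition_level(4)    # 4
#' decomposition_level(256)  # 10
#' @export
decomposition_level <- function(fs) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs < 1) {
    abort("`fs` must be a single number >= 1 Hz.")
  }
  l2 <- log2(fs)
  if (abs(l2 - round(l2)) > 1e-9) {
    warn(sprintf("fs = %g Hz is not a power of two; using round(log2(fs)) = %d.",
                 fs, round(l2)))
  }
  as.integer(round(l2) + 2L)
}

#' Motion-artifact filter configuration
#'
#' @param j Wavelet decomposition level; `NULL` (default) derives it from
#'   the signal's sampling frequency via [decomposition_level()].
#' @param wavelet Mother wavelet; only `"haar"` is implemented.
#' @param delta_low Assumed artifact proportion for quiet segments
#'   (default 0.01).
#' @param delta_high Assumed artifact proportion for high-motion segments
#'   (default 0.10).
#' @param sigma_gate Per-axis acceleration standard-deviation gate in
#'   m/s^2 (default 0.04): a segment is treated as motion-corrupted when
#'   any axis exceeds it.
#' @param variant `"improved"` (overlapped segments, central retention;
#'   default) or `"original"` (non-overlapped segments).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(j = NULL, wavelet = "haar",
                          delta_low = 0.01, delta_high = 0.10,
                          sigma_gate = 0.04,
                          variant = c("improved", "original")) {
  variant <- match.arg(variant)
  if (!identical(wavelet, "haar")) {
    abort("only the Haar mother wavelet is implemented.")
  }
  if (!(delta_low > 0 && delta_low <= delta_high && delta_high < 1)) {
    abort("need 0 < delta_low <= delta_high < 1.")
  }
  if (sigma_gate <= 0) abort("`sigma_gate` must be positive.")
  if (!is.null(j) && (j < 1 || j != round(j))) {
    abort("`j` must be a positive integer level.")
  }
  structure(list(j = if (is.null(j)) NULL else as.integer(j),
                 wavelet = wavelet, delta_low = delta_low,
                 delta_high = delta_high, sigma_gate = sigma_gate,
                 variant = variant),
            class = "filter_config")
}

## ---- stationary wavelet transform (Haar, periodic, orthonormal) ----------
## Level l uses the Haar pair upsampled by 2^(l-1) (a trous):
##   a_l[k] = (a_{l-1}[k] + a_{l-1}[k + 2^(l-1)]) / sqrt(2)   (periodic index)
##   d_l[k] = (a_{l-1}[k] - a_{l-1}[k + 2^(l-1)]) / sqrt(2)
## The inverse averages the two shift-consistent reconstructions per level,
## which is exact for the undecimated transform.

#' Stationary (undecimated) Haar wavelet transform of a segment
#'
#' Periodic-boundary orthonormal Haar SWT to `j` levels. The transform is
#' redundant: every level keeps the full segment length, which makes it
#' shift-invariant — the property that lets per-sample thresholding work.
#'
#' @param x Numeric segment; its length must be divisible by `2^j`.
#' @param j Number of decomposition levels.
#' @return A list of class `swt_workspace`: `details` (list of `j`
#'   coefficient vectors, level 1 = finest), `approx` (level-`j`
#'   approximation), `n`, `j`.
#' @export
swt_haar <- function(x, j) {
  n <- length(x)
  if (n %% 2^j != 0) {
    abort(sprintf("segment length %d is not divisible by 2^%d.", n, j))
  }
  a <- as.numeric(x)
  details <- vector("list", j)
  for (l in seq_len(j)) {
    s <- 2^(l - 1)
    idx <- ((seq_len(n) - 1 + s) %% n) + 1  # periodic shift by s
    details[[l]] <- (a - a[idx]) / sqrt(2)
    a <- (a + a[idx]) / sqrt(2)
  }
  structure(list(details = details, approx = a, n = n, j = j),
            class = "swt_workspace")
}

#' Inverse stationary Haar wavelet transform
#'
#' Exact inverse of [swt_haar()]: at each level the two shift-consistent
#' single-branch reconstructions are averaged.
#'
#' @param w An `swt_workspace` from [swt_haar()].
#' @return Numeric vector of length `w$n`.
#' @export
iswt_haar <- function(w) {
  n <- w$n
  a <- w$approx
  for (l in rev(seq_len(w$j))) {
    s <- 2^(l - 1)
    d <- w$details[[l]]
    idx <- ((seq_len(n) - 1 - s) %% n) + 1  # periodic shift by -s
    a <- 0.5 * ((a + d) / sqrt(2) + (a[idx] - d[idx]) / sqrt(2))
  }
  a
}

#' Laplace-model coefficient thresholds
#'
#' Wavelet coefficients of the clean signal are modelled as zero-mean
#' Laplace; under that model the fraction of coefficients outside
#' `[T_low, T_high]` with `T_low = mean(|d|) * ln(delta)` is exactly
#' `delta`, the assumed artifact proportion.
#'
#' @param d Coefficient vector for one decomposition level (nonempty).
#' @param delta Assumed artifact proportion, in (0, 1).
#' @return Named numeric `c(low = T_low, high = -T_low)`.
#' @examples
#' laplace_thresholds(c(1, 1, 1, 1), 0.10)  # +/- 2.302585
#' @export
laplace_thresholds <- function(d, delta) {
  if (!length(d)) abort("empty coefficient vector.")
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta >= 1) {
    abort("`delta` must lie strictly between 0 and 1.")
  }
  t_low <- mean(abs(d)) * log(delta)
  c(low = t_low, high = -t_low)
}

#' Select the artifact proportion from wrist acceleration
#'
#' A segment is flagged as motion-corrupted when the sample standard
#' deviation of any of the three acceleration axes over the segment's time
#' span reaches the gate (0.04 m/s^2 by default); quiet segments use
#' `delta_low`, flagged segments `delta_high`.
#'
#' @param acc_x,acc_y,acc_z Acceleration samples over the segment span,
#'   m/s^2; each nonempty.
#' @param config A [filter_config()].
#' @return `config$delta_low` or `config$delta_high`.
#' @export
select_delta <- function(acc_x, acc_y, acc_z, config = filter_config()) {
  if (!length(acc_x) || !length(acc_y) || !length(acc_z)) {
    abort("empty acceleration slice.")
  }
  sds <- c(sd_or_zero(acc_x), sd_or_zero(acc_y), sd_or_zero(acc_z))
  if (all(sds < config$sigma_gate)) config$delta_low else config$delta_high
}

sd_or_zero <- function(v) if (length(v) < 2L) 0 else sd(v)

#' Threshold the detail coefficients of a workspace
#'
#' Per level, coefficients falling outside the Laplace thresholds for
#' `delta` are treated as motion artifacts and set to zero; in-range
#' coefficients and the approximation band are untouched.
#'
#' @param w An `swt_workspace`.
#' @param delta Assumed artifact proportion for this segment.
#' @return The workspace with thresholded details and a `thresholds`
#'   element (per-level low/high).
#' @export
threshold_coefficients <- function(w, delta) {
  thr <- matrix(NA_real_, nrow = w$j, ncol = 2,
                dimnames = list(NULL, c("low", "high")))
  for (l in seq_len(w$j)) {
    tl <- laplace_thresholds(w$details[[l]], delta)
    thr[l, ] <- tl
    d <- w$details[[l]]
    d[d < tl["low"] | d > tl["high"]] <- 0
    w$details[[l]] <- d
  }
  w$thresholds <- thr
  w
}

## acceleration samples whose timestamps fall in [t0, t1) of the SC clock
acc_slice <- function(acc, t0, t1) {
  i0 <- ceiling((t0 - 1e-9) * acc$fs) + 1
  i1 <- floor((t1 - 1e-9) * acc$fs) + 1
  i0 <- max(1L, as.integer(i0)); i1 <- min(length(acc$x), as.integer(i1))
  if (i1 < i0) return(NULL)
  list(x = acc$x[i0:i1], y = acc$y[i0:i1], z = acc$z[i0:i1])
}

check_span <- function(sc, acc, seg_len) {
  gap <- abs(length(sc$samples) / sc$fs - length(acc$x) / acc$fs)
  if (gap > seg_len / sc$fs) {
    abort(sprintf(
      "SC and acceleration spans differ by %.1f s, more than one segment.", gap))
  }
}

reflect_pad <- function(x, left, right) {
  n <- length(x)
  lp <- if (left > 0) x[pmin(n, seq(left + 1, 2, by = -1))] else numeric(0)
  rp <- if (right > 0) x[pmax(1, seq(n - 1, n - right, by = -1))] else numeric(0)
  c(lp, x, rp)
}

filter_segment <- function(seg, delta, j, thresholding = TRUE) {
  w <- swt_haar(seg, j)
  if (thresholding) w <- threshold_coefficients(w, delta)
  iswt_haar(w)
}

#' Original non-overlapped SWT artifact filter
#'
#' Processes consecutive non-overlapped segments of `2^j` samples: each
#' segment is transformed with the Haar SWT, its detail coefficients are
#' thresholded with the Laplace rule (the artifact proportion `delta`
#' selected per segment from the time-aligned acceleration), and the
#' segment is reconstructed with the inverse transform. A tail shorter
#' than a full segment is reflection-padded, filtered and truncated.
#' Reconstruction discontinuities at segment joints are this variant's
#' known defect; see [filter_improved()].
#'
#' @param sc SC [sc_recording()].
#' @param acc Time-aligned [triaxial_recording()].
#' @param config A [filter_config()].
#' @param thresholding Internal test hook; `FALSE` makes every segment a
#'   pure SWT/ISWT round trip.
#' @return Filtered [sc_recording()], same length as the input. The
#'   per-segment delta choices are attached as attribute `"deltas"`.
#' @export
filter_original <- function(sc, acc, config = filter_config(),
                            thresholding = TRUE) {
  j <- config$j %||% decomposition_level(sc$fs)
  seg_len <- 2^j
  n <- length(sc$samples)
  if (n < seg_len) abort(sprintf("signal shorter than one %d-sample segment.",
                                 seg_len))
  check_span(sc, acc, seg_len)
  n_seg <- ceiling(n / seg_len)
  out <- numeric(n_seg * seg_len)
  deltas <- numeric(n_seg)
  x <- reflect_pad(sc$samples, 0, n_seg * seg_len - n)
  for (s in seq_len(n_seg)) {
    i0 <- (s - 1) * seg_len + 1
    i1 <- s * seg_len
    sl <- acc_slice(acc, (i0 - 1) / sc$fs, min(i1, n) / sc$fs)
    deltas[s] <- if (is.null(sl)) config$delta_low else
      select_delta(sl$x, sl$y, sl$z, config)
    out[i0:i1] <- filter_segment(x[i0:i1], deltas[s], j, thresholding)
  }
  res <- sc_recording(out[seq_len(n)], fs = sc$fs,
                      start_epoch = sc$start_epoch, units = sc$units)
  attr(res, "deltas") <- deltas
  attr(res, "j") <- j
  res
}

#' Improved overlapped SWT artifact filter
#'
#' Same per-segment machinery as [filter_original()], but segments are
#' `2 * 2^j` samples long and slide with hop `2^j` (50% overlap); only the
#' central `2^j` samples of each reconstruction are written to the output,
#' so the joint discontinuities the inverse transform creates at segment
#' edges fall in the discarded margins. Signal ends are reflection-padded
#' by `2^(j-1)` samples. The retained central parts tile the signal
#' exactly: output length equals input length.
#'
#' @inheritParams filter_original
#' @return Filtered [sc_recording()] with attributes `"deltas"` and `"j"`.
#' @export
filter_improved <- function(sc, acc, config = filter_config(),
                            thresholding = TRUE) {
  j <- config$j %||% decomposition_level(sc$fs)
  hop <- 2^j
  seg_len <- 2 * hop
  margin <- hop / 2          # 2^(j-1) discarded each side
  n <- length(sc$samples)
  if (n < hop) abort(sprintf("signal shorter than one %d-sample segment.", hop))
  check_span(sc, acc, hop)
  n_seg <- ceiling(n / hop)
  x <- reflect_pad(sc$samples, margin, n_seg * hop - n + margin)
  out <- numeric(n_seg * hop)
  deltas <- numeric(n_seg)
  for (s in seq_len(n_seg)) {
    p0 <- (s - 1) * hop + 1            # segment start in padded signal
    seg <- x[p0:(p0 + seg_len - 1)]
    ## delta from the acceleration over the segment's (unpadded) time span
    t0 <- max(0, ((s - 1) * hop - margin)) / sc$fs
    t1 <- min(n, (s * hop + margin)) / sc$fs
    sl <- acc_slice(acc, t0, t1)
    deltas[s] <- if (is.null(sl)) config$delta_low else
      select_delta(sl$x, sl$y, sl$z, config)
    rec <- filter_segment(seg, deltas[s], j, thresholding)
    out[((s - 1) * hop + 1):(s * hop)] <- rec[(margin + 1):(margin + hop)]
  }
  res <- sc_recording(out[seq_len(n)], fs = sc$fs,
                      start_epoch = sc$start_epoch, units = sc$units)
  attr(res, "deltas") <- deltas
  attr(res, "j") <- j
  res
}

#' Apply the configured artifact filter
#'
#' Dispatches to [filter_original()] or [filter_improved()] according to
#' `config$variant`.
#'
#' @inheritParams filter_original
#' @return Filtered [sc_recording()].
#' @export
filter_artifacts <- function(sc, acc, config = filter_config()) {
  switch(config$variant,
         original = filter_original(sc, acc, config),
         improved = filter_improved(sc, acc, config))
}

#' Compare the original and improved filter variants
#'
#' Runs both variants on the same input and summarises where they deviate
#' from the raw signal, in particular near the original variant's segment
#' joints (multiples of `2^j` samples), where the inverse transform's
#' reconstruction spikes appear.
#'
#' @inheritParams filter_original
#' @param deviation_threshold Deviations above this (microsiemens) are
#'   counted; default 0.01, the SCR peak-relevance amplitude.
#' @param joint_radius Samples around a joint counted as "joint-adjacent".
#' @return A list of class `filter_comparison`: `samples` (tibble with
#'   per-sample input, both outputs and absolute deviations), `summary`
#'   (one-row tibble: max deviations, counts of above-threshold deviations
#'   overall and joint-adjacent for each variant), `j`, `joints`.
#' @export
compare_filters <- function(sc, acc, config = filter_config(),
                            deviation_threshold = 0.01, joint_radius = 2) {
  j <- config$j %||% decomposition_level(sc$fs)
  cfg <- config; cfg$j <- j
  orig <- filter_original(sc, acc, cfg)
  impr <- filter_improved(sc, acc, cfg)
  n <- length(sc$samples)
  joints <- seq(2^j, n - 1, by = 2^j)   # joint between samples k and k+1
  near_joint <- rep(FALSE, n)
  for (k in joints) {
    near_joint[max(1, k - joint_radius + 1):min(n, k + joint_radius)] <- TRUE
  }
  samples <- tibble::tibble(
    index = seq_len(n),
    time_s = recording_times(sc),
    input = sc$samples,
    original = orig$samples,
    improved = impr$samples,
    dev_original = abs(orig$samples - sc$samples),
    dev_improved = abs(impr$samples - sc$samples),
    dev_between = abs(orig$samples - impr$samples),
    near_joint = near_joint
  )
  summary <- tibble::tibble(
    j = j,
    max_dev_original = max(samples$dev_original),
    max_dev_improved = max(samples$dev_improved),
    n_dev_original = sum(samples$dev_original > deviation_threshold),
    n_dev_improved = sum(samples$dev_improved > deviation_threshold),
    n_joint_dev_original = sum(samples$dev_original > deviation_threshold &
                                 samples$near_joint),
    n_joint_dev_between = sum(samples$dev_between > deviation_threshold &
                                samples$near_joint)
  )
  structure(list(samples = samples, summary = summary, j = j, joints = joints),
            class = "filter_comparison")
}

#' @export
print.filter_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<filter_comparison> j = %d (segments of %d samples)\n",
              x$j, 2^x$j))
  cat(sprintf("  max |original - input| = %.3g uS (%d above threshold, %d at joints)\n",
              s$max_dev_original, s$n_dev_original, s$n_joint_dev_original))
  cat(sprintf("  max |improved - input| = %.3g uS (%d above threshold)\n",
              s$max_dev_improved, s$n_dev_improved))
  invisible(x)
}
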