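#' Canonical bi-exponential SCR kernel
#'
#' Shape of a single skin conductance response: zero before the event,
#' a bi-exponential `exp(-t/tau_decay) - exp(-t/tau_rise)` afterwards,
#' rescaled so its maximum is exactly 1. Single-peaked and causal, the
#' standard phenomenological SCR shape.
#'
#' @param t Time in seconds relative to the event onset (vectorised).
#' @param tau_rise Rise time constant in seconds (default 0.75).
#' @param tau_decay Decay time constant in seconds (default 2); must
#'   exceed `tau_rise`.
#' @return Numeric vector of unit-peak amplitudes.
#' @examples
#' scr_kernel(seq(0, 10, by = 0.25))
#' @export
scr_kernel <- function(t, tau_rise = 0.75, tau_decay = 2) {
  if (!is.finite(tau_rise) || !is.finite(tau_decay) ||
      tau_rise <= 0 || tau_decay <= tau_rise) {
    abort("need tau_decay > tau_rise > 0.")
  }
  ## closed-form argmax of exp(-t/td) - exp(-t/tr)
  t_peak <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  peak <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  out <- numeric(length(t))
  pos <- which(t > 0)
  out[pos] <- (exp(-t[pos] / tau_decay) - exp(-t[pos] / tau_rise)) / peak
  out
}

#' Specification of a synthetic driving session
#'
#' Collects every knob of the synthetic-session generator. Defaults emulate
#' the study protocol this pipeline targets: a 40-minute simulated drive,
#' wrist-device SC at 4 Hz, triaxial acceleration at 32 Hz, and a KSS
#' self-report every 10 minutes; the latent drowsiness state is
#' piecewise-constant per 10-minute block (1 = alert, 2 = slightly drowsy,
#' 3 = drowsy) and drives tonic drift, phasic event rate and the KSS band.
#'
#' @param duration_s Session length in seconds; must be a multiple of
#'   `kss_period_s`.
#' @param sc_fs SC sampling frequency in Hz.
#' @param acc_fs Accelerometer sampling frequency in Hz.
#' @param drowsiness_profile Latent state (1/2/3) per 10-minute block.
#' @param scl_base Tonic level at session start, microsiemens.
#' @param scl_drift Tonic drift per state, microsiemens per minute
#'   (length 3, states 1..3).
#' @param scr_rate_per_min Phasic (SCR) event rate per state, events/min
#'   (length 3).
#' @param scr_amp_range Min/max SCR amplitude, microsiemens.
#' @param artifact_burst_rate_per_min Motion-artifact burst rate, bursts/min.
#' @param artifact_amp Artifact burst amplitude, microsiemens.
#' @param artifact_duration_s Burst duration in seconds (snapped to the SC
#'   sample grid).
#' @param noise_sd Additive Gaussian measurement noise sd, microsiemens.
#' @param acc_wobble_sd Baseline per-axis acceleration sd, m/s^2 (quiet
#'   wrist, well below the 0.04 m/s^2 artifact gate).
#' @param acc_burst_sd Per-axis acceleration sd inside artifact bursts,
#'   m/s^2 (vigorous shaking).
#' @param tau_rise,tau_decay SCR kernel time constants, seconds.
#' @param kss_period_s Seconds between KSS self-reports.
#' @param start_epoch Session start, seconds since the Unix epoch.
#' @param seed Integer seed; the session is fully reproducible from it.
#' @return A list of class `session_spec`.
#' @export
session_spec <- function(duration_s = 2400,
                         sc_fs = 4,
                         acc_fs = 32,
                         drowsiness_profile = c(1, 1, 2, 3),
                         scl_base = 2,
                         scl_drift = c(0, -0.02, -0.04),
                         scr_rate_per_min = c(6, 3, 1),
                         scr_amp_range = c(0.02, 0.2),
                         artifact_burst_rate_per_min = 0.5,
                         artifact_amp = 0.5,
                         artifact_duration_s = 2,
                         noise_sd = 0.005,
                         acc_wobble_sd = 0.01,
                         acc_burst_sd = 0.5,
                         tau_rise = 0.75,
                         tau_decay = 2,
                         kss_period_s = 600,
                         start_epoch = 0,
                         seed = NULL) {
  n_blocks <- duration_s / kss_period_s
  if (n_blocks != round(n_blocks) || n_blocks < 1) {
    abort("`duration_s` must be a positive multiple of `kss_period_s`.")
  }
  if (length(drowsiness_profile) != n_blocks) {
    abort(sprintf("`drowsiness_profile` needs one state per %g-s block (%d).",
                  kss_period_s, as.integer(n_blocks)))
  }
  if (!all(drowsiness_profile %in% 1:3)) {
    abort("latent states must be in {1, 2, 3}.")
  }
  if (any(c(scr_rate_per_min, artifact_burst_rate_per_min) < 0)) {
    abort("rates must be >= 0.")
  }
  if (any(scr_amp_range <= 0) || scr_amp_range[1] > scr_amp_range[2]) {
    abort("`scr_amp_range` must be positive and ordered.")
  }
  spec <- as.list(environment())
  spec$n_blocks <- as.integer(n_blocks)
  structure(spec, class = "session_spec")
}

kss_band <- list(`1` = 1:5, `2` = 6:7, `3` = 8:9)

#' Generate a synthetic driving session
#'
#' Builds a full session from a [session_spec()]: tonic level with
#' state-dependent drift, Poisson phasic events shaped by [scr_kernel()],
#' Gaussian measurement noise, and spiky motion-artifact bursts that are
#' exactly time-locked to high-variance epochs of the generated triaxial
#' acceleration (quiet wobble outside bursts, vigorous shaking inside).
#' KSS scores are drawn from the latent state's band (state 1 -> 1..5,
#' 2 -> 6..7, 3 -> 8..9). Ground truth — the artifact-free signal, the
#' tonic/phasic split, SCR event times, artifact epochs and latent
#' states — is stored alongside, so every downstream stage can be checked
#' against what was injected.
#'
#' @param spec A [session_spec()].
#' @return A list of class `sc_session` with elements `sc`
#'   ([sc_recording()]), `acc` ([triaxial_recording()]), `kss`
#'   (KSS tibble) and `truth` (list: `clean`, `scl`, `scr`, `scr_events`,
#'   `artifact_epochs`, `states`).
#' @examples
#' s <- generate_session(session_spec(seed = 7))
#' s$sc
#' @export
generate_session <- function(spec = session_spec()) {
  stopifnot(inherits(spec, "session_spec"))
  if (!is.null(spec$seed)) {
    return(withr::with_seed(spec$seed, generate_session_impl(spec)))
  }
  generate_session_impl(spec)
}

generate_session_impl <- function(spec) {
  fs <- spec$sc_fs
  n <- as.integer(round(spec$duration_s * fs))
  t <- (seq_len(n) - 1) / fs
  block_of <- function(tt) pmin(floor(tt / spec$kss_period_s) + 1, spec$n_blocks)
  state <- spec$drowsiness_profile[block_of(t)]

  ## tonic: cumulative state-dependent drift from the base level
  drift_per_sample <- spec$scl_drift[state] / 60 / fs
  scl <- spec$scl_base + cumsum(drift_per_sample) - drift_per_sample[1]

  ## phasic: Poisson events per block, bi-exponential kernel
  events <- purrr::map_dfr(seq_len(spec$n_blocks), function(b) {
    rate <- spec$scr_rate_per_min[spec$drowsiness_profile[b]]
    k <- rpois(1, rate * spec$kss_period_s / 60)
    if (k == 0) return(tibble::tibble(time_s = numeric(), amplitude = numeric(),
                                      state = integer()))
    tibble::tibble(
      time_s = sort(runif(k, (b - 1) * spec$kss_period_s, b * spec$kss_period_s)),
      amplitude = runif(k, spec$scr_amp_range[1], spec$scr_amp_range[2]),
      state = spec$drowsiness_profile[b]
    )
  })
  scr <- numeric(n)
  support <- ceiling(20 * spec$tau_decay * fs)  # kernel < 1e-8 beyond this
  for (i in seq_len(nrow(events))) {
    i0 <- floor(events$time_s[i] * fs) + 1
    idx <- i0:min(n, i0 + support)
    scr[idx] <- scr[idx] + events$amplitude[i] *
      scr_kernel(t[idx] - events$time_s[i], spec$tau_rise, spec$tau_decay)
  }

  noise <- rnorm(n, 0, spec$noise_sd)
  clean <- scl + scr + noise

  ## artifact bursts, epochs snapped to the SC sample grid so that any
  ## overlap with an analysis segment carries at least one SC sample's
  ## worth of shaking acceleration
  n_bursts <- rpois(1, spec$artifact_burst_rate_per_min * spec$duration_s / 60)
  epochs <- tibble::tibble(start_s = numeric(), end_s = numeric())
  if (n_bursts > 0) {
    dur <- round(spec$artifact_duration_s * fs) / fs
    starts <- round(runif(n_bursts, 0, spec$duration_s - dur) * fs) / fs
    epochs <- tibble::tibble(start_s = sort(starts), end_s = sort(starts) + dur)
    ## merge overlapping bursts into maximal epochs
    merged <- epochs[1, ]
    for (i in seq_len(nrow(epochs))[-1]) {
      j <- nrow(merged)
      if (epochs$start_s[i] <= merged$end_s[j]) {
        merged$end_s[j] <- max(merged$end_s[j], epochs$end_s[i])
      } else {
        merged <- dplyr::bind_rows(merged, epochs[i, ])
      }
    }
    epochs <- merged
  }
  in_epoch <- function(tt) {
    hit <- rep(FALSE, length(tt))
    for (i in seq_len(nrow(epochs))) {
      hit <- hit | (tt >= epochs$start_s[i] & tt < epochs$end_s[i])
    }
    hit
  }
  sc <- clean
  art_idx <- which(in_epoch(t))
  if (length(art_idx)) {
    sc[art_idx] <- sc[art_idx] + spec$artifact_amp *
      sample(c(-1, 1), length(art_idx), replace = TRUE) *
      (0.6 + 0.4 * runif(length(art_idx)))
  }

  ## acceleration: quiet wobble outside epochs, shaking inside; gravity on z
  n_acc <- as.integer(round(spec$duration_s * spec$acc_fs))
  t_acc <- (seq_len(n_acc) - 1) / spec$acc_fs
  sd_acc <- ifelse(in_epoch(t_acc), spec$acc_burst_sd, spec$acc_wobble_sd)
  acc <- triaxial_recording(
    x = rnorm(n_acc, 0, sd_acc),
    y = rnorm(n_acc, 0, sd_acc),
    z = 9.81 + rnorm(n_acc, 0, sd_acc),
    fs = spec$acc_fs, start_epoch = spec$start_epoch
  )

  kss_times <- seq_len(spec$n_blocks) * spec$kss_period_s
  kss_scores <- vapply(spec$drowsiness_profile, function(s) {
    band <- kss_band[[as.character(s)]]
    band[sample.int(length(band), 1)]
  }, integer(1))

  structure(list(
    sc = sc_recording(sc, fs = fs, start_epoch = spec$start_epoch),
    acc = acc,
    kss = kss_log(kss_times, kss_scores, spec$kss_period_s),
    truth = list(
      clean = sc_recording(clean, fs = fs, start_epoch = spec$start_epoch),
      scl = scl, scr = scr,
      scr_events = events,
      artifact_epochs = epochs,
      states = spec$drowsiness_profile
    ),
    spec = spec
  ), class = "sc_session")
}

#' @export
print.sc_session <- function(x, ...) {
  cat(sprintf(
    "<sc_session> %.0f min, SC @ %g Hz, acc @ %g Hz, %d SCR events, %d artifact epochs\n",
    x$spec$duration_s / 60, x$spec$sc_fs, x$spec$acc_fs,
    nrow(x$truth$scr_events), nrow(x$truth$artifact_epochs)))
  invisible(x)
}

#' Write a synthetic session to device-export files
#'
#' Emits the three CSVs the readers in this package understand (SC channel,
#' triaxial acceleration, KSS log) plus a JSON ground-truth sidecar.
#'
#' @param session An `sc_session` from [generate_session()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Named character vector of the four paths, invisibly.
#' @export
write_session <- function(session, dir, prefix = "session") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(sc = file.path(dir, paste0(prefix, "_sc.csv")),
         acc = file.path(dir, paste0(prefix, "_acc.csv")),
         kss = file.path(dir, paste0(prefix, "_kss.csv")),
         truth = file.path(dir, paste0(prefix, "_truth.json")))
  write_device_channel(session$sc, p["sc"])
  write_triaxial(session$acc, p["acc"])
  write_kss_log(session$kss, p["kss"])
  jsonlite::write_json(list(
    scr_events = session$truth$scr_events,
    artifact_epochs = session$truth$artifact_epochs,
    states = session$truth$states
  ), p["truth"], auto_unbox = TRUE, digits = NA)
  invisible(p)
}
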