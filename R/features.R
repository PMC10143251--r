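#' Canonical feature catalogue
#'
#' The 23 features computed per 15-s window, in canonical order: time- and
#' frequency-domain statistics of the SC signal, SCR peak count and SCL
#' statistics, with the five redundancy-prone features (SC mean / max /
#' median, SCL mean / max) listed last so that correlation pruning drops
#' them rather than their earlier partners.
#'
#' @return Character vector of the 23 canonical feature names.
#' @export
feature_catalogue <- function() {
  c(
    ## SC, time domain
    "sc_t_std", "sc_t_min", "sc_t_kurtosis", "sc_t_skewness",
    "sc_t_variance", "sc_t_range",
    ## SC, frequency domain (statistics of the magnitude spectrum)
    "sc_f_mean", "sc_f_std", "sc_f_min", "sc_f_max", "sc_f_kurtosis",
    "sc_f_skewness", "sc_f_variance", "sc_f_range", "sc_f_median",
    ## SC components, time domain
    "scr_num_peaks", "scl_t_std", "scl_t_min",
    ## redundancy-prone set, pruned on typical data
    "sc_t_mean", "sc_t_max", "sc_t_median", "scl_t_mean", "scl_t_max"
  )
}

#' One-sided magnitude spectrum of a window
#'
#' Magnitude of the discrete Fourier transform (via FFT), DC bin included,
#' scaled by `1/fs` so values are in uS/Hz. Only the non-redundant half of
#' the spectrum is returned.
#'
#' @param window Numeric sample vector, length >= 2.
#' @param fs Sampling frequency in Hz.
#' @return Tibble with columns `freq` (Hz) and `magnitude` (uS/Hz).
#' @export
magnitude_spectrum <- function(window, fs) {
  n <- length(window)
  if (n < 2) abort("need at least 2 samples for a spectrum.")
  X <- fft(window)
  keep <- seq_len(floor(n / 2) + 1)
  tibble::tibble(freq = (keep - 1) * fs / n,
                 magnitude = Mod(X)[keep] / fs)
}

## moment statistics used throughout the catalogue: std/variance are the
## sample (n-1) versions; skewness and kurtosis are the plain third and
## fourth standardised moments (kurtosis of a normal ~ 3, no excess
## correction); both are defined as 0 on zero-variance windows.
moment_stats <- function(x, prefix) {
  m <- mean(x)
  v <- var(x)
  m2 <- mean((x - m)^2)
  if (m2 > 0) {
    skew <- mean((x - m)^3) / m2^1.5
    kurt <- mean((x - m)^4) / m2^2
  } else {
    skew <- 0
    kurt <- 0
  }
  stats::setNames(
    c(m, sqrt(v), min(x), max(x), median(x), kurt, skew, v, max(x) - min(x)),
    paste0(prefix, c("mean", "std", "min", "max", "median", "kurtosis",
                     "skewness", "variance", "range")))
}

#' Count relevant SCR peaks in a phasic window
#'
#' A peak is a strict local maximum of the phasic (SCR) trace whose
#' amplitude exceeds the relevance threshold, 0.01 uS by convention.
#'
#' @param scr_window Numeric phasic samples.
#' @param amp_threshold Relevance threshold in uS (default 0.01).
#' @return Non-negative integer peak count.
#' @export
count_scr_peaks <- function(scr_window, amp_threshold = 0.01) {
  n <- length(scr_window)
  if (n < 3) return(0L)
  mid <- 2:(n - 1)
  peaks <- scr_window[mid] > scr_window[mid - 1] &
    scr_window[mid] > scr_window[mid + 1] &
    scr_window[mid] > amp_threshold
  sum(peaks)
}

#' Extract the 23-feature vector of one window
#'
#' Time-domain statistics of the SC samples, the same statistics of the
#' one-sided magnitude spectrum (frequency domain), the relevant-SCR peak
#' count and SCL statistics. Zero-variance windows get skewness and
#' kurtosis 0 by convention.
#'
#' @param sc_window,scl_window,scr_window Sample vectors of one window.
#' @param fs Sampling frequency in Hz.
#' @param peak_threshold SCR peak relevance threshold in uS.
#' @return Named numeric vector with the 23 canonical features.
#' @export
extract_features <- function(sc_window, scl_window, scr_window, fs,
                             peak_threshold = 0.01) {
  if (!length(sc_window)) abort("empty window.")
  st <- moment_stats(sc_window, "sc_t_")
  sf <- moment_stats(magnitude_spectrum(sc_window, fs)$magnitude, "sc_f_")
  sl <- moment_stats(scl_window, "scl_t_")
  out <- c(st, sf, sl,
           scr_num_peaks = as.numeric(count_scr_peaks(scr_window,
                                                      peak_threshold)))
  out[feature_catalogue()]
}

#' Build the per-window feature table
#'
#' @param labeled_windows Labelled window tibble from [assign_labels()].
#' @param fs Sampling frequency in Hz.
#' @param peak_threshold SCR peak relevance threshold in uS.
#' @return A tibble (class `feature_table`) with the 23 feature columns
#'   and `class`; all 23 names are initially selected (attribute
#'   `selected_features`).
#' @export
extract_feature_table <- function(labeled_windows, fs, peak_threshold = 0.01) {
  feats <- purrr::pmap(
    list(labeled_windows$sc, labeled_windows$scl, labeled_windows$scr),
    function(sc, scl, scr) {
      tibble::as_tibble_row(extract_features(sc, scl, scr, fs, peak_threshold))
    })
  tab <- dplyr::bind_cols(dplyr::bind_rows(feats),
                          tibble::tibble(class = labeled_windows$class))
  new_feature_table(tab, feature_catalogue())
}

new_feature_table <- function(tab, selected) {
  structure(tab, selected_features = selected,
            class = c("feature_table", class(tibble::as_tibble(tab))))
}

#' Names of the currently selected features of a table
#'
#' @param table A feature table.
#' @return Character vector (falls back to all non-class columns when the
#'   table carries no selection attribute).
#' @export
selected_features <- function(table) {
  attr(table, "selected_features") %||% setdiff(names(table), "class")
}

#' Pearson correlation coefficient
#'
#' `rho = cov(X, Y) / (sigma(X) * sigma(Y))`, with an explicit error on
#' constant inputs, where the coefficient is undefined.
#'
#' @param x,y Equal-length numeric vectors, length >= 2, both non-constant.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("need two equal-length vectors with at least 2 points.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: constant input.")
  }
  cor(x, y, method = "pearson")
}

#' Prune redundant features by pairwise correlation
#'
#' Greedy pass over the features in canonical order: a feature is dropped
#' when its absolute Pearson correlation with any already-retained feature
#' exceeds the threshold (0.90 by default). Because the redundancy-prone
#' five sit last in the canonical order, ties resolve in favour of the
#' catalogue's earlier features. Constant columns are dropped with a
#' warning (their correlation is undefined).
#'
#' @param table Feature table with >= 2 rows.
#' @param rho_threshold Absolute-correlation threshold (default 0.90).
#' @return The table with an updated `selected_features` attribute and a
#'   `pruning_log` attribute (tibble: dropped feature, the retained
#'   feature it matched, their rho).
#' @export
correlation_prune <- function(table, rho_threshold = 0.90) {
  if (nrow(table) < 2) abort("need at least 2 rows to estimate correlations.")
  feats <- intersect(selected_features(table), setdiff(names(table), "class"))
  retained <- character(0)
  log <- tibble::tibble(feature = character(), against = character(),
                        rho = numeric())
  for (f in feats) {
    v <- table[[f]]
    if (sd(v) == 0) {
      warn(sprintf("dropping constant feature '%s' (correlation undefined).", f))
      log <- dplyr::add_row(log, feature = f, against = NA_character_,
                            rho = NA_real_)
      next
    }
    rhos <- vapply(retained, function(g) cor(v, table[[g]]), numeric(1))
    hit <- which(abs(rhos) > rho_threshold)
    if (length(hit)) {
      log <- dplyr::add_row(log, feature = f, against = retained[hit[1]],
                            rho = rhos[hit[1]])
    } else {
      retained <- c(retained, f)
    }
  }
  out <- new_feature_table(table, retained)
  attr(out, "pruning_log") <- log
  out
}

#' Rank features by correlation with the class label
#'
#' Companion report to [correlation_prune()]: the average Pearson
#' correlation between each feature and the one-vs-rest class indicator,
#' the quantity the usual attribute evaluators rank by.
#'
#' @param table Feature table with a `class` column.
#' @return Tibble (`feature`, `rho_class`) sorted by decreasing
#'   `|rho_class|`; constant features get `NA`.
#' @export
feature_class_correlation <- function(table) {
  feats <- setdiff(names(table), "class")
  classes <- sort(unique(table$class))
  rho <- vapply(feats, function(f) {
    v <- table[[f]]
    if (sd(v) == 0) return(NA_real_)
    mean(vapply(classes, function(k) {
      ind <- as.numeric(table$class == k)
      if (sd(ind) == 0) return(0)
      abs(cor(v, ind))
    }, numeric(1)))
  }, numeric(1))
  dplyr::arrange(tibble::tibble(feature = feats, rho_class = rho),
                 dplyr::desc(abs(rho_class)))
}
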