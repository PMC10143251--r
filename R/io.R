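#' Read a single-channel device export
#'
#' Wrist-device exports are one CSV file per channel: line 1 holds the session
#' start time (seconds since the Unix epoch), line 2 the sampling frequency in
#' Hz, and every following line one sample. Benchtop DAQ exports are
#' two-column `timestamp,value` CSVs; `mode = "timestamped"` handles those,
#' inferring `fs` from the median timestamp spacing.
#'
#' @param path Path to the CSV export.
#' @param units Unit tag stored on the recording (`"uS"`, `"m_s2"`, `"raw"`).
#' @param mode `"header"` (two-line header, default) or `"timestamped"`.
#' @return An [sc_recording()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("1587123456.0", "4.0", "0.50", "0.52", "0.51"), f)
#' read_device_channel(f)
#' @export
read_device_channel <- function(path, units = c("uS", "m_s2", "raw"),
                                mode = c("header", "timestamped")) {
  units <- match.arg(units)
  mode <- match.arg(mode)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]

  if (mode == "timestamped") {
    rows <- strsplit(lines, ",", fixed = TRUE)
    bad <- which(lengths(rows) != 2L)
    if (length(bad)) {
      abort(sprintf("parse error: row %d does not have 2 columns.", bad[1]))
    }
    ts <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 1L)))
    vals <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 2L)))
    if (anyNA(ts) || anyNA(vals)) {
      abort(sprintf("parse error: non-numeric value in row %d.",
                    which(is.na(ts) | is.na(vals))[1]))
    }
    if (length(ts) < 2L) abort("timestamped export needs at least 2 rows.")
    fs <- 1 / median(diff(ts))
    return(sc_recording(vals, fs = fs, start_epoch = ts[1], units = units))
  }

  if (length(lines) < 2L) {
    abort("format error: expected a 2-line header (start epoch, fs).")
  }
  start_epoch <- suppressWarnings(as.numeric(lines[1]))
  fs <- suppressWarnings(as.numeric(lines[2]))
  if (is.na(start_epoch) || start_epoch < 0) {
    abort("format error in line 1: start epoch must be a non-negative real.")
  }
  if (is.na(fs) || fs <= 0) {
    abort("format error in line 2: sampling frequency must be a positive real.")
  }
  body <- lines[-(1:2)]
  if (!length(body)) abort("empty channel: no sample rows after the header.")
  samples <- suppressWarnings(as.numeric(body))
  if (anyNA(samples)) {
    abort(sprintf("parse error: non-numeric sample in row %d.",
                  which(is.na(samples))[1] + 2L))
  }
  sc_recording(samples, fs = fs, start_epoch = start_epoch, units = units)
}

#' Write a single-channel device export
#'
#' Inverse of [read_device_channel()] in `"header"` mode. Values are written
#' with enough digits that a write/read round trip reproduces the recording.
#'
#' @param rec An [sc_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_device_channel <- function(rec, path) {
  stopifnot(inherits(rec, "sc_recording"))
  writeLines(c(format(rec$start_epoch, digits = 15),
               format(rec$fs, digits = 15),
               formatC(rec$samples, digits = 9, format = "g")),
             path)
  invisible(path)
}

#' Read a triaxial accelerometer export
#'
#' Same two-line header as [read_device_channel()], then rows of
#' `x,y,z`. Devices export either m/s^2 directly or raw 1/64-g counts;
#' with `raw_counts = TRUE` each value is multiplied by `conversion`
#' (default 9.81/64) so downstream thresholds always apply in m/s^2.
#'
#' @param path Path to the CSV export.
#' @param raw_counts Are values raw accelerometer counts?
#' @param conversion Count-to-m/s^2 factor used when `raw_counts = TRUE`.
#' @return A [triaxial_recording()].
#' @export
read_triaxial <- function(path, raw_counts = FALSE, conversion = 9.81 / 64) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) abort("format error: expected header plus data rows.")
  start_epoch <- suppressWarnings(as.numeric(lines[1]))
  fs <- suppressWarnings(as.numeric(lines[2]))
  if (is.na(start_epoch) || is.na(fs) || fs <= 0) {
    abort("format error: header lines must be positive reals (epoch, fs).")
  }
  rows <- strsplit(lines[-(1:2)], ",", fixed = TRUE)
  bad <- which(lengths(rows) != 3L)
  if (length(bad)) {
    abort(sprintf("parse error: row %d has %d columns, expected 3.",
                  bad[1] + 2L, lengths(rows)[bad[1]]))
  }
  m <- suppressWarnings(matrix(as.numeric(unlist(rows)), ncol = 3, byrow = TRUE))
  if (anyNA(m)) abort("parse error: non-numeric acceleration value.")
  if (raw_counts) m <- m * conversion
  triaxial_recording(m[, 1], m[, 2], m[, 3], fs = fs, start_epoch = start_epoch)
}

#' Write a triaxial accelerometer export
#'
#' @param rec A [triaxial_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_triaxial <- function(rec, path) {
  stopifnot(inherits(rec, "triaxial_recording"))
  rows <- paste(formatC(rec$x, digits = 9, format = "g"),
                formatC(rec$y, digits = 9, format = "g"),
                formatC(rec$z, digits = 9, format = "g"), sep = ",")
  writeLines(c(format(rec$start_epoch, digits = 15),
               format(rec$fs, digits = 15), rows), path)
  invisible(path)
}

#' Read a Karolinska Sleepiness Scale response log
#'
#' A KSS log is a headerless CSV of `time_s,score`: the time (seconds since
#' session start) at which the driver reported a score, and the 1-9 score.
#' Each response covers the preceding `covers_prior_s` seconds (default 600,
#' the standard 10-minute reporting period).
#'
#' @param path Path to the CSV log.
#' @param covers_prior_s Seconds each response covers (default 600).
#' @return A tibble with columns `time_s`, `score`, `covers_prior_s`,
#'   sorted by `time_s`. An empty file yields a zero-row tibble.
#' @export
read_kss_log <- function(path, covers_prior_s = 600) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble::tibble(time_s = numeric(), score = integer(),
                          covers_prior_s = numeric()))
  }
  rows <- strsplit(lines, ",", fixed = TRUE)
  bad <- which(lengths(rows) != 2L)
  if (length(bad)) abort(sprintf("parse error: row %d needs 2 columns.", bad[1]))
  time_s <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 1L)))
  score <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 2L)))
  if (anyNA(time_s) || anyNA(score)) abort("parse error: non-numeric KSS row.")
  kss_log(time_s, score, covers_prior_s)
}

#' Build a validated KSS log tibble
#'
#' @param time_s Response times in seconds since session start (increasing).
#' @param score Integer KSS scores in 1..9.
#' @param covers_prior_s Seconds each response covers.
#' @return Tibble with columns `time_s`, `score`, `covers_prior_s`.
#' @export
kss_log <- function(time_s, score, covers_prior_s = 600) {
  if (any(score < 1 | score > 9 | score != round(score))) {
    abort("validation error: KSS scores must be integers in 1..9.")
  }
  ord <- order(time_s)
  time_s <- time_s[ord]; score <- score[ord]
  if (any(diff(time_s) <= 0)) {
    abort("validation error: KSS response times must be strictly increasing.")
  }
  tibble::tibble(time_s = time_s, score = as.integer(score),
                 covers_prior_s = rep(as.numeric(covers_prior_s),
                                      length.out = length(time_s)))
}

#' Write a KSS response log
#'
#' @param kss KSS tibble as returned by [read_kss_log()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kss_log <- function(kss, path) {
  writeLines(paste(format(kss$time_s, digits = 10), kss$score, sep = ","), path)
  invisible(path)
}

#' Write a feature table to CSV
#'
#' One header row of feature names plus `class`, one row per window.
#' Class labels are written as integers; feature values with 9 significant
#' digits so read-back reproduces the table.
#'
#' @param table Feature table (tibble with feature columns and `class`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  if (!nrow(table)) abort("refusing to write an empty feature table.")
  df <- as.data.frame(table)
  df$class <- as.integer(df$class)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 9, format = "g"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Path to the CSV.
#' @return Tibble with feature columns and an integer `class` column.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  df$class <- as.integer(df$class)
  tibble::as_tibble(df)
}
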