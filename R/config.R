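#' Pipeline configuration
#'
#' Collects every tunable of the processing chain with the study defaults:
#' artifact proportions 0.01/0.10, 0.04 m/s^2 acceleration gate, 15-s
#' windows, |rho| > 0.90 pruning, 0.01 uS SCR peak threshold, 10-fold
#' cross-validation.
#'
#' @param oversample_to Target Hz for linear oversampling before
#'   filtering, or `NULL` to keep the native rate.
#' @param filter A [filter_config()].
#' @param no_filter Skip artifact filtering entirely.
#' @param scl_cutoff,scl_order Tonic low-pass cutoff (Hz) and order.
#' @param window_s Window length in seconds.
#' @param peak_threshold SCR peak relevance threshold in uS.
#' @param rho_threshold Correlation-pruning threshold.
#' @param no_prune Skip correlation pruning.
#' @param algorithm Classifier: `"rf"`, `"bagging"` or `"boosting"`.
#' @param folds Cross-validation folds.
#' @param seed Seed for fold assignment and model fitting.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(oversample_to = NULL,
                            filter = filter_config(),
                            no_filter = FALSE,
                            scl_cutoff = 0.05, scl_order = 1,
                            window_s = 15,
                            peak_threshold = 0.01,
                            rho_threshold = 0.90,
                            no_prune = FALSE,
                            algorithm = "rf",
                            folds = 10,
                            seed = 1) {
  cfg <- as.list(environment())
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (!is.null(cfg$oversample_to) && cfg$oversample_to <= 0) {
    abort("config error at `oversample_to`: must be positive.")
  }
  if (cfg$scl_cutoff <= 0) abort("config error at `scl_cutoff`: must be > 0.")
  if (cfg$window_s <= 0) abort("config error at `window_s`: must be > 0.")
  if (cfg$rho_threshold <= 0 || cfg$rho_threshold >= 1) {
    abort("config error at `rho_threshold`: must lie in (0, 1).")
  }
  if (!cfg$algorithm %in% c("rf", "bagging", "boosting")) {
    abort("config error at `algorithm`: one of rf, bagging, boosting.")
  }
  if (cfg$folds < 2) abort("config error at `folds`: need >= 2.")
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' Missing keys take the study defaults; unknown keys and badly typed or
#' inconsistent values are rejected with the offending key path in the
#' message. Filter settings live under a nested `filter:` block.
#'
#' @param path Path to a YAML file (an empty file yields all defaults).
#' @return A [pipeline_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) abort("config error: top level must be a YAML mapping.")
  top_known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), top_known)
  if (length(unknown)) {
    abort(sprintf("config error: unknown key(s) %s.",
                  paste0("`", unknown, "`", collapse = ", ")))
  }
  fargs <- raw$filter
  raw$filter <- NULL
  if (!is.null(fargs)) {
    f_known <- names(formals(filter_config))
    f_unknown <- setdiff(names(fargs), f_known)
    if (length(f_unknown)) {
      abort(sprintf("config error: unknown key(s) under `filter`: %s.",
                    paste0("`", f_unknown, "`", collapse = ", ")))
    }
    raw$filter <- do.call(filter_config, fargs)
  }
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration to YAML
#'
#' Round-trips with [load_config()].
#'
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$filter <- unclass(x$filter)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}
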