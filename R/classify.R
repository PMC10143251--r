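#' Confusion matrix from pooled predictions
#'
#' @param truth,pred Integer class labels (1..3).
#' @param levels Class levels (default `1:3`).
#' @return A `levels x levels` integer matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion_matrix <- function(truth, pred, levels = 1:3) {
  m <- table(factor(truth, levels = levels), factor(pred, levels = levels))
  matrix(as.integer(m), nrow = length(levels),
         dimnames = list(true = levels, predicted = levels))
}

#' Accuracy, precision and recall from a confusion matrix
#'
#' Per class, one-vs-rest TP/TN/FP/FN counts are read off the matrix and
#' the binary formulas applied: accuracy `(TP+TN)/(TP+TN+FP+FN)`,
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, as percentages to one
#' decimal. Aggregate accuracy is the pooled multi-class accuracy
#' (trace / total, which equals the micro-averaged one-vs-rest formula);
#' aggregate precision and recall are support-weighted means by default,
#' unweighted (macro) means with `aggregate = "macro"`. A class with no
#' true instances has undefined recall and is omitted from the aggregates
#' with a warning.
#'
#' @param cm Confusion matrix (rows = truth, columns = prediction).
#' @param aggregate `"weighted"` (default) or `"macro"`.
#' @return List: `per_class` tibble (class, tp, tn, fp, fn, accuracy,
#'   precision, recall), and scalars `accuracy`, `precision`, `recall`
#'   in percent.
#' @examples
#' cm <- matrix(c(8, 1, 0, 2, 9, 0, 0, 0, 10), nrow = 3)
#' metrics_from_confusion(cm)$accuracy  # 90
#' @export
metrics_from_confusion <- function(cm, aggregate = c("weighted", "macro")) {
  aggregate <- match.arg(aggregate)
  total <- sum(cm)
  if (total <= 0) abort("empty confusion matrix.")
  k <- nrow(cm)
  per <- purrr::map_dfr(seq_len(k), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    tibble::tibble(
      class = i, tp = tp, tn = tn, fp = fp, fn = fn,
      support = tp + fn,
      accuracy = round(100 * (tp + tn) / total, 1),
      precision = if (tp + fp > 0) round(100 * tp / (tp + fp), 1) else NA_real_,
      recall = if (tp + fn > 0) round(100 * tp / (tp + fn), 1) else NA_real_
    )
  })
  if (any(per$support == 0)) {
    warn(sprintf("class(es) %s have no true instances; omitted from aggregates.",
                 paste(per$class[per$support == 0], collapse = ", ")))
  }
  ok <- per$support > 0
  w <- if (aggregate == "weighted") per$support[ok] else rep(1, sum(ok))
  agg_p <- per$precision[ok]
  agg_p[is.na(agg_p)] <- 0  # no predictions at all for that class
  list(
    per_class = per,
    accuracy = round(100 * sum(diag(cm)) / total, 1),
    precision = round(sum(w * agg_p) / sum(w), 1),
    recall = round(sum(w * per$recall[ok]) / sum(w), 1)
  )
}

## ---- multi-class adaptive boosting (SAMME) over small CART trees ---------

samme_fit <- function(df, n_rounds = 50, maxdepth = 3) {
  df$class <- factor(df$class)
  k <- nlevels(df$class)
  n <- nrow(df)
  w <- rep(1 / n, n)
  learners <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(
      class ~ ., data = df, weights = w, method = "class",
      control = rpart::rpart.control(maxdepth = maxdepth, cp = 0,
                                     minsplit = 2, xval = 0))
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != df$class)) / sum(w)
    if (err >= 1 - 1 / k) break           # worse than chance: stop
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(k - 1)
    w <- w * exp(alpha * (pred != df$class))
    w <- w / sum(w)
    learners[[length(learners) + 1]] <- fit
    alphas <- c(alphas, alpha)
    if (err < 1e-10) break                # perfect fit: done
  }
  structure(list(learners = learners, alphas = alphas,
                 levels = levels(df$class)),
            class = "samme_boost")
}

#' @export
predict.samme_boost <- function(object, newdata, ...) {
  votes <- matrix(0, nrow = nrow(newdata), ncol = length(object$levels),
                  dimnames = list(NULL, object$levels))
  for (m in seq_along(object$learners)) {
    p <- predict(object$learners[[m]], newdata, type = "class")
    votes[cbind(seq_len(nrow(newdata)), as.integer(p))] <-
      votes[cbind(seq_len(nrow(newdata)), as.integer(p))] + object$alphas[m]
  }
  factor(object$levels[max.col(votes, ties.method = "first")],
         levels = object$levels)
}

fit_model <- function(df, algorithm, n_trees = 100, boost_rounds = 50,
                      boost_depth = 3) {
  df$class <- factor(df$class)
  p <- ncol(df) - 1L
  switch(algorithm,
    rf = randomForest::randomForest(class ~ ., data = df, ntree = n_trees),
    ## bagging = random forest that considers every predictor at each split
    bagging = randomForest::randomForest(class ~ ., data = df,
                                         ntree = n_trees, mtry = p),
    boosting = samme_fit(df, n_rounds = boost_rounds, maxdepth = boost_depth),
    abort(sprintf("unknown algorithm '%s'.", algorithm))
  )
}

predict_model <- function(model, newdata) {
  as.integer(as.character(predict(model, newdata, type = "class")))
}

#' Cross-validated evaluation of an ensemble classifier
#'
#' Stratified k-fold cross-validation (k = 10 by default): windows are
#' split into folds preserving class proportions, one model per fold is
#' trained on the currently selected features, and the pooled out-of-fold
#' predictions form a single confusion matrix from which accuracy,
#' precision and recall are computed. Deterministic given the table,
#' algorithm and seed.
#'
#' @param table Feature table with a `class` column; at least `k` rows
#'   and 2 classes.
#' @param algorithm `"rf"` (random forest), `"bagging"` (bootstrap
#'   aggregated trees) or `"boosting"` (multi-class adaptive boosting of
#'   small CART trees).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment and tree growing.
#' @param n_trees Trees per forest for rf/bagging.
#' @param boost_rounds,boost_depth Boosting rounds and base-tree depth.
#' @param aggregate Metric aggregation, `"weighted"` or `"macro"`.
#' @return A list of class `drowsiness_report`: `algorithm`, `k`, `seed`,
#'   `n`, `confusion`, `per_class`, `accuracy`, `precision`, `recall`.
#' @export
crossval_evaluate <- function(table, algorithm = c("rf", "bagging", "boosting"),
                              k = 10, seed = 1, n_trees = 100,
                              boost_rounds = 50, boost_depth = 3,
                              aggregate = c("weighted", "macro")) {
  algorithm <- match.arg(algorithm)
  aggregate <- match.arg(aggregate)
  n <- nrow(table)
  if (n < k) abort(sprintf("need at least k = %d rows.", k))
  if (length(unique(table$class)) < 2) abort("need at least 2 classes.")
  feats <- selected_features(table)
  df <- as.data.frame(table)[, c(feats, "class")]

  withr::with_seed(seed, {
    counts <- base::table(df$class)
    folds <- integer(n)
    if (min(counts) >= k) {
      for (cl in names(counts)) {
        idx <- sample(which(df$class == cl))
        folds[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      warn(sprintf("class with only %d members: falling back to a
non-stratified split.", min(counts)))
      folds <- rep_len(seq_len(k), n)[sample(n)]
    }
    pred <- integer(n)
    for (f in seq_len(k)) {
      hold <- folds == f
      model <- fit_model(df[!hold, , drop = FALSE], algorithm,
                         n_trees = n_trees, boost_rounds = boost_rounds,
                         boost_depth = boost_depth)
      pred[hold] <- predict_model(model, df[hold, , drop = FALSE])
    }
    cm <- confusion_matrix(df$class, pred,
                           levels = sort(unique(as.integer(df$class))))
    mets <- metrics_from_confusion(cm, aggregate)
    structure(list(algorithm = algorithm, k = k, seed = seed, n = n,
                   features = feats, confusion = cm,
                   per_class = mets$per_class, accuracy = mets$accuracy,
                   precision = mets$precision, recall = mets$recall),
              class = "drowsiness_report")
  })
}

#' @export
print.drowsiness_report <- function(x, ...) {
  cat(sprintf("<drowsiness_report> %s, %d-fold CV on %d windows (%d features)\n",
              x$algorithm, x$k, x$n, length(x$features)))
  cat(sprintf("  accuracy %.1f%%  precision %.1f%%  recall %.1f%%\n",
              x$accuracy, x$precision, x$recall))
  cat("  confusion (rows = true):\n")
  print(x$confusion)
  invisible(x)
}

#' @export
#' @method tidy drowsiness_report
tidy.drowsiness_report <- function(x, ...) x$per_class

#' @export
#' @method glance drowsiness_report
glance.drowsiness_report <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, folds = x$k, seed = x$seed,
                 n = x$n, n_features = length(x$features),
                 accuracy = x$accuracy, precision = x$precision,
                 recall = x$recall)
}

#' Serialise / restore a classification report
#'
#' @param report A `drowsiness_report`.
#' @param path JSON output path.
#' @return `path` invisibly, or the restored report.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(list(
    algorithm = report$algorithm, k = report$k, seed = report$seed,
    n = report$n, features = report$features,
    confusion = unname(as.data.frame(report$confusion)),
    per_class = report$per_class, accuracy = report$accuracy,
    precision = report$precision, recall = report$recall
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cm <- as.matrix(x$confusion)
  dimnames(cm) <- list(true = seq_len(nrow(cm)), predicted = seq_len(ncol(cm)))
  structure(list(algorithm = x$algorithm, k = x$k, seed = x$seed, n = x$n,
                 features = x$features, confusion = cm,
                 per_class = tibble::as_tibble(x$per_class),
                 accuracy = x$accuracy, precision = x$precision,
                 recall = x$recall),
            class = "drowsiness_report")
}

#' Run the full drowsiness-detection pipeline
#'
#' Executes the processing chain end to end: optional linear oversampling,
#' motion-artifact filtering (improved overlapped variant by default),
#' tonic/phasic decomposition, 15-s windowing, KSS labelling, feature
#' extraction, correlation pruning and cross-validated classification.
#'
#' @param sc SC [sc_recording()] (or an `sc_session`, whose components are
#'   then used and `acc`/`kss` may be omitted).
#' @param acc [triaxial_recording()] aligned with `sc`.
#' @param kss KSS tibble.
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, every intermediate
#'   artifact is written there (filtered channel, feature table, report).
#' @return List of class `sc_pipeline_result`: `report`
#'   (`drowsiness_report`), `feature_table`, `windows`, `filtered`,
#'   `decomposed`, `config`.
#' @export
run_pipeline <- function(sc, acc = NULL, kss = NULL,
                         config = pipeline_config(), outdir = NULL) {
  if (inherits(sc, "sc_session")) {
    acc <- acc %||% sc$acc
    kss <- kss %||% sc$kss
    sc <- sc$sc
  }
  if (is.null(acc) || is.null(kss)) abort("need `acc` and `kss` inputs.")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  if (!is.null(config$oversample_to) && config$oversample_to > sc$fs) {
    sc <- stage("oversample", oversample_linear(sc, config$oversample_to))
  }
  filtered <- if (isTRUE(config$no_filter)) sc else {
    stage("filter", filter_artifacts(sc, acc, config$filter))
  }
  dec <- stage("decompose",
               decompose_scl_scr(filtered, cutoff = config$scl_cutoff,
                                 order = config$scl_order))
  windows <- stage("window", window_segments(dec, config$window_s))
  windows <- stage("label", assign_labels(windows, kss))
  tab <- stage("features",
               extract_feature_table(windows, dec$fs, config$peak_threshold))
  if (!isTRUE(config$no_prune)) {
    tab <- stage("prune", correlation_prune(tab, config$rho_threshold))
  }
  report <- stage("classify",
                  crossval_evaluate(tab, config$algorithm, k = config$folds,
                                    seed = config$seed))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_device_channel(filtered, file.path(outdir, "filtered_sc.csv"))
    write_feature_table(tab, file.path(outdir, "feature_table.csv"))
    write_report(report, file.path(outdir, "report.json"))
  }
  structure(list(report = report, feature_table = tab, windows = windows,
                 filtered = filtered, decomposed = dec, config = config),
            class = "sc_pipeline_result")
}

#' @export
print.sc_pipeline_result <- function(x, ...) {
  cat(sprintf("<sc_pipeline_result> %d windows, %d selected features\n",
              nrow(x$feature_table), length(selected_features(x$feature_table))))
  print(x$report)
  invisible(x)
}
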