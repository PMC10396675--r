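# Stratified k-fold cross-validation harness and confusion-derived
# reporting.  The positive class is "malignant" throughout; every sample
# receives exactly one out-of-fold prediction and metrics are pooled over
# those predictions.

#' Stratified fold assignment
#'
#' @param labels factor or character class labels.
#' @param k_folds number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids in 1..k_folds.
#' @export
make_folds <- function(labels, k_folds = 10L, seed = 1L) {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts < k_folds))
    stopf("class '%s' has only %d members, fewer than k_folds = %d; use a smaller k",
          names(counts)[which.min(counts)], min(counts), k_folds)
  folds <- integer(length(labels))
  with_local_seed(derive_seed(seed, 23L), {
    for (cl in levels(labels)) {
      ix <- which(labels == cl)
      ix <- ix[sample(length(ix))]
      folds[ix] <- rep_len(seq_len(k_folds), length(ix))
    }
  })
  folds
}

#' Confusion-derived classification metrics
#'
#' `accuracy = (TP+TN)/N`, `sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)`, `fpr = FP/(FP+TN)`,
#' `error_rate = 1 - accuracy`, positive class = malignant.  Ratios with a
#' zero denominator are reported as `NA` and named in `undefined`.
#'
#' @param TP,FP,TN,FN non-negative integer counts, total > 0.
#' @return List with the five metrics (fractions) and an `undefined`
#'   character vector.
#' @export
confusion_metrics <- function(TP, FP, TN, FN) {
  for (nm in c("TP", "FP", "TN", "FN")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 ||
        v != round(v))
      stopf("count '%s' must be a non-negative integer", nm)
  }
  n <- TP + FP + TN + FN
  if (n == 0) stopf("total count must be positive")
  undefined <- character(0)
  ratio <- function(num, den, nm) {
    if (den == 0) { undefined <<- c(undefined, nm); return(NA_real_) }
    num / den
  }
  acc <- (TP + TN) / n
  list(accuracy = acc,
       sensitivity = ratio(TP, TP + FN, "sensitivity"),
       specificity = ratio(TN, TN + FP, "specificity"),
       false_positive_rate = ratio(FP, FP + TN, "false_positive_rate"),
       error_rate = 1 - acc,
       undefined = undefined)
}

#' Cross-validate a bank of classifiers
#'
#' Stratified k-fold CV; for each classifier the out-of-fold predictions are
#' pooled into one confusion matrix (positive class = malignant) from which
#' accuracy, sensitivity, specificity, FPR and error rate are derived.
#' Wall-clock training time and prediction throughput are recorded per
#' classifier; they are hardware-dependent and reported only.
#'
#' @param features numeric matrix (samples x features).
#' @param labels factor/character with levels `benign`/`malignant`.
#' @param specs character vector of preset names (see
#'   [classifier_presets()]) or a list of [build_classifier()] objects.
#' @param k_folds number of folds (default 10).
#' @param seed integer seed controlling folds and stochastic learners.
#' @param verbose print progress.
#' @return An `eval_report` data frame (one row per classifier) carrying
#'   per-classifier confusion matrices, fold ids and out-of-fold
#'   predictions as attributes.
#' @export
cross_validate <- function(features, labels, specs = default_classifier_bank(),
                           k_folds = 10L, seed = 1L, verbose = FALSE) {
  features <- as.matrix(features)
  labels <- as.factor(as.character(labels))
  if (nrow(features) != length(labels))
    stopf("features has %d rows but %d labels given", nrow(features),
          length(labels))
  pos <- if ("malignant" %in% levels(labels)) "malignant"
         else levels(labels)[length(levels(labels))]
  y01 <- as.integer(labels == pos)
  folds <- make_folds(labels, k_folds, seed)
  if (is.character(specs))
    specs <- lapply(specs, build_classifier, seed = seed)

  rows <- list(); confusions <- list(); oof <- list()
  for (clf in specs) {
    pred <- integer(length(y01))
    t_fit <- 0; t_pred <- 0
    for (f in seq_len(k_folds)) {
      tr <- folds != f; te <- !tr
      t0 <- proc.time()[["elapsed"]]
      fitted <- fit_classifier(clf, features[tr, , drop = FALSE], y01[tr])
      t1 <- proc.time()[["elapsed"]]
      pred[te] <- predict_classifier(fitted, features[te, , drop = FALSE])
      t2 <- proc.time()[["elapsed"]]
      t_fit <- t_fit + (t1 - t0); t_pred <- t_pred + (t2 - t1)
    }
    tp <- sum(pred == 1L & y01 == 1L); fp <- sum(pred == 1L & y01 == 0L)
    tn <- sum(pred == 0L & y01 == 0L); fn <- sum(pred == 0L & y01 == 1L)
    m <- confusion_metrics(tp, fp, tn, fn)
    rows[[clf$name]] <- data.frame(
      method = clf$name,
      prediction_speed_obs_per_sec = length(y01) / max(t_pred, 1e-6),
      training_time_sec = t_fit,
      accuracy_pct = 100 * m$accuracy,
      sensitivity = m$sensitivity,
      specificity = m$specificity,
      false_positive_rate = m$false_positive_rate,
      error_rate_pct = 100 * m$error_rate,
      tp = tp, fp = fp, tn = tn, fn = fn)
    confusions[[clf$name]] <- c(TP = tp, FP = fp, TN = tn, FN = fn)
    oof[[clf$name]] <- pred
    if (verbose)
      message(sprintf("%-24s acc %5.1f%%  (fit %.2fs)", clf$name,
                      100 * m$accuracy, t_fit))
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(report, class = c("eval_report", "data.frame"),
            confusions = confusions, folds = folds, oof = oof,
            positive_class = pos, k_folds = k_folds, seed = seed)
}

#' Rank classifiers and write report files
#'
#' Writes `results.csv` (the benchmark table), `summary.json` (best method
#' by accuracy, training time as tie-breaker) and
#' `confusion_matrices.json`.
#'
#' @param report an `eval_report` from [cross_validate()].
#' @param out output directory.
#' @return Invisibly, a list with the output paths and the ranked table.
#' @export
rank_and_report <- function(report, out) {
  if (!inherits(report, "eval_report") || nrow(report) == 0)
    stopf("report must be a non-empty eval_report")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out)) stopf("cannot create output directory '%s'", out)
  ord <- order(-report$accuracy_pct, report$training_time_sec)
  ranked <- report[ord, , drop = FALSE]
  csv_path <- file.path(out, "results.csv")
  utils::write.csv(as.data.frame(ranked), csv_path, row.names = FALSE)
  best <- ranked[1, ]
  summary <- list(
    best = list(method = best$method,
                accuracy_pct = best$accuracy_pct,
                sensitivity = best$sensitivity,
                specificity = best$specificity,
                false_positive_rate = best$false_positive_rate,
                training_time_sec = best$training_time_sec),
    ranking = ranked$method,
    k_folds = attr(report, "k_folds"),
    positive_class = attr(report, "positive_class"))
  json_path <- file.path(out, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  conf_path <- file.path(out, "confusion_matrices.json")
  jsonlite::write_json(lapply(attr(report, "confusions"), as.list), conf_path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(results_csv = csv_path, summary_json = json_path,
                 confusions_json = conf_path, ranked = ranked))
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", nrow(x), "classifier(s),", attr(x, "k_folds"),
      "folds, positive =", attr(x, "positive_class"), "\n")
  df <- as.data.frame(x)[, c("method", "accuracy_pct", "sensitivity",
                             "specificity", "training_time_sec")]
  df$accuracy_pct <- round(df$accuracy_pct, 1)
  df$sensitivity <- round(df$sensitivity, 3)
  df$specificity <- round(df$specificity, 3)
  df$training_time_sec <- round(df$training_time_sec, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
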