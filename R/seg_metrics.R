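# Semantic segmentation scoring: global/mean accuracy, mean/weighted IoU
# and mean boundary-F1 for binary (nodule vs background) masks.

seg_confusion <- function(pred, truth) {
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# boundary pixels of a binary mask: foreground pixels 4-adjacent to a
# background pixel (image border itself does not create boundary)
boundary_coords <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up <- rbind(m[1, , drop = FALSE], m[-h, , drop = FALSE])
  dn <- rbind(m[-1, , drop = FALSE], m[h, , drop = FALSE])
  lf <- cbind(m[, 1, drop = FALSE], m[, -w, drop = FALSE])
  rt <- cbind(m[, -1, drop = FALSE], m[, w, drop = FALSE])
  b <- m == 1L & (up == 0L | dn == 0L | lf == 0L | rt == 0L)
  which(b, arr.ind = TRUE)
}

bf_class_score <- function(pred_c, truth_c, tol) {
  pb <- boundary_coords(pred_c)
  tb <- boundary_coords(truth_c)
  if (nrow(pb) == 0 && nrow(tb) == 0) return(1)
  if (nrow(pb) == 0 || nrow(tb) == 0) return(0)
  precision <- cpp_match_fraction(pb * 1.0, tb * 1.0, tol)
  recall <- cpp_match_fraction(tb * 1.0, pb * 1.0, tol)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

metrics_from_confusion <- function(cf, bf) {
  n <- sum(cf)
  # per-class (background = 0, nodule = 1) recall and IoU
  rec <- c(bg = unname(if (cf["tn"] + cf["fp"] > 0) cf["tn"] / (cf["tn"] + cf["fp"]) else NA),
           nod = unname(if (cf["tp"] + cf["fn"] > 0) cf["tp"] / (cf["tp"] + cf["fn"]) else NA))
  iou <- c(bg = unname(if (cf["tn"] + cf["fp"] + cf["fn"] > 0)
                         cf["tn"] / (cf["tn"] + cf["fp"] + cf["fn"]) else NA),
           nod = unname(if (cf["tp"] + cf["fp"] + cf["fn"] > 0)
                          cf["tp"] / (cf["tp"] + cf["fp"] + cf["fn"]) else NA))
  freq <- c(bg = unname((cf["tn"] + cf["fp"]) / n),
            nod = unname((cf["tp"] + cf["fn"]) / n))
  present <- freq > 0
  structure(list(
    global_accuracy = unname((cf["tp"] + cf["tn"]) / n),
    mean_accuracy = mean(rec, na.rm = TRUE),
    mean_iou = mean(iou[!is.na(iou)]),
    weighted_iou = sum(freq[present] * iou[present]),
    mean_bf_score = bf,
    per_class_iou = iou,
    confusion = cf
  ), class = "seg_metrics")
}

#' Segmentation metric suite
#'
#' Computes global accuracy, mean per-class accuracy (recall), mean and
#' class-frequency-weighted IoU, and mean boundary-F1.  Boundary pixels are
#' foreground pixels of a class 4-adjacent to the other class; a predicted
#' boundary pixel matches if a true boundary pixel lies within
#' `bf_tolerance` (Euclidean), and vice versa for recall.
#'
#' @param pred,truth equal-shaped binary \{0, 1\} matrices.
#' @param bf_tolerance boundary match tolerance in pixels; default 0.75% of
#'   the image diagonal (the usual convention for this metric).
#' @return An object of class `seg_metrics` (all scores in \[0, 1\]).
#' @export
compute_seg_metrics <- function(pred, truth, bf_tolerance = NULL) {
  if (!all(dim(pred) == dim(truth))) stopf("pred and truth shapes differ")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stopf("masks must be binary {0,1}")
  pred <- matrix(as.integer(pred), nrow(pred), ncol(pred))
  truth <- matrix(as.integer(truth), nrow(truth), ncol(truth))
  if (is.null(bf_tolerance))
    bf_tolerance <- 0.0075 * sqrt(sum(dim(truth)^2))
  cf <- seg_confusion(pred, truth)
  bf <- mean(c(bf_class_score(1L - pred, 1L - truth, bf_tolerance),
               bf_class_score(pred, truth, bf_tolerance)))
  metrics_from_confusion(cf, bf)
}

# pooled metrics across a set of slices: pixel confusion summed, BF score
# averaged per slice
pooled_seg_metrics <- function(preds, truths, bf_tolerance = NULL) {
  stopifnot(length(preds) == length(truths))
  if (is.null(bf_tolerance))
    bf_tolerance <- 0.0075 * sqrt(sum(dim(truths[[1]])^2))
  cf <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  bfs <- numeric(length(preds))
  for (i in seq_along(preds)) {
    p <- matrix(as.integer(preds[[i]]), nrow(preds[[i]]), ncol(preds[[i]]))
    t <- matrix(as.integer(truths[[i]]), nrow(truths[[i]]), ncol(truths[[i]]))
    cf <- cf + seg_confusion(p, t)
    bfs[i] <- mean(c(bf_class_score(1L - p, 1L - t, bf_tolerance),
                     bf_class_score(p, t, bf_tolerance)))
  }
  metrics_from_confusion(cf, mean(bfs))
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf(paste0("<seg_metrics> global acc %.4f | mean acc %.4f | ",
                     "mean IoU %.4f | weighted IoU %.4f | mean BF %.4f\n"),
              x$global_accuracy, x$mean_accuracy, x$mean_iou, x$weighted_iou,
              x$mean_bf_score))
  invisible(x)
}
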