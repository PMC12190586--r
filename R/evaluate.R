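#' Confusion matrix with predictions in rows
#'
#' Builds a K x K count matrix with rows indexing the predicted label and
#' columns the true label.
#'
#' @param predicted,truth Integer 0-based class labels of equal length.
#' @param n_classes Number of classes K (default: inferred).
#' @param class_names Optional K labels for printing.
#' @return Integer matrix of class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(predicted, truth, n_classes = NULL,
                             class_names = NULL) {
  stopifnot(length(predicted) == length(truth))
  if (is.null(n_classes)) n_classes <- max(predicted, truth) + 1L
  stopifnot(all(predicted >= 0 & predicted < n_classes),
            all(truth >= 0 & truth < n_classes))
  lv <- 0:(n_classes - 1L)
  cm <- as.matrix(table(factor(predicted, levels = lv),
                        factor(truth, levels = lv)))
  if (is.null(class_names)) class_names <- paste0("class", lv)
  dimnames(cm) <- list(predicted = class_names, true = class_names)
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' One-vs-rest counts for a class
#'
#' Treats class `k` as positive and all others pooled as negative:
#' `TP = cm[k, k]`, `FP` the rest of predicted row `k`, `FN` the rest of true
#' column `k`, `TN` everything else.
#'
#' @param cm A confusion matrix (rows = predicted, cols = true).
#' @param k 1-based class index.
#' @return Named vector `c(tp, fp, tn, fn)`.
#' @export
one_vs_rest_counts <- function(cm, k) {
  K <- nrow(cm)
  if (k < 1L || k > K) stop("class index out of range", call. = FALSE)
  tp <- cm[k, k]
  fp <- sum(cm[k, ]) - tp
  fn <- sum(cm[, k]) - tp
  tn <- sum(cm) - tp - fp - fn
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Binary classification metrics from one-vs-rest counts
#'
#' Accuracy `(TP+TN)/(TP+FP+TN+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, F1 `2*Pre*Rec/(Pre+Rec)`, and the Matthews correlation
#' coefficient `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A zero denominator yields 0 with a warning (precision/recall/F1/MCC).
#'
#' @param tp,fp,tn,fn Nonnegative counts, not all zero.
#' @return Named vector `c(acc, pre, rec, f1, mcc)`.
#' @export
metrics_from_counts <- function(tp, fp, tn, fn) {
  tp <- unname(tp); fp <- unname(fp); tn <- unname(tn); fn <- unname(fn)
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  tot <- tp + fp + tn + fn
  if (tot == 0) stop("all counts are zero", call. = FALSE)
  div0 <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s has zero denominator; returning 0", what),
              call. = FALSE)
      0
    } else num / den
  }
  acc <- (tp + tn) / tot
  pre <- div0(tp, tp + fp, "precision")
  rec <- div0(tp, tp + fn, "recall")
  f1 <- if (pre + rec == 0) 0 else 2 * pre * rec / (pre + rec)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- div0(tp * tn - fp * fn, mcc_den, "MCC")
  c(acc = acc, pre = pre, rec = rec, f1 = f1, mcc = mcc)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p0 - pe) / (1 - pe)` with observed agreement
#' `p0 = trace / total` and chance agreement
#' `pe = sum_k rowsum_k * colsum_k / total^2`.
#'
#' @param cm Confusion matrix (any orientation; the statistic is symmetric in
#'   the marginals).
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix", call. = FALSE)
  p0 <- sum(diag(cm)) / tot
  pe <- sum(rowSums(cm) * colSums(cm)) / tot^2
  if (pe >= 1) stop("degenerate matrix: chance agreement is 1", call. = FALSE)
  (p0 - pe) / (1 - pe)
}

# Midrank (Mann-Whitney) AUC of scores for a binary 0/1 label vector.
binary_auc <- function(scores, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest mean AUC
#'
#' For each class, computes the area under the ROC curve of the binary
#' problem "this class vs the rest" from that class's predicted probability,
#' using the rank statistic (Mann-Whitney U normalization, midranks for
#' ties). Returns the unweighted mean over classes present in the labels;
#' classes with zero positives or zero negatives are skipped with a warning.
#'
#' @param scores `n x K` matrix of class probabilities (rows summing to 1).
#' @param labels Integer 0-based true classes, length `n`.
#' @return Mean AUC in \[0, 1\]; attribute `"per_class"` holds the per-class
#'   values (NA where skipped).
#' @export
ovr_auc <- function(scores, labels) {
  stopifnot(is.matrix(scores), nrow(scores) == length(labels))
  if (any(abs(rowSums(scores) - 1) > 1e-6))
    stop("probability rows must sum to 1", call. = FALSE)
  K <- ncol(scores)
  per <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    pos <- labels == (k - 1L)
    if (!any(pos) || all(pos)) {
      warning(sprintf("class %d has zero positives or zero negatives; skipped",
                      k - 1L), call. = FALSE)
      next
    }
    per[k] <- binary_auc(scores[, k], pos)
  }
  structure(mean(per, na.rm = TRUE), per_class = per)
}

# Otsu's histogram threshold: maximizes between-class variance over
# `levels` equal-width bins spanning the value range.
otsu_threshold <- function(v, levels = 256L) {
  r <- range(v)
  if (r[1L] == r[2L]) return(r[1L])
  br <- seq(r[1L], r[2L], length.out = levels + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (br[-1L] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[levels]
  sb <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  br[which.max(sb) + 1L]
}

#' Attention-to-lesion alignment (IoU)
#'
#' Quantifies how well a network attention map localizes the lesion: the map
#' is binarized (by default at its own Otsu threshold) and the
#' intersection-over-union with the ground-truth lesion mask is returned.
#'
#' @param a_model Attention map: matrix or `"network_attention_map"`.
#' @param lesion_mask Logical/0-1 matrix of the same shape; must contain at
#'   least one positive pixel.
#' @param threshold `"otsu"` (default) or `"fixed"`.
#' @param level Threshold level when `threshold = "fixed"` (default 0.5).
#' @return IoU in \[0, 1\].
#' @export
attention_alignment <- function(a_model, lesion_mask,
                                threshold = c("otsu", "fixed"), level = 0.5) {
  threshold <- match.arg(threshold)
  a <- if (is.list(a_model)) a_model$values else a_model
  m <- lesion_mask > 0
  if (!identical(dim(a), dim(m)))
    stop("attention map and mask shapes do not match", call. = FALSE)
  if (!any(m)) stop("lesion mask is empty", call. = FALSE)
  thr <- if (threshold == "otsu") otsu_threshold(as.vector(a)) else level
  bin <- a > thr
  inter <- sum(bin & m)
  uni <- sum(bin | m)
  if (uni == 0) 0 else inter / uni
}

#' Evaluate a fitted model on one split
#'
#' Predicts the requested split, builds the confusion matrix (rows =
#' predicted, cols = true), computes the six one-vs-rest metrics per class,
#' aggregates them (unweighted macro mean by default, support-weighted with
#' `average = "weighted"`), Cohen's kappa on the full matrix, the one-vs-rest
#' mean AUC, and — when lesion masks are available — the mean
#' attention-to-lesion IoU of [attention_alignment()].
#'
#' @param object A fitted [gazecam()] model.
#' @param data A `"polyp_data"`-style list.
#' @param split Which split to evaluate (default `"test"`).
#' @param average `"macro"` (default) or `"weighted"` aggregation of the
#'   per-class one-vs-rest metrics.
#' @return A list of class `"metric_report"`: `accuracy`, `precision`,
#'   `recall`, `f1`, `mcc`, `kappa`, `auc`, `per_class`, `confusion`, `n`,
#'   and `mean_attention_iou` (NA without masks).
#' @export
evaluate_model <- function(object, data, split = "test",
                           average = c("macro", "weighted")) {
  average <- match.arg(average)
  idx <- which(data$split == split)
  if (length(idx) == 0L) stop(sprintf("no images in split '%s'", split),
                              call. = FALSE)
  sub <- data$images[, , , idx, drop = FALSE]
  truth <- data$labels[idx]
  probs <- predict(object, sub, type = "prob")
  pred <- max.col(probs, ties.method = "first") - 1L
  K <- object$num_classes
  cm <- confusion_matrix(pred, truth, K)
  per <- t(vapply(seq_len(K), function(k) {
    cnt <- one_vs_rest_counts(cm, k)
    suppressWarnings(metrics_from_counts(cnt["tp"], cnt["fp"],
                                         cnt["tn"], cnt["fn"]))
  }, numeric(5)))
  dimnames(per) <- list(rownames(cm), c("acc", "pre", "rec", "f1", "mcc"))
  w <- if (average == "weighted") colSums(cm) / sum(cm) else rep(1 / K, K)
  agg <- colSums(per * w)
  auc <- suppressWarnings(ovr_auc(probs, truth))
  iou <- NA_real_
  if (!is.null(data$masks)) {
    att <- predict(object, sub, type = "attention")
    iou <- mean(vapply(seq_along(idx), function(j)
      attention_alignment(att[, , j], data$masks[, , idx[j]]), numeric(1)))
  }
  structure(list(accuracy = sum(diag(cm)) / sum(cm),
                 precision = agg[["pre"]], recall = agg[["rec"]],
                 f1 = agg[["f1"]], mcc = agg[["mcc"]],
                 kappa = cohens_kappa(cm), auc = as.numeric(auc),
                 per_class = per, confusion = cm, n = length(idx),
                 average = average, split = split,
                 mean_attention_iou = iou),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> split '%s', n = %d (%s average)\n",
              x$split, x$n, x$average))
  cat(sprintf("  Acc %.4f  Pre %.4f  Rec %.4f  F1 %.4f  MCC %.4f  Kappa %.4f  AUC %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1, x$mcc, x$kappa, x$auc))
  if (!is.na(x$mean_attention_iou))
    cat(sprintf("  mean attention-lesion IoU %.4f\n", x$mean_attention_iou))
  cat("  confusion matrix (rows = predicted, cols = true):\n")
  print(unclass(x$confusion))
  invisible(x)
}
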