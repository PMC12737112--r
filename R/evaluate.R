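#' Categorical classification report
#'
#' Full metric suite for single-label six-class frame prediction:
#' accuracy; balanced accuracy (unweighted mean of per-class recalls);
#' precision, recall and F1, each micro- and macro-averaged; Hamming loss;
#' per-class support.  Macro averages are unweighted means over the six
#' modeled emotions; classes absent from the truth contribute recall 0.
#' Hamming loss is computed on class-label assignments — the per-frame
#' misclassification rate — so `hamming_loss = 1 - accuracy` and, with
#' every frame predicted, `micro-F1 = accuracy`.
#'
#' @param true_labels,pred_labels Character vectors of equal length; true
#'   labels must be modeled emotions (`other` frames are excluded
#'   upstream).
#' @return A `classification_report` list.
#' @export
classification_report <- function(true_labels, pred_labels) {
  lv <- emotion_levels()
  stopifnot(length(true_labels) == length(pred_labels))
  if (length(true_labels) == 0L) stop("empty input")
  if (!all(true_labels %in% lv)) {
    stop("true labels must be one of the six modeled emotions")
  }
  truth <- factor(true_labels, levels = lv)
  pred <- factor(pred_labels, levels = lv)
  cm <- table(truth, pred)
  tp <- diag(cm)
  support <- rowSums(cm)
  pred_n <- colSums(cm)
  n <- length(truth)
  acc <- sum(tp) / n
  recall_c <- ifelse(support > 0, tp / support, 0)
  prec_c <- ifelse(pred_n > 0, tp / pred_n, 0)
  f1_c <- ifelse(prec_c + recall_c > 0,
                 2 * prec_c * recall_c / (prec_c + recall_c), 0)
  micro_p <- sum(tp) / sum(pred_n)   # = accuracy when every frame predicted
  micro_r <- sum(tp) / sum(support)
  micro_f1 <- 2 * micro_p * micro_r / (micro_p + micro_r)
  structure(list(
    n = n,
    accuracy = acc,
    balanced_accuracy = mean(recall_c),
    precision_micro = micro_p, recall_micro = micro_r, f1_micro = micro_f1,
    precision_macro = mean(prec_c), recall_macro = mean(recall_c),
    f1_macro = mean(f1_c),
    hamming_loss = 1 - acc,
    per_class = data.frame(emotion = lv, support = as.vector(support),
                           precision = as.vector(prec_c),
                           recall = as.vector(recall_c),
                           f1 = as.vector(f1_c))
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Classification report (%d frames)\n", x$n))
  cat(sprintf("  accuracy %.4f | balanced accuracy %.4f | hamming %.4f\n",
              x$accuracy, x$balanced_accuracy, x$hamming_loss))
  cat(sprintf("  micro  P/R/F1: %.4f / %.4f / %.4f\n",
              x$precision_micro, x$recall_micro, x$f1_micro))
  cat(sprintf("  macro  P/R/F1: %.4f / %.4f / %.4f\n",
              x$precision_macro, x$recall_macro, x$f1_macro))
  print(x$per_class, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Regression report for emotion-intensity prediction
#'
#' Per-emotion mean squared error and mean absolute error over valid
#' (unmasked) frames, and cosine similarity between each emotion's
#' predicted and true time series.  The overall MSE/MAE is the unweighted
#' mean of the six per-emotion values; the overall cosine similarity is
#' reported both as the unweighted mean of the per-emotion cosines and as
#' the mean per-frame cosine (`cosine_frames`).  An emotion whose true or
#' predicted series has zero norm has undefined cosine, reported as `NA`.
#'
#' @param true_dists,pred_dists `n x 6` matrices.
#' @param mask Optional binary vector marking valid frames (default: all).
#' @return A `regression_report` list.
#' @export
regression_report <- function(true_dists, pred_dists, mask = NULL) {
  stopifnot(ncol(true_dists) == 6L, all(dim(true_dists) == dim(pred_dists)))
  if (is.null(mask)) mask <- rep(1L, nrow(true_dists))
  keep <- as.logical(mask)
  if (!any(keep)) stop("no valid frames after masking")
  tr <- true_dists[keep, , drop = FALSE]
  pr <- pred_dists[keep, , drop = FALSE]
  lv <- emotion_levels()
  mse <- colMeans((pr - tr)^2)
  mae <- colMeans(abs(pr - tr))
  cosine <- vapply(1:6, function(j) {
    num <- sum(tr[, j] * pr[, j])
    den <- sqrt(sum(tr[, j]^2)) * sqrt(sum(pr[, j]^2))
    if (den == 0) NA_real_ else num / den
  }, numeric(1))
  frame_cos <- {
    num <- rowSums(tr * pr)
    den <- sqrt(rowSums(tr^2)) * sqrt(rowSums(pr^2))
    ok <- den > 0
    if (any(ok)) mean(num[ok] / den[ok]) else NA_real_
  }
  structure(list(
    n = sum(keep),
    per_emotion = data.frame(emotion = lv, mse = as.vector(mse),
                             mae = as.vector(mae),
                             cosine = as.vector(cosine)),
    mse_overall = mean(mse),
    mae_overall = mean(mae),
    cosine_overall = mean(cosine, na.rm = TRUE),
    cosine_frames = frame_cos
  ), class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("Regression report (%d valid frames)\n", x$n))
  print(x$per_emotion, row.names = FALSE, digits = 4)
  cat(sprintf("  overall MSE %.4f | MAE %.4f | cosine %.4f\n",
              x$mse_overall, x$mae_overall, x$cosine_overall))
  invisible(x)
}

#' Row-normalized confusion matrix
#'
#' 6x6 matrix of counts and the row-normalized percentage matrix (each row
#' is the percentage of samples of a true class predicted as each output
#' class).  Rows without support are all-zero and flagged in the
#' `empty_rows` attribute.
#'
#' @inheritParams classification_report
#' @return A `confusion_matrix` list with `counts` and `percent`.
#' @export
confusion_percent <- function(true_labels, pred_labels) {
  lv <- emotion_levels()
  truth <- factor(true_labels, levels = lv)
  pred <- factor(pred_labels, levels = lv)
  counts <- unclass(table(truth, pred))
  rs <- rowSums(counts)
  percent <- counts * 0
  nz <- rs > 0
  percent[nz, ] <- 100 * counts[nz, , drop = FALSE] / rs[nz]
  structure(list(counts = counts, percent = percent,
                 empty_rows = lv[!nz]),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (row-normalized %):\n")
  print(round(x$percent, 1))
  if (length(x$empty_rows) > 0) {
    cat("  no support for:", paste(x$empty_rows, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a confusion matrix as CSV with emotion-name headers
#'
#' @param cm A `confusion_matrix`.
#' @param path Output file.
#' @param what `"percent"` (default, one decimal) or `"counts"`.
#' @return The path, invisibly.
#' @export
write_confusion_csv <- function(cm, path, what = c("percent", "counts")) {
  what <- match.arg(what)
  m <- cm[[what]]
  if (what == "percent") m <- round(m, 1)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Evaluate intensity predictions on the categorical task
#'
#' Maps continuous Method II predictions to dominant-emotion labels by
#' frame-wise argmax ([dominant_from_distribution()]) and evaluates them
#' with the full categorical metric suite against the Method I truth on
#' the same frames, enabling a direct comparison of the two annotation
#' schemes.
#'
#' @param pred_dists `n x 6` matrix of predicted intensities.
#' @param true_m1_labels Character vector of Method I truths (modeled
#'   emotions only) on the same `n` frames.
#' @return A list with `report` ([classification_report()]) and
#'   `confusion` ([confusion_percent()]).
#' @export
map_and_report <- function(pred_dists, true_m1_labels) {
  if (nrow(pred_dists) != length(true_m1_labels)) {
    stop("prediction and truth cover different frame sets")
  }
  mapped <- dominant_from_distribution(pred_dists)
  # argmax of a non-degenerate prediction is always a modeled emotion; a
  # degenerate all-zero prediction falls back to the tie-break class
  mapped[mapped == "other"] <- emotion_levels()[1L]
  list(report = classification_report(true_m1_labels, mapped),
       confusion = confusion_percent(true_m1_labels, mapped))
}

#' Serialize a classification report to CSV
#'
#' Writes the scalar metrics and the per-class table.
#'
#' @param report A `classification_report`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_report_csv <- function(report, path) {
  scalars <- data.frame(
    metric = c("n", "accuracy", "balanced_accuracy", "precision_micro",
               "recall_micro", "f1_micro", "precision_macro", "recall_macro",
               "f1_macro", "hamming_loss"),
    value = c(report$n, report$accuracy, report$balanced_accuracy,
              report$precision_micro, report$recall_micro, report$f1_micro,
              report$precision_macro, report$recall_macro, report$f1_macro,
              report$hamming_loss))
  utils::write.csv(scalars, path, row.names = FALSE)
  invisible(path)
}
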