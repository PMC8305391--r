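#' Area under the ROC curve by the rank statistic
#'
#' One-vs-rest AUC computed from the Mann-Whitney rank statistic with
#' midranks for ties: the probability that a random positive receives a
#' higher score than a random negative, counting ties as one half.
#'
#' @param scores numeric scores (higher = more positive).
#' @param positive logical (or 0/1) indicator of the positive class.
#' @return scalar AUC, or NA when either group is empty.
#' @export
auc_rank <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve coordinates for one class
#'
#' @param scores numeric scores of the positive class.
#' @param positive logical indicator.
#' @return data.frame with `threshold`, `fpr`, `tpr`, sorted from the
#'   most permissive to the strictest threshold.
#' @export
roc_curve <- function(scores, positive) {
  positive <- as.logical(positive)
  thr <- c(-Inf, sort(unique(scores)), Inf)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  tpr <- vapply(thr, function(t) sum(scores >= t & positive) /
                  max(n1, 1L), numeric(1L))
  fpr <- vapply(thr, function(t) sum(scores >= t & !positive) /
                  max(n0, 1L), numeric(1L))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Multi-class evaluation report
#'
#' Computes, from out-of-fold predictions, the headline multi-class
#' metrics: overall accuracy, macro-averaged precision, Cohen's kappa,
#' one-vs-rest AUC per class (from the class-probability scores, when
#' given), raw and row-normalized confusion matrices, the number of
#' correctly predicted cases, and the share of misclassified subjects
#' whose predicted class is adjacent (differs by one) to the true class in
#' the canonical trajectory ordering.
#'
#' @param truth integer true labels 1..K.
#' @param pred integer predicted labels 1..K.
#' @param probs optional N x K matrix of class probabilities (columns =
#'   classes); needed for the AUC entries.
#' @param n_classes number of classes K (default `max(truth, pred)`).
#' @return an object of class `"eval_report"`.
#' @export
evaluate_predictions <- function(truth, pred, probs = NULL,
                                 n_classes = max(c(truth, pred))) {
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  if (length(truth) != length(pred)) {
    stop("truth and pred must be aligned", call. = FALSE)
  }
  K <- as.integer(n_classes)
  N <- length(truth)
  conf <- matrix(0L, K, K,
                 dimnames = list(true = paste0("class", seq_len(K)),
                                 pred = paste0("class", seq_len(K))))
  for (i in seq_len(N)) conf[truth[i], pred[i]] <- conf[truth[i], pred[i]] + 1L

  n_correct <- sum(diag(conf))
  accuracy <- n_correct / N
  row_tot <- rowSums(conf)
  col_tot <- colSums(conf)
  conf_norm <- conf / ifelse(row_tot > 0, row_tot, 1)

  prec_k <- ifelse(col_tot > 0, diag(conf) / col_tot, NA_real_)
  precision <- mean(prec_k, na.rm = TRUE)

  pe <- sum(row_tot * col_tot) / N^2
  kappa <- if (pe >= 1) 0 else (accuracy - pe) / (1 - pe)

  auc <- rep(NA_real_, K)
  if (!is.null(probs)) {
    probs <- as.matrix(probs)
    for (k in seq_len(K)) auc[k] <- auc_rank(probs[, k], truth == k)
  }

  errors <- truth != pred
  adjacency <- if (any(errors)) {
    mean(abs(truth[errors] - pred[errors]) == 1L)
  } else NA_real_

  structure(list(accuracy = accuracy, precision = precision,
                 precision_by_class = prec_k, kappa = kappa, auc = auc,
                 confusion = conf, confusion_norm = conf_norm,
                 n_correct = n_correct, n = N,
                 adjacency_error_share = adjacency,
                 n_classes = K),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %d classes, n=%d: accuracy=%.3f precision=%.3f kappa=%.3f\n",
    x$n_classes, x$n, x$accuracy, x$precision, x$kappa))
  if (!all(is.na(x$auc))) {
    cat("per-class AUC:",
        paste(sprintf("%.3f", x$auc), collapse = " "), "\n")
  }
  if (!is.na(x$adjacency_error_share)) {
    cat(sprintf("share of errors between neighboring classes: %.2f\n",
                x$adjacency_error_share))
  }
  invisible(x)
}
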