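#' Classification metrics: accuracy and macro F1 / AUC-ROC / AUC-PR
#'
#' Accuracy is computed from the argmax prediction (lowest index on ties).
#' F1, AUC-ROC and AUC-PR are computed one-vs-rest per class and averaged
#' without class weighting (macro). AUCs are obtained by trapezoidal
#' integration of the ROC / precision-recall curve over all distinct score
#' thresholds; the resulting AUC-ROC equals the Mann-Whitney pair statistic.
#' Classes absent from `labels` are excluded from the macro averages with a
#' warning.
#'
#' @param probs N x K score matrix (rows on the simplex, or any monotone
#'   scores; column k scores class k).
#' @param labels Length-N integer vector of 1-based true classes.
#' @return A `fa_metrics` list: `accuracy`, `f1_macro`, `auc_roc_macro`,
#'   `auc_pr_macro`, `per_class` data frame, `n_test`.
#' @export
compute_metrics <- function(probs, labels) {
  probs <- as.matrix(probs)
  stopifnot(nrow(probs) == length(labels))
  K <- ncol(probs)
  pred <- max.col(probs, ties.method = "first")
  acc <- mean(pred == labels)
  present <- sort(unique(labels))
  absent <- setdiff(seq_len(K), present)
  if (length(absent) > 0)
    warning("classes absent from labels excluded from macro averages: ",
            paste(absent, collapse = ", "))
  per <- lapply(present, function(k) {
    y <- as.integer(labels == k)
    yhat <- as.integer(pred == k)
    tp <- sum(y == 1 & yhat == 1); fp <- sum(y == 0 & yhat == 1)
    fn <- sum(y == 1 & yhat == 0)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    data.frame(class = k, f1 = f1,
               auc_roc = auc_roc(probs[, k], y),
               auc_pr = auc_pr(probs[, k], y))
  })
  per <- do.call(rbind, per)
  structure(list(accuracy = acc,
                 f1_macro = mean(per$f1),
                 auc_roc_macro = mean(per$auc_roc),
                 auc_pr_macro = mean(per$auc_pr),
                 per_class = per,
                 n_test = length(labels)),
            class = "fa_metrics")
}

#' @export
print.fa_metrics <- function(x, ...) {
  cat(sprintf("n=%d  accuracy %.4f  F1(macro) %.4f  AUC-ROC(macro) %.4f  AUC-PR(macro) %.4f\n",
              x$n_test, x$accuracy, x$f1_macro, x$auc_roc_macro, x$auc_pr_macro))
  invisible(x)
}

#' ROC curve points for a binary score
#'
#' False/true positive rates at every distinct score threshold (descending),
#' starting at (0, 0) and ending at (1, 1). Tied scores move in one step.
#'
#' @param score Numeric scores (higher = more positive).
#' @param y 0/1 labels.
#' @return Data frame with `fpr`, `tpr`.
#' @export
roc_points <- function(score, y) {
  stopifnot(length(score) == length(y), all(y %in% c(0, 1)))
  P <- sum(y == 1); Ng <- sum(y == 0)
  if (P == 0 || Ng == 0) return(data.frame(fpr = c(0, 1), tpr = c(0, 1)))
  o <- order(score, decreasing = TRUE)
  s <- score[o]; yy <- y[o]
  tps <- cumsum(yy); fps <- cumsum(1 - yy)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tied block
  data.frame(fpr = c(0, fps[keep] / Ng), tpr = c(0, tps[keep] / P))
}

#' Precision-recall curve points for a binary score
#'
#' Precision and recall at every distinct score threshold (descending).
#' The curve is anchored at recall 0 with the precision of the first block.
#'
#' @inheritParams roc_points
#' @return Data frame with `recall`, `precision`.
#' @export
pr_points <- function(score, y) {
  stopifnot(length(score) == length(y), all(y %in% c(0, 1)))
  P <- sum(y == 1)
  if (P == 0) return(data.frame(recall = c(0, 1), precision = c(0, 0)))
  o <- order(score, decreasing = TRUE)
  yy <- y[o]; s <- score[o]
  tps <- cumsum(yy); k <- seq_along(yy)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  rec <- tps[keep] / P
  prec <- tps[keep] / k[keep]
  data.frame(recall = c(0, rec), precision = c(prec[1], prec))
}

auc_roc <- function(score, y) {
  pts <- roc_points(score, y)
  trapz_auc(pts$fpr, pts$tpr)
}

auc_pr <- function(score, y) {
  pts <- pr_points(score, y)
  trapz_auc(pts$recall, pts$precision)
}

trapz_auc <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
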