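#' Confusion counts for binary per-residue predictions
#'
#' @param y_true Binary 0/1 vector of observed turn labels.
#' @param y_pred Binary 0/1 vector of predicted labels, same length.
#' @return A \code{confusion_counts} list with TP, TN, FP, FN.
#' @export
confusion_counts <- function(y_true, y_pred) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred))
    stop("confusion_counts: length mismatch (", length(y_true), " vs ",
         length(y_pred), ")")
  if (!all(y_true %in% c(0L, 1L)) || !all(y_pred %in% c(0L, 1L)))
    stop("confusion_counts: labels must be 0/1")
  structure(
    list(TP = sum(y_true == 1L & y_pred == 1L),
         TN = sum(y_true == 0L & y_pred == 0L),
         FP = sum(y_true == 0L & y_pred == 1L),
         FN = sum(y_true == 1L & y_pred == 0L)),
    class = "confusion_counts")
}

#' Prediction-quality measures from confusion counts
#'
#' Computes the four standard beta-turn prediction measures:
#' Qtotal = 100 (TP+TN)/(TP+TN+FP+FN) (accuracy),
#' Qpredicted = 100 TP/(TP+FP) (positive predictive value),
#' Qobserved = 100 TP/(TP+FN) (sensitivity/coverage), and the Matthews
#' correlation coefficient
#' MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' A measure whose denominator is zero is reported as 0 and named in the
#' \code{flags} attribute.
#'
#' @param counts A \code{\link{confusion_counts}} object (or list with TP,
#'   TN, FP, FN).
#' @return List with Qtotal, Qpredicted, Qobserved (percentages), MCC, and
#'   a \code{flags} character vector of zero-denominator measures.
#' @export
compute_metrics <- function(counts) {
  TP <- as.numeric(counts$TP); TN <- as.numeric(counts$TN)
  FP <- as.numeric(counts$FP); FN <- as.numeric(counts$FN)
  if (any(c(TP, TN, FP, FN) < 0)) stop("compute_metrics: negative counts")
  total <- TP + TN + FP + FN
  if (total == 0) stop("compute_metrics: all counts are zero")
  flags <- character(0)
  q_tot <- 100 * (TP + TN) / total
  if (TP + FP > 0) q_pred <- 100 * TP / (TP + FP)
  else { q_pred <- 0; flags <- c(flags, "Qpredicted") }
  if (TP + FN > 0) q_obs <- 100 * TP / (TP + FN)
  else { q_obs <- 0; flags <- c(flags, "Qobserved") }
  denom2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (denom2 > 0) mcc <- (TP * TN - FP * FN) / sqrt(denom2)
  else { mcc <- 0; flags <- c(flags, "MCC") }
  list(Qtotal = q_tot, Qpredicted = q_pred, Qobserved = q_obs, MCC = mcc,
       flags = flags)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every distinct score as a threshold (ties grouped), returning the
#' (FPR, TPR) points and the trapezoid-rule area, which equals the
#' Mann-Whitney probability that a random positive outscores a random
#' negative (ties counted half).
#'
#' @param y_true Binary 0/1 vector; both classes must be present.
#' @param scores Real-valued scores, higher = more turn-like.
#' @return List with \code{roc} (data frame: threshold, FPR, TPR) and
#'   \code{auc}.
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(scores)) stop("roc_auc: length mismatch")
  n_pos <- sum(y_true == 1L)
  n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("roc_auc: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- y_true[ord]
  # collapse tied scores into single threshold steps
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(1L - y)[last_of_group]
  roc <- data.frame(threshold = c(Inf, s[last_of_group]),
                    FPR = c(0, fp / n_neg),
                    TPR = c(0, tp / n_pos))
  auc <- sum(diff(roc$FPR) * (roc$TPR[-1] + roc$TPR[-nrow(roc)]) / 2)
  list(roc = roc, auc = auc)
}
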