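#' Classification metric suite
#'
#' Computes AUC (rank / Mann-Whitney formulation, ties handled by midranks),
#' confusion matrix at a score threshold, precision, recall (TPR), F1 and
#' accuracy for binary labels against real-valued scores. Matrix inputs
#' (multi-label tasks) are micro-averaged: both arguments are flattened
#' before any metric is computed.
#'
#' If only one class is present the AUC is undefined: it is returned as `NA`
#' with a warning; the threshold metrics are still computed.
#'
#' @param y_true binary labels (vector or matrix in `{0,1}`).
#' @param y_score real scores, same shape as `y_true`.
#' @param threshold score cut for the confusion matrix, default 0.5.
#' @return list: `auc`, `confusion` (2x2 matrix), `precision`, `recall`,
#'   `tpr` (= recall), `f1`, `accuracy`, `n`.
#' @examples
#' evaluate_scores(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))$auc  # 0.75
#' @export
evaluate_scores <- function(y_true, y_score, threshold = 0.5) {
  y_true <- as.numeric(y_true)
  y_score <- as.numeric(y_score)
  if (length(y_true) != length(y_score)) {
    stop("evaluate_scores: y_true and y_score must have equal length", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1))) {
    stop("evaluate_scores: y_true must be binary (0/1)", call. = FALSE)
  }
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  auc <- if (n_pos == 0 || n_neg == 0) {
    warning("evaluate_scores: AUC undefined (single-class y_true)", call. = FALSE)
    NA_real_
  } else {
    # Mann-Whitney: AUC = (R_pos - n_pos(n_pos+1)/2) / (n_pos * n_neg)
    r <- rank(y_score, ties.method = "average")
    (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  pred <- as.numeric(y_score >= threshold)
  tp <- sum(pred == 1 & y_true == 1)
  fp <- sum(pred == 1 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1)
  tn <- sum(pred == 0 & y_true == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(
    auc = auc,
    confusion = matrix(c(tn, fp, fn, tp), 2L, 2L,
                       dimnames = list(truth = c("0", "1"), predicted = c("0", "1"))),
    precision = precision,
    recall = recall,
    tpr = recall,
    f1 = f1,
    accuracy = (tp + tn) / length(y_true),
    n = length(y_true)
  )
}

#' ROC and precision-recall curve points
#'
#' Curve points at every distinct score cut, suitable for plotting or CSV
#' export.
#'
#' @inheritParams evaluate_scores
#' @return data.frame with columns `threshold`, `fpr`, `tpr`, `precision`,
#'   `recall`.
#' @export
curve_points <- function(y_true, y_score) {
  y_true <- as.numeric(y_true)
  ord <- order(y_score, decreasing = TRUE)
  y <- y_true[ord]
  s <- y_score[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  keep <- c(diff(s) != 0, TRUE)  # last point per distinct threshold
  n_pos <- sum(y)
  n_neg <- length(y) - n_pos
  data.frame(
    threshold = s[keep],
    fpr = if (n_neg > 0) fp[keep] / n_neg else NA_real_,
    tpr = if (n_pos > 0) tp[keep] / n_pos else NA_real_,
    precision = tp[keep] / pmax(tp[keep] + fp[keep], 1),
    recall = if (n_pos > 0) tp[keep] / n_pos else NA_real_
  )
}

#' Inject label noise by permuting whole label vectors
#'
#' Selects `round(fraction * n)` sample rows without replacement (seeded)
#' and randomly permutes their label vectors *among themselves*; every other
#' row is untouched. This preserves the multiset of label vectors while
#' destroying the feature-label pairing for the selected rows. An
#' alternative per-entry flipping mode is available.
#'
#' @param labels binary label matrix (n x g) or vector.
#' @param fraction proportion of rows to corrupt, in `[0, 1]`.
#' @param seed integer seed.
#' @param mode `"permute"` (default; shuffle selected rows among themselves)
#'   or `"flip"` (flip each entry of the selected rows).
#' @return labels of the same shape with noise applied.
#' @export
inject_label_noise <- function(labels, fraction, seed = 1L,
                               mode = c("permute", "flip")) {
  mode <- match.arg(mode)
  fraction <- check_proportion(fraction, "fraction")
  vec <- is.null(dim(labels))
  m <- if (vec) matrix(labels, ncol = 1L) else as.matrix(labels)
  n <- nrow(m)
  k <- round(fraction * n)
  if (k > 0L) {
    with_seed(seed, {
      rows <- sample.int(n, k)
      if (mode == "permute") {
        m[rows, ] <- m[rows[sample.int(k)], , drop = FALSE]
      } else {
        m[rows, ] <- 1 - m[rows, , drop = FALSE]
      }
    })
  }
  if (vec) as.vector(m) else m
}
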