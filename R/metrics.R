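# Classification metrics over masked multi-label scores.

# rank-based AUC; ties between a positive and a negative count 1/2
auc_rank <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# average precision: sum over distinct score thresholds of
# (recall step) * (precision at that threshold), highest scores first
average_precision <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- c(s[-1] != s[-length(s)], TRUE)   # block ends of tied scores
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  recall <- tp / n1
  sum(diff(c(0, recall)) * prec)
}

#' Evaluate masked multi-label scores
#'
#' Per head coordinate: accuracy at the probability threshold, balanced
#' accuracy, rank AUC (ties counted one half), average precision, and (in
#' regression mode) mean squared error — all computed only over observed
#' entries. Heads with a single observed class get `NA` for AUC and average
#' precision rather than an error.
#'
#' @param scores `n x l` score matrix (probabilities, or continuous
#'   predictions in regression mode).
#' @param labels `n x l` label matrix (`NA` = unobserved).
#' @param threshold probability threshold for accuracy (default 0.5).
#' @param regression if `TRUE` compute MSE instead of the classification
#'   metrics.
#' @return data frame with one row per head coordinate.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5,
                            regression = FALSE) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  if (!all(dim(scores) == dim(labels)))
    stop_panfc("scores and labels must have matching dimensions")
  out <- lapply(seq_len(ncol(scores)), function(j) {
    obs <- !is.na(labels[, j])
    s <- scores[obs, j]; y <- labels[obs, j]
    if (length(y) == 0)
      return(data.frame(head = j, n_obs = 0L, accuracy = NA_real_,
                        balanced_accuracy = NA_real_, auc = NA_real_,
                        average_precision = NA_real_, mse = NA_real_))
    if (regression) {
      return(data.frame(head = j, n_obs = length(y), accuracy = NA_real_,
                        balanced_accuracy = NA_real_, auc = NA_real_,
                        average_precision = NA_real_,
                        mse = mean((s - y)^2)))
    }
    pred <- as.integer(s >= threshold)
    acc <- mean(pred == y)
    sens <- if (any(y == 1)) mean(pred[y == 1] == 1) else NA_real_
    spec <- if (any(y == 0)) mean(pred[y == 0] == 0) else NA_real_
    data.frame(head = j, n_obs = length(y), accuracy = acc,
               balanced_accuracy = mean(c(sens, spec)),
               auc = auc_rank(s, y),
               average_precision = average_precision(s, y),
               mse = NA_real_)
  })
  res <- do.call(rbind, out)
  cn <- colnames(labels)
  res$head <- if (!is.null(cn)) cn else as.character(res$head)
  res
}
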