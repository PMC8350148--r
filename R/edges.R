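# Edge-wise group discrimination: per-pair two-sample t-tests on the
# (symmetrized) updated connectivity entries, Benjamini-Hochberg corrected.

#' Collect symmetrized connectivity edges per subject
#'
#' Runs the fitted model on each subject and extracts the upper triangle of
#' the symmetrized updated connectivity matrix, `(k'_ij + k'_ji) / 2` for
#' every unordered pair `i < j` (the learned matrix is asymmetric in
#' general; the diagonal is excluded). With the `no_reweighting` ablation
#' the first matrix K is used.
#'
#' @param fit a fitted `"panfc"` model.
#' @param data dataset of subjects.
#' @param subset optional subject ids.
#' @return `n x (N(N-1)/2)` matrix, one row per subject, with attributes
#'   `pairs` (two-column index matrix) and `region_names`.
#' @export
collect_edges <- function(fit, data, subset = NULL) {
  if (!inherits(fit, "panfc")) stop_panfc("'fit' must be a fitted panfc model")
  mats <- predict(fit, data, type = "connectivity", subset = subset)
  N <- fit$config$n_regions
  ut <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]  # (i, j), i < j
  edges <- t(vapply(mats, function(K) {
    S <- (K + t(K)) / 2
    S[cbind(ut[, 1L], ut[, 2L])]
  }, numeric(nrow(ut))))
  rownames(edges) <- names(mats)
  colnames(edges) <- paste0("e", ut[, 1L], "_", ut[, 2L])
  attr(edges, "pairs") <- unname(ut)
  attr(edges, "region_names") <- fit$region_names
  edges
}

#' Edge-wise two-sample t-tests with FDR correction
#'
#' For each unordered region pair, a two-sample t-test compares connectivity
#' between the two groups (equal-variance pooled t by default, matching the
#' plain independent-samples test; Welch optional). Raw p-values are
#' adjusted across all pairs with the Benjamini-Hochberg step-up procedure
#' and flagged at level `alpha`. Pairs whose pooled variance is exactly zero
#' get `t = 0`, `p = 1` with a warning.
#'
#' @param edges edge matrix from [collect_edges()] (or any `n x P` matrix;
#'   pair indices are then taken from its attributes when present).
#' @param group length-n 0/1 (or logical/factor) group indicator; both
#'   groups need at least 2 subjects. Subjects with `NA` are dropped.
#' @param alpha significance level after adjustment (default 0.05).
#' @param var_equal pooled-variance t (default) or Welch.
#' @return data frame sorted by adjusted p: pair indices and region names,
#'   group mean difference, `t`, `df`, `p`, `p_adj`, `significant`.
#' @export
edge_ttests <- function(edges, group, alpha = 0.05, var_equal = TRUE) {
  edges <- as.matrix(edges)
  if (length(group) != nrow(edges))
    stop_panfc("'group' must have one entry per subject row")
  g <- as.integer(as.factor(group)) - 1L
  keep <- !is.na(g)
  edges_k <- edges[keep, , drop = FALSE]
  g <- g[keep]
  n1 <- sum(g == 1L); n0 <- sum(g == 0L)
  if (n1 < 2L || n0 < 2L)
    stop_panfc("both groups need at least 2 subjects")

  m1 <- colMeans(edges_k[g == 1L, , drop = FALSE])
  m0 <- colMeans(edges_k[g == 0L, , drop = FALSE])
  v1 <- apply(edges_k[g == 1L, , drop = FALSE], 2L, stats::var)
  v0 <- apply(edges_k[g == 0L, , drop = FALSE], 2L, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  degen <- !is.finite(se) | se < 1e-300
  if (any(degen))
    warning(sprintf("%d pair(s) have zero variance in both groups; p set to 1",
                    sum(degen)))
  tstat <- ifelse(degen, 0, (m1 - m0) / se)
  p <- ifelse(degen, 1, 2 * stats::pt(-abs(tstat), df))
  p_adj <- stats::p.adjust(p, method = "BH")

  pairs <- attr(edges, "pairs")
  rn <- attr(edges, "region_names")
  if (is.null(pairs)) pairs <- cbind(seq_len(ncol(edges)), NA_integer_)
  out <- data.frame(
    region_i = pairs[, 1L], region_j = pairs[, 2L],
    name_i = if (!is.null(rn)) rn[pairs[, 1L]] else NA_character_,
    name_j = if (!is.null(rn)) rn[pairs[, 2L]] else NA_character_,
    mean_diff = m1 - m0, t = tstat, df = df, p = p, p_adj = p_adj,
    significant = p_adj <= alpha,
    stringsAsFactors = FALSE)
  out[order(out$p_adj, out$p), ]
}
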