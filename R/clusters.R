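# DSM-5 symptom-cluster utilities: cluster mapping, dominant-cluster
# computation, hidden-feature extraction and 2-D embedding.

#' DSM-5 PTSD cluster criteria
#'
#' The 20 symptoms partition into Intrusion (B, symptoms 1-5), Avoidance
#' (C, 6-7), Negative alterations in mood and cognition (D, 8-14) and
#' Hyperarousal (E, 15-20). A cluster is met with at least 1 (B, C) or at
#' least 2 (D, E) of its symptoms.
#'
#' @return data frame with columns `cluster`, `from`, `to`, `min_count`.
#' @export
cluster_criteria <- function() {
  data.frame(cluster = c("B", "C", "D", "E"),
             from = c(1L, 6L, 8L, 15L),
             to = c(5L, 7L, 14L, 20L),
             min_count = c(1L, 1L, 2L, 2L),
             stringsAsFactors = FALSE)
}

#' Map 20-bit symptom vectors to the four DSM-5 clusters
#'
#' Applies the per-cluster minimum-count rule: B and C are met with at least
#' one of their symptoms, D and E with at least two.
#'
#' @param symptoms a length-20 0/1 vector, or an `n x 20` matrix of them
#'   (columns in the order B1-B5, C1-C2, D1-D7, E1-E6). `NA` rows give `NA`
#'   clusters.
#' @return length-4 0/1 vector named B, C, D, E (or an `n x 4` matrix).
#' @export
symptoms_to_clusters <- function(symptoms) {
  vec_in <- is.vector(symptoms)
  m <- if (vec_in) matrix(symptoms, nrow = 1L) else as.matrix(symptoms)
  if (ncol(m) != 20L)
    stop_panfc("symptom vectors must have exactly 20 entries")
  if (any(!is.na(m) & !(m %in% c(0, 1))))
    stop_panfc("symptom values must be 0/1 (or NA)")
  crit <- cluster_criteria()
  out <- sapply(seq_len(nrow(crit)), function(q) {
    cnt <- rowSums(m[, crit$from[q]:crit$to[q], drop = FALSE])
    as.integer(cnt >= crit$min_count[q])
  })
  out <- matrix(out, ncol = 4L, dimnames = list(rownames(m), crit$cluster))
  if (vec_in) out[1L, ] else out
}

#' Dominant symptom cluster per subject
#'
#' For every subject: the four cluster scores (fraction of the cluster's
#' symptoms met), each score's mid-rank percentile within the cohort's
#' distribution for that cluster, and the dominant cluster — the cluster
#' with the highest percentile, provided it exceeds the runner-up by more
#' than `margin` percentile points (default 0: a strict unique maximum);
#' otherwise none (`NA`).
#'
#' @param symptoms `n x 20` 0/1 matrix of symptom bits (n >= 2). Subjects
#'   with any `NA` get `NA` results.
#' @param margin minimum percentile lead of the top cluster over the
#'   runner-up (default 0, i.e. strict uniqueness).
#' @return data frame with per-cluster `score_*` and `pct_*` columns and a
#'   `dominant` factor (levels B, C, D, E; `NA` = none).
#' @export
dominant_cluster <- function(symptoms, margin = 0) {
  m <- as.matrix(symptoms)
  if (ncol(m) != 20L) stop_panfc("need an n x 20 symptom matrix")
  if (nrow(m) < 2L) stop_panfc("need at least 2 subjects")
  crit <- cluster_criteria()
  scores <- sapply(seq_len(nrow(crit)), function(q) {
    rowMeans(m[, crit$from[q]:crit$to[q], drop = FALSE])
  })
  colnames(scores) <- crit$cluster
  ok <- stats::complete.cases(scores)
  pct <- matrix(NA_real_, nrow(m), 4L, dimnames = list(NULL, crit$cluster))
  for (q in 1:4) {
    x <- scores[ok, q]
    # mid-rank percentile: average of P(< x) and P(<= x), ties deterministic
    pct[ok, q] <- 100 * (rank(x, ties.method = "average") - 0.5) / length(x)
  }
  dominant <- rep(NA_character_, nrow(m))
  for (s in which(ok)) {
    o <- order(pct[s, ], decreasing = TRUE)
    if (pct[s, o[1L]] > pct[s, o[2L]] + margin)
      dominant[s] <- crit$cluster[o[1L]]
  }
  out <- data.frame(scores, pct, dominant = factor(dominant,
                                                   levels = crit$cluster))
  names(out) <- c(paste0("score_", crit$cluster), paste0("pct_", crit$cluster),
                  "dominant")
  rownames(out) <- rownames(m)
  out
}

#' Extract the classifier's 100-dimensional features
#'
#' Returns, for every subject, the activation of the classifier's first
#' linear layer (the feature map read from the updated connectivity matrix),
#' used for the 2-D cohort visualisation.
#'
#' @param fit a fitted `"panfc"` model.
#' @param data dataset to extract from.
#' @param subset optional subject ids.
#' @return `n x c_hidden[1]` matrix (100 columns under the default
#'   architecture), rownames = subject ids.
#' @export
extract_hidden_features <- function(fit, data, subset = NULL) {
  if (!inherits(fit, "panfc")) stop_panfc("'fit' must be a fitted panfc model")
  predict(fit, data, type = "hidden", subset = subset)
}

#' Two-dimensional embedding of feature vectors (exact t-SNE)
#'
#' Embeds each row of a feature matrix into two dimensions with exact
#' t-distributed stochastic neighbour embedding: Gaussian input affinities
#' calibrated per point to the target perplexity, Student-t output
#' affinities, gradient descent with momentum and early exaggeration.
#' Initialisation is the first two principal components (deterministic, so
#' duplicated feature rows stay coincident); `init = "random"` draws a
#' seeded Gaussian start instead.
#'
#' @param features numeric `n x p` matrix.
#' @param seed integer seed (used by the optimiser only through the random
#'   initialisation, if selected).
#' @param perplexity effective neighbour count; capped at `(n - 1) / 3`.
#' @param n_iter gradient-descent iterations (default 400).
#' @param init `"pca"` (default) or `"random"`.
#' @return `n x 2` coordinate matrix.
#' @export
embed_2d <- function(features, seed = 1L, perplexity = 30, n_iter = 400L,
                     init = c("pca", "random")) {
  init <- match.arg(init)
  Xfull <- as.matrix(features)
  # identical feature rows embed to one shared point (exactly coincident)
  key <- apply(Xfull, 1L, paste, collapse = "\r")
  uniq <- !duplicated(key)
  X <- Xfull[uniq, , drop = FALSE]
  expand <- match(key, key[uniq])
  n <- nrow(X)
  if (n < 4L) stop_panfc("need at least 4 distinct points to embed")
  perplexity <- min(perplexity, (n - 1) / 3)

  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sump <- sum(p)
      if (sump < 1e-300) { H <- 0 } else {
        p <- p / sump
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12

  Y <- if (init == "pca") {
    pc <- stats::prcomp(X, rank. = 2L)$x
    if (ncol(pc) < 2L) pc <- cbind(pc, 0)
    pc / max(1e-12, stats::sd(pc[, 1L])) * 1e-2
  } else {
    with_seed(seed, matrix(stats::rnorm(n * 2L, sd = 1e-2), n, 2L))
  }

  G <- matrix(0, n, 2L)
  gains <- matrix(1, n, 2L)
  update <- matrix(0, n, 2L)
  for (iter in seq_len(n_iter)) {
    exag <- if (iter <= 100L) 4 else 1
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < 1e-12] <- 1e-12
    L <- (exag * P - Q) * num
    G <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(G) != sign(update), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    momentum <- if (iter <= 250L) 0.5 else 0.8
    update <- momentum * update - 200 * gains * G
    Y <- Y + update
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y <- Y[expand, , drop = FALSE]
  rownames(Y) <- rownames(Xfull)
  colnames(Y) <- c("dim1", "dim2")
  Y
}

#' Plot the 2-D feature embedding coloured by dominant cluster
#'
#' Scatter of [embed_2d()] coordinates; subjects without a dominant cluster
#' are skipped (not drawn).
#'
#' @param coords `n x 2` coordinates.
#' @param dominant factor of dominant clusters (`NA` = none), as returned by
#'   [dominant_cluster()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_embedding <- function(coords, dominant, ...) {
  keep <- !is.na(dominant)
  cols <- c(B = "#1b9e77", C = "#d95f02", D = "#7570b3", E = "#e7298a")
  graphics::plot(coords[keep, 1L], coords[keep, 2L],
                 col = cols[as.character(dominant[keep])], pch = 19,
                 xlab = "dim 1", ylab = "dim 2", ...)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 19,
                   bty = "n")
  invisible(NULL)
}

#' Build the persistence (survival) prediction task
#'
#' Selects subjects diagnosed at the first time-point whose third-time-point
#' diagnosis is observed; the binary label is whether the diagnosis is still
#' met at the third time-point (chronic course). These labels feed the
#' single-logit survival head.
#'
#' @param data a [panfc_dataset()] or cohort.
#' @return list with `dataset` (the eligible subset, `persists_t3` filled),
#'   `subject_ids` and `labels` (named 0/1 vector).
#' @export
build_survival_task <- function(data) {
  dataset <- as_panfc_dataset(data)
  lab <- dataset$labels
  eligible <- !is.na(lab$dx_t1) & lab$dx_t1 == 1L & !is.na(lab$dx_t3)
  if (!any(eligible))
    stop_panfc("no subjects diagnosed at t1 with an observed t3 diagnosis")
  ids <- lab$subject_id[eligible]
  y <- lab$dx_t3[eligible]
  names(y) <- ids
  sub <- dataset
  sub$subjects <- dataset$subjects[ids]
  sub$labels <- lab[eligible, , drop = FALSE]
  sub$labels$persists_t3 <- y
  sub$subject_ids <- ids
  rownames(sub$labels) <- NULL
  list(dataset = sub, subject_ids = ids, labels = y)
}
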