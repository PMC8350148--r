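# Network forward pass.
#
# Pair ordering convention used throughout: for one subject the N^2 ordered
# pairs are enumerated with the SECOND index fastest, r = (i - 1) * N + j,
# i.e. row-major order of the connectivity matrix K[i, j]. The classifier
# reads the matrix flattened in this same order (diagonal included).

panfc_init_params <- function(config, seed = NULL) {
  gain <- function(par, g) {
    if (g == 1) par else list(W = par$W * g, b = par$b * g)
  }
  init <- function() {
    params <- list()
    if (!config$identity_E) {
      cf <- config$conv_filters
      k <- config$kernel_size
      gE <- config$init_gain_E %||% 1
      E <- list()
      c_in <- 1L
      len <- config$n_timepoints
      for (layer in 1:6) {
        E[[paste0("conv", layer)]] <- gain(nn_conv_init(c_in, cf[layer], k), gE)
        c_in <- cf[layer]
        if (layer %in% config$pool_after) len <- len %/% 2L
      }
      E$fc <- gain(nn_linear_init(cf[6] * len, config$embed_dim), gE)
      params$E <- E
    }
    if (!config$pearson_F) {
      d <- config$embed_dim
      d2 <- 2L * d
      gF <- config$init_gain_F %||% 1
      l1 <- gain(nn_linear_init(d2, config$f_hidden[1]), gF)
      l2 <- gain(nn_linear_init(config$f_hidden[1], config$f_hidden[2]), gF)
      if (isTRUE(config$similarity_init)) {
        # difference-kernel initialisation: every first-layer unit reads a
        # projection of (e_i - e_j) and the second layer pools them with
        # nonnegative weights, so the initial score is a monotone function
        # of the pair's embedding distance — a similarity measure from the
        # first training step (subsequent steps are free to reshape it)
        l1$W[d + seq_len(d), ] <- -l1$W[seq_len(d), , drop = FALSE]
        l2$W <- abs(l2$W)
      }
      params$F <- list(
        l1 = l1,
        l2 = l2,
        l3 = gain(nn_linear_init(config$f_hidden[2], 1L), gF))
    }
    params$C <- list(
      l1 = nn_linear_init(config$n_regions^2, config$c_hidden[1]),
      l2 = nn_linear_init(config$c_hidden[1], config$c_hidden[2]),
      l3 = nn_linear_init(config$c_hidden[2], config$head_size))
    params
  }
  if (is.null(seed)) init() else with_seed(seed, init())
}

# ---- extractor E -----------------------------------------------------------

# Xb: (n_series x T) matrix, one row per region series (possibly several
# subjects stacked). Returns (n_series x d) embeddings.
e_forward <- function(params, Xb, config, train = FALSE) {
  if (config$identity_E) return(list(emb = Xb, cache = NULL))
  nB <- nrow(Xb)
  k <- config$kernel_size
  pad <- (k - 1L) %/% 2L
  A <- array(t(Xb), c(1L, ncol(Xb), nB))
  caches <- vector("list", 6L)
  for (layer in 1:6) {
    cv <- nn_conv_fwd(A, params$E[[paste0("conv", layer)]], k, pad)
    rl <- nn_relu_fwd(cv$out)
    st <- list(conv = cv, relu = rl, pooled = layer %in% config$pool_after)
    A <- rl$out
    if (st$pooled) {
      pl <- nn_pool_fwd(A)
      st$pool <- pl
      A <- pl$out
    }
    if (!train) st$conv$A <- NULL   # drop input buffers outside training
    caches[[layer]] <- st
  }
  d <- dim(A)
  feat <- matrix(A, d[1L] * d[2L], d[3L])        # (C*L) x n_series
  fc <- nn_linear_fwd(t(feat), params$E$fc)
  list(emb = fc$out,
       cache = if (train) list(layers = caches, fc = fc, featdim = d) else NULL)
}

e_backward <- function(params, cache, demb, config) {
  k <- config$kernel_size
  pad <- (k - 1L) %/% 2L
  grads <- list()
  fcb <- nn_linear_bwd(demb, params$E$fc, cache$fc)
  grads$fc <- list(W = fcb$dW, b = fcb$db)
  dA <- array(t(fcb$dX), cache$featdim)
  for (layer in 6:1) {
    st <- cache$layers[[layer]]
    if (st$pooled) dA <- nn_pool_bwd(dA, st$pool)
    dA <- nn_relu_bwd(dA, st$relu)
    cvb <- nn_conv_bwd(dA, params$E[[paste0("conv", layer)]], st$conv, k, pad)
    grads[[paste0("conv", layer)]] <- list(W = cvb$dW, b = cvb$db)
    dA <- cvb$dA
  }
  grads[c(paste0("conv", 1:6), "fc")]
}

# ---- similarity network F --------------------------------------------------

# U: (n_pairs x 2d) concatenated embedding pairs -> sigmoid scores in (0, 1)
f_forward <- function(params, U, train = FALSE) {
  l1 <- nn_linear_fwd(U, params$F$l1); r1 <- nn_relu_fwd(l1$out)
  l2 <- nn_linear_fwd(r1$out, params$F$l2); r2 <- nn_relu_fwd(l2$out)
  l3 <- nn_linear_fwd(r2$out, params$F$l3)
  s <- nn_sigmoid(drop(l3$out))
  list(s = s,
       cache = if (train) list(l1 = l1, r1 = r1, l2 = l2, r2 = r2, l3 = l3,
                               s = s) else NULL)
}

f_backward <- function(params, cache, ds) {
  dz <- matrix(ds * cache$s * (1 - cache$s), ncol = 1L)
  b3 <- nn_linear_bwd(dz, params$F$l3, cache$l3)
  d2 <- nn_relu_bwd(b3$dX, cache$r2)
  b2 <- nn_linear_bwd(d2, params$F$l2, cache$l2)
  d1 <- nn_relu_bwd(b2$dX, cache$r1)
  b1 <- nn_linear_bwd(d1, params$F$l1, cache$l1)
  list(dU = b1$dX,
       grads = list(l1 = list(W = b1$dW, b = b1$db),
                    l2 = list(W = b2$dW, b = b2$db),
                    l3 = list(W = b3$dW, b = b3$db)))
}

# ---- Pearson-correlation replacement for F (ablation) ----------------------

# row-standardize embeddings; rows with zero variance correlate as 0
pearson_standardize <- function(emb) {
  V <- emb - rowMeans(emb)
  ss <- sqrt(rowSums(V * V))
  degen <- ss < 1e-12
  ssafe <- ifelse(degen, 1, ss)
  list(Z = V / ssafe, ss = ssafe, degen = degen)
}

pearson_scores <- function(emb, ii, jj, train = FALSE) {
  if (ncol(emb) < 2L)
    stop_panfc("Pearson similarity needs embeddings of dimension >= 2")
  st <- pearson_standardize(emb)
  Z <- st$Z
  Z[st$degen, ] <- 0
  s <- rowSums(Z[ii, , drop = FALSE] * Z[jj, , drop = FALSE])
  list(s = s, cache = if (train) list(Z = Z, st = st, ii = ii, jj = jj))
}

pearson_backward <- function(emb, cache, ds) {
  Z <- cache$Z
  dZ <- rowsum(ds * Z[cache$jj, , drop = FALSE], cache$ii) +
        rowsum(ds * Z[cache$ii, , drop = FALSE], cache$jj)
  # back through v -> v / ||v||, then through centering
  proj <- rowSums(Z * dZ)
  dV <- (dZ - Z * proj) / cache$st$ss
  dV[cache$st$degen, ] <- 0
  dV - rowMeans(dV)
}

# ---- classifier C ----------------------------------------------------------

c_forward <- function(params, Cin, config, train = FALSE) {
  l1 <- nn_linear_fwd(Cin, params$C$l1); r1 <- nn_relu_fwd(l1$out)
  dp1 <- nn_dropout_fwd(r1$out, if (train) config$dropout else 0)
  l2 <- nn_linear_fwd(dp1$out, params$C$l2); r2 <- nn_relu_fwd(l2$out)
  dp2 <- nn_dropout_fwd(r2$out, if (train) config$dropout else 0)
  l3 <- nn_linear_fwd(dp2$out, params$C$l3)
  list(logits = l3$out, hidden = r1$out,
       cache = if (train) list(l1 = l1, r1 = r1, dp1 = dp1, l2 = l2, r2 = r2,
                               dp2 = dp2, l3 = l3) else NULL)
}

c_backward <- function(params, cache, dlogits) {
  b3 <- nn_linear_bwd(dlogits, params$C$l3, cache$l3)
  d2 <- nn_relu_bwd(nn_dropout_bwd(b3$dX, cache$dp2), cache$r2)
  b2 <- nn_linear_bwd(d2, params$C$l2, cache$l2)
  d1 <- nn_relu_bwd(nn_dropout_bwd(b2$dX, cache$dp1), cache$r1)
  b1 <- nn_linear_bwd(d1, params$C$l1, cache$l1)
  list(dCin = b1$dX,
       grads = list(l1 = list(W = b1$dW, b = b1$db),
                    l2 = list(W = b2$dW, b = b2$db),
                    l3 = list(W = b3$dW, b = b3$db)))
}

# ---- full batched forward --------------------------------------------------

# Xb: (B*N x T), B subjects stacked; returns scores, weights and (in training)
# all caches needed for the backward pass
model_forward_batch <- function(params, Xb, B, config, train = FALSE,
                                cache_upstream = train) {
  N <- config$n_regions
  d <- config$embed_dim
  ef <- e_forward(params, Xb, config, train = train && cache_upstream)
  emb <- ef$emb

  i_loc <- rep(seq_len(N), each = N)
  j_loc <- rep(seq_len(N), times = N)
  offs <- rep((seq_len(B) - 1L) * N, each = N * N)
  ii <- offs + rep(i_loc, times = B)
  jj <- offs + rep(j_loc, times = B)

  up <- train && cache_upstream
  if (config$pearson_F) {
    p1 <- pearson_scores(emb, ii, jj, train = up)
    s1 <- p1$s; f1 <- p1
  } else {
    U1 <- cbind(emb[ii, , drop = FALSE], emb[jj, , drop = FALSE])
    f1 <- f_forward(params, U1, train = up)
    s1 <- f1$s
  }

  out <- list(emb = emb, s1 = s1, ii = ii, jj = jj, B = B,
              e_cache = ef$cache, f1 = if (up) f1,
              cache_upstream = cache_upstream)

  if (!config$no_reweighting) {
    Karr <- array(s1, c(N, N, B))              # Karr[j, i, b] = k_ij
    cs <- colSums(Karr)                         # (N x B): sum over j incl diag
    dg <- matrix(Karr[cbind(rep(seq_len(N), B), rep(seq_len(N), B),
                            rep(seq_len(B), each = N))], N, B)
    w <- config$beta + (1 - config$beta) * (cs - dg)   # (N x B)
    wvec <- as.vector(w)
    emb2 <- emb * wvec
    if (config$pearson_F) {
      p2 <- pearson_scores(emb2, ii, jj, train = up)
      s2 <- p2$s; f2 <- p2
    } else {
      U2 <- cbind(emb2[ii, , drop = FALSE], emb2[jj, , drop = FALSE])
      f2 <- f_forward(params, U2, train = up)
      s2 <- f2$s
    }
    out$w <- w; out$s2 <- s2
    out$emb2 <- emb2
    out$f2 <- if (up) f2
    class_in <- s2
  } else {
    class_in <- s1
  }

  Cin <- t(matrix(class_in, N * N, B))
  cf <- c_forward(params, Cin, config, train = train)
  out$Cin <- Cin
  out$logits <- cf$logits
  out$hidden <- cf$hidden
  out$c2 <- if (train) cf$cache
  out
}

# Backward pass. dlogits2 is the gradient w.r.t. the logits of the classifier
# applied to the updated matrix K' (already scaled by its loss weight);
# dlogits1 w.r.t. the K-path logits. Either may be NULL (zero). Returns
# gradients in the same nested shape as `params`.
model_backward_batch <- function(params, fwd, config,
                                 dlogits1 = NULL, dlogits2 = NULL,
                                 c1_cache = NULL) {
  N <- config$n_regions
  d <- config$embed_dim
  B <- fwd$B
  ii <- fwd$ii; jj <- fwd$jj
  grads <- par_zeros(params)
  demb <- matrix(0, nrow(fwd$emb), d)
  ds1 <- numeric(N * N * B)

  split_dU <- function(dU) {
    rowsum(dU[, seq_len(d), drop = FALSE], ii) +
      rowsum(dU[, d + seq_len(d), drop = FALSE], jj)
  }

  upstream <- isTRUE(fwd$cache_upstream)

  if (!is.null(dlogits2) && !config$no_reweighting) {
    cb2 <- c_backward(params, fwd$c2, dlogits2)
    grads$C <- par_add(grads$C, cb2$grads)
    ds2 <- as.vector(t(cb2$dCin))
    if (!upstream) {
      # frozen upstream modules: classifier gradients only
    } else if (config$pearson_F) {
      demb2 <- pearson_backward(fwd$emb2, fwd$f2$cache, ds2)
    } else {
      fb2 <- f_backward(params, fwd$f2$cache, ds2)
      grads$F <- par_add(grads$F, fb2$grads)
      demb2 <- split_dU(fb2$dU)
    }
    if (upstream) {
      wvec <- as.vector(fwd$w)
      dw <- matrix(rowSums(demb2 * fwd$emb), N, B)
      demb <- demb + demb2 * wvec
      # attention: dK[i, j] += (1 - beta) * dw_i for j != i
      datt <- array(rep(as.vector(dw), each = N), c(N, N, B)) *
        (1 - config$beta)
      datt[cbind(rep(seq_len(N), B), rep(seq_len(N), B),
                 rep(seq_len(B), each = N))] <- 0
      ds1 <- ds1 + as.vector(datt)
    }
  }

  if (!is.null(dlogits1)) {
    cache1 <- if (config$no_reweighting) fwd$c2 else c1_cache
    cb1 <- c_backward(params, cache1, dlogits1)
    grads$C <- par_add(grads$C, cb1$grads)
    ds1 <- ds1 + as.vector(t(cb1$dCin))
  }

  if (upstream && any(ds1 != 0)) {
    if (config$pearson_F) {
      demb <- demb + pearson_backward(fwd$emb, fwd$f1$cache, ds1)
    } else {
      fb1 <- f_backward(params, fwd$f1$cache, ds1)
      grads$F <- par_add(grads$F, fb1$grads)
      demb <- demb + split_dU(fb1$dU)
    }
  }

  if (upstream && !config$identity_E) {
    grads$E <- e_backward(params, fwd$e_cache, demb, config)
  }
  grads
}

# Data-dependent rescaling of the classifier's first layer (LSUV-style
# calibrated initialisation): fold the training-set mean and spread of the
# flattened connectivity scores into W1 and b1, so that the classifier
# starts centred and unit-scaled. Equivalent to standardising the classifier
# input, expressed purely as a choice of initial parameters — the model
# class is unchanged.
calibrate_classifier_init <- function(params, X_all, n_subjects, config,
                                      max_subjects = 64L) {
  N <- config$n_regions
  n_use <- min(n_subjects, max_subjects)
  feats <- NULL
  for (start in seq(1L, n_use, by = 16L)) {
    b <- start:min(start + 15L, n_use)
    rows <- as.vector(outer(seq_len(N), (b - 1L) * N, `+`))
    fwd <- model_forward_batch(params, X_all[rows, , drop = FALSE],
                               length(b), config, train = FALSE)
    feats <- rbind(feats, fwd$Cin)
  }
  calibrate_classifier_from(params, feats)
}

calibrate_classifier_from <- function(params, feats) {
  mu <- colMeans(feats)
  sdv <- pmax(apply(feats, 2L, stats::sd), 1e-4)
  W1 <- params$C$l1$W / sdv           # row r scaled by 1 / sd of feature r
  params$C$l1$b <- params$C$l1$b - as.vector(crossprod(W1, mu))
  params$C$l1$W <- W1
  params
}

# ---- exported stage operations --------------------------------------------

#' Embed each region's time course
#'
#' Applies the shared feature extractor `E` (six 1-D convolutions with ReLU,
#' max-pooling after layers 1, 2, 4 and 6, and a final linear map)
#' independently to every region's signal.
#'
#' @param x an `N x T` numeric matrix (rows = regions) or a subject entry of
#'   a [panfc_dataset()].
#' @param params model parameters from [panfc_init_params()] or a fitted
#'   model's `$params`.
#' @param config a [panfc_config()].
#' @return an `N x d` matrix of region embeddings (with the `identity_E`
#'   ablation, the input itself).
#' @export
embed_regions <- function(x, params, config) {
  x <- as_subject_matrix(x)
  if (ncol(x) != config$n_timepoints)
    stop_panfc(sprintf("series length %d does not match config (T = %d%s)",
                       ncol(x), config$n_timepoints,
                       if (!config$identity_E) ", minimum 16" else ""))
  e_forward(params, x, config)$emb
}

#' Learned pairwise connectivity scores
#'
#' Applies the similarity network `F` to the concatenation `[e_i, e_j]` of
#' every ordered pair of region embeddings, giving the connectivity matrix
#' `K[i, j] = F([e_i, e_j])` with entries in (0, 1) (sigmoid output). With the
#' `pearson_F` ablation, `K[i, j]` is the sample Pearson correlation of the
#' two embedding vectors (entries in `[-1, 1]`).
#'
#' @param emb `N x d` embedding matrix.
#' @param params,config as in [embed_regions()].
#' @return an `N x N` matrix (asymmetric in general; diagonal computed but
#'   ignored by the attention sum).
#' @export
pairwise_connectivity <- function(emb, params, config) {
  N <- nrow(emb)
  ii <- rep(seq_len(N), each = N)
  jj <- rep(seq_len(N), times = N)
  s <- if (config$pearson_F) {
    pearson_scores(emb, ii, jj)$s
  } else {
    f_forward(params, cbind(emb[ii, , drop = FALSE], emb[jj, , drop = FALSE]))$s
  }
  t(matrix(s, N, N))
}

#' Attention weights from a connectivity matrix
#'
#' `w_i = beta + (1 - beta) * sum_{j != i} k_ij`: each region's weight
#' aggregates its outgoing connectivity scores, excluding the diagonal. With
#' scores in `[0, 1]` the weights lie in `[beta, beta + (1 - beta) * (N - 1)]`.
#'
#' @param K an `N x N` connectivity matrix.
#' @param beta scalar in `[0, 1]`; `beta = 1` gives all weights 1.
#' @return numeric vector of N region weights.
#' @export
attention_weights <- function(K, beta) {
  check_number(beta, "beta", lower = 0, upper = 1)
  beta + (1 - beta) * (rowSums(K) - diag(K))
}

#' Reweight region embeddings
#'
#' Scales row i of the embedding matrix by the attention weight `w_i`,
#' producing the updated embeddings `e'_i = w_i e_i` that feed the second
#' connectivity matrix.
#'
#' @param emb `N x d` embedding matrix.
#' @param w numeric vector of N attention weights.
#' @return the reweighted `N x d` matrix.
#' @export
reweight_embeddings <- function(emb, w) {
  if (length(w) != nrow(emb))
    stop_panfc("length(w) must equal nrow(emb)")
  emb * w
}

#' Single-subject forward pass
#'
#' Runs the six model stages on one subject and returns every intermediate:
#' the first connectivity matrix `K`, the attention weights, the updated
#' matrix `Kprime` (computed by the same network `F` on the reweighted
#' embeddings), the head logits read from `Kprime` flattened row-major
#' (diagonal included), and the classifier's first-layer feature activation.
#' With the `no_reweighting` ablation the classifier reads `K` and `Kprime`
#' is `NULL`.
#'
#' @param x `N x T` subject matrix (or dataset subject entry).
#' @param params,config as in [embed_regions()].
#' @return a list with elements `K`, `Kprime`, `logits`, `embeddings`,
#'   `weights`, `hidden`.
#' @export
panfc_forward <- function(x, params, config) {
  x <- as_subject_matrix(x)
  if (nrow(x) != config$n_regions)
    stop_panfc(sprintf("subject has %d regions, config expects %d",
                       nrow(x), config$n_regions))
  fwd <- model_forward_batch(params, x, 1L, config, train = FALSE)
  N <- config$n_regions
  w <- if (is.null(fwd$w)) NULL else drop(fwd$w)
  if (!is.null(w)) {
    lo <- min(config$beta, 1)
    hi <- config$beta + (1 - config$beta) * (N - 1)
    if (!config$pearson_F && (any(w < lo - 1e-9) || any(w > hi + 1e-9)))
      stop_panfc("attention weights escaped their [beta, beta+(1-beta)(N-1)] bounds")
  }
  list(K = t(matrix(fwd$s1, N, N)),
       Kprime = if (!config$no_reweighting) t(matrix(fwd$s2, N, N)),
       logits = drop(fwd$logits),
       embeddings = fwd$emb,
       weights = w,
       hidden = drop(fwd$hidden))
}

# accept either a bare matrix or a subject record from a dataset
as_subject_matrix <- function(x) {
  if (is.list(x) && !is.null(x$matrix)) x <- x$matrix
  if (!is.matrix(x) || !is.numeric(x))
    stop_panfc("subject time series must be a numeric regions x timepoints matrix")
  if (any(!is.finite(x)))
    stop_panfc("subject time series contains non-finite values")
  x
}
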