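#' Model architecture configuration
#'
#' Describes the full network: the shared six-layer 1-D convolutional
#' extractor `E` that embeds each region's time course, the three-layer
#' similarity MLP `F` that scores region pairs, the attention parameter
#' `beta`, the loss trade-off `lambda`, and the classifier `C`. Defaults are
#' the reference architecture (64/128/256/256/512/512 conv filters, kernel 3,
#' padding 1, max-pooling after layers 1, 2, 4 and 6, embedding dimension 32,
#' `beta = 0.9`, `lambda = 0.6`, classifier hidden widths 100 and 32 with
#' dropout 0.5). Hidden widths that the original description leaves open (the
#' two hidden layers of `F`, the classifier's second hidden layer, the
#' dropout rate) are configurable with documented defaults.
#'
#' @param n_regions number of parcellated regions N (rows of each subject
#'   matrix). The study's Harvard-Oxford parcellation has N = 117.
#' @param n_timepoints number of signal samples T per region. Must be at
#'   least 16 so that the four max-pooling halvings leave a non-empty
#'   feature map.
#' @param embed_dim embedding dimension d of each region (default 32).
#' @param head_size number of output logits l: 3 for diagnosis at the three
#'   follow-ups (also used by the severity-regression variant), 20 for the
#'   DSM-5 symptoms, 1 for the persistence (survival) head.
#' @param beta attention floor in `[0, 1]`: region weight
#'   `w_i = beta + (1 - beta) * sum_{j != i} k_ij`. `beta = 1` disables
#'   attention (all weights 1).
#' @param lambda loss trade-off in `[0, 1]`:
#'   `L = lambda * L1 + (1 - lambda) * L2`, where `L1` is the loss of the
#'   classifier applied to the first connectivity matrix K and `L2` the loss
#'   on the attention-updated matrix K'. Inference always uses K'.
#' @param conv_filters integer vector of six filter counts for `E`.
#' @param kernel_size odd kernel width of every conv layer (default 3,
#'   padding `(kernel_size - 1) / 2` keeps length).
#' @param pool_after indices of conv layers followed by max-pooling
#'   (kernel 2, stride 2); default `c(1, 2, 4, 6)`.
#' @param f_hidden two hidden widths of the similarity MLP `F`
#'   (default `c(64, 16)`).
#' @param c_hidden two hidden widths of the classifier `C`; the first is the
#'   width of the feature layer used for the 2-D visualisation (default
#'   `c(100, 32)`).
#' @param dropout dropout rate after the first two classifier layers
#'   (default 0.5; applied only during training).
#' @param init_gain_E,init_gain_F multipliers on the fan-in uniform
#'   initialisation bounds of the extractor and the similarity network
#'   (default 1). A gain above 1 on `F` widens the initial spread of the
#'   connectivity scores, which otherwise start nearly constant across
#'   subjects and provide no discriminative signal to the classifier.
#' @param similarity_init if `TRUE` (default), the first layer of `F` is
#'   initialised as alternating difference and sum detectors over the two
#'   concatenated embeddings (`[w, -w]` / `[w, +w]` weight pairs), so the
#'   pair score responds to the pair's relative geometry — and hence to
#'   inter-regional coupling — from the first training step. A plain fan-in
#'   uniform start (`FALSE`) makes `F` locally linear in the pair, whose
#'   score mean is then blind to coupling, and training tends to memorise
#'   instead of discovering a similarity readout.
#' @param calibrated_init if `TRUE` (default), [panfc_fit()] rescales the
#'   classifier's first layer at initialisation so that it reads a centred,
#'   unit-scaled version of the flattened connectivity (training-set mean
#'   and spread folded into `W1`, `b1`). The connectivity scores otherwise
#'   concentrate near 0.5 with a spread of order 0.01-0.1, which stalls
#'   gradient descent in the classifier.
#' @param regression_mode if `TRUE` the head is trained with masked MSE
#'   against standardized continuous severity scores instead of binary
#'   cross-entropy.
#' @param identity_E ablation: the extractor is the identity, so the
#'   embedding of region i is its raw T-long series (d becomes T).
#' @param pearson_F ablation: the similarity network is replaced by the
#'   sample Pearson correlation of the two embeddings (of the raw series
#'   when `identity_E` is also set). Entries then lie in `[-1, 1]`.
#' @param no_reweighting ablation: stages 3-5 are skipped and the classifier
#'   reads the first connectivity matrix K; K' is not computed.
#'
#' @return an object of class `"panfc_config"` (a validated list).
#' @seealso [panfc_fit()], [panfc_control()]
#' @export
#' @examples
#' cfg <- panfc_config(n_regions = 10, n_timepoints = 64,
#'                     conv_filters = c(4, 4, 8, 8, 8, 8), embed_dim = 8)
#' cfg$embed_dim
panfc_config <- function(n_regions, n_timepoints,
                         embed_dim = 32L,
                         head_size = 3L,
                         beta = 0.9,
                         lambda = 0.6,
                         conv_filters = c(64L, 128L, 256L, 256L, 512L, 512L),
                         kernel_size = 3L,
                         pool_after = c(1L, 2L, 4L, 6L),
                         f_hidden = c(64L, 16L),
                         c_hidden = c(100L, 32L),
                         dropout = 0.5,
                         init_gain_E = 1,
                         init_gain_F = 1,
                         similarity_init = TRUE,
                         calibrated_init = TRUE,
                         regression_mode = FALSE,
                         identity_E = FALSE,
                         pearson_F = FALSE,
                         no_reweighting = FALSE) {
  check_number(n_regions, "n_regions", lower = 2, integer = TRUE)
  check_number(n_timepoints, "n_timepoints", lower = 2, integer = TRUE)
  check_number(embed_dim, "embed_dim", lower = 1, integer = TRUE)
  check_number(beta, "beta", lower = 0, upper = 1)
  check_number(lambda, "lambda", lower = 0, upper = 1)
  check_number(dropout, "dropout", lower = 0, upper = 1)
  if (!head_size %in% c(1L, 3L, 20L))
    stop_panfc("'head_size' must be 1 (survival), 3 (diagnosis/severity) or 20 (symptoms)")
  if (length(conv_filters) != 6L || any(conv_filters < 1))
    stop_panfc("'conv_filters' must list six positive filter counts")
  if (kernel_size %% 2L != 1L)
    stop_panfc("'kernel_size' must be odd (length-preserving padding)")
  if (length(f_hidden) != 2L || length(c_hidden) != 2L)
    stop_panfc("'f_hidden' and 'c_hidden' must each give two hidden widths")
  for (flg in c(regression_mode, identity_E, pearson_F, no_reweighting)) {
    check_flag(flg, "ablation/mode flag")
  }

  if (!identity_E) {
    len <- as.integer(n_timepoints)
    for (layer in 1:6) {
      if (layer %in% pool_after) len <- len %/% 2L
    }
    if (len < 1L)
      stop_panfc(sprintf(
        "n_timepoints = %d is too short: %d max-pooling halvings need T >= %d",
        n_timepoints, length(pool_after), 2L^length(pool_after)))
  }

  cfg <- list(
    n_regions = as.integer(n_regions),
    n_timepoints = as.integer(n_timepoints),
    embed_dim = if (identity_E) as.integer(n_timepoints) else as.integer(embed_dim),
    head_size = as.integer(head_size),
    beta = beta,
    lambda = lambda,
    conv_filters = as.integer(conv_filters),
    kernel_size = as.integer(kernel_size),
    pool_after = as.integer(pool_after),
    f_hidden = as.integer(f_hidden),
    c_hidden = as.integer(c_hidden),
    dropout = dropout,
    init_gain_E = init_gain_E,
    init_gain_F = init_gain_F,
    similarity_init = isTRUE(similarity_init),
    calibrated_init = isTRUE(calibrated_init),
    regression_mode = regression_mode,
    identity_E = identity_E,
    pearson_F = pearson_F,
    no_reweighting = no_reweighting
  )
  class(cfg) <- "panfc_config"
  cfg
}

#' @export
print.panfc_config <- function(x, ...) {
  cat("Pairwise-attention network configuration\n")
  cat(sprintf("  regions N = %d, signal length T = %d, embedding d = %d\n",
              x$n_regions, x$n_timepoints, x$embed_dim))
  cat(sprintf("  head l = %d%s, beta = %g, lambda = %g\n", x$head_size,
              if (x$regression_mode) " (MSE regression)" else "",
              x$beta, x$lambda))
  cat(sprintf("  extractor filters: %s (kernel %d, pool after %s)\n",
              paste(x$conv_filters, collapse = "/"), x$kernel_size,
              paste(x$pool_after, collapse = ",")))
  cat(sprintf("  F hidden: %s; C hidden: %s; dropout %g\n",
              paste(x$f_hidden, collapse = "/"),
              paste(x$c_hidden, collapse = "/"), x$dropout))
  abl <- c("identity_E", "pearson_F", "no_reweighting")[
    c(x$identity_E, x$pearson_F, x$no_reweighting)]
  if (length(abl)) cat("  ablations:", paste(abl, collapse = ", "), "\n")
  invisible(x)
}

#' Training control parameters
#'
#' Optimizer and cross-validation settings. Defaults are the reference
#' training protocol: Adam with `beta1 = 0.5`, `beta2 = 0.999`, initial
#' learning rate 1e-4 divided by 10 every 30 epochs, 100 epochs, batch
#' size 20.
#'
#' @param epochs number of passes over the training set.
#' @param batch_size subjects per gradient step (the final short batch is
#'   kept).
#' @param learning_rate initial Adam step size.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param lr_decay_every divide the learning rate by `lr_decay_factor` every
#'   this many epochs (set `Inf` to disable).
#' @param lr_decay_factor decay divisor (default 10).
#' @param weight_decay decoupled L2 shrinkage per step (AdamW style;
#'   default 0, i.e. plain Adam).
#' @param n_restarts number of independent initialisations warmed up for
#'   `restart_epochs` epochs; the one with the lowest training loss
#'   continues to the full epoch count (default 1 = no restarts). Selection
#'   uses the training set only.
#' @param restart_epochs warm-up length per restart (default 10).
#' @param lr_scale_E,lr_scale_F per-module multipliers on the learning rate
#'   for the extractor and the similarity network (default 1; the classifier
#'   always trains at the base rate). Values below 1 let the classifier
#'   learn its readout of the initial similarity geometry before the
#'   upstream networks reshape it, which protects against the collapse of
#'   the connectivity scores onto a constant.
#' @param shuffle reshuffle subject order every epoch (seeded).
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout; identical seeds give bit-identical training histories.
#' @param verbose print the loss every `verbose` epochs (0 = silent).
#'
#' @return an object of class `"panfc_control"`.
#' @export
panfc_control <- function(epochs = 100L, batch_size = 20L,
                          learning_rate = 1e-4,
                          adam_beta1 = 0.5, adam_beta2 = 0.999,
                          lr_decay_every = 30L, lr_decay_factor = 10,
                          weight_decay = 0,
                          lr_scale_E = 1, lr_scale_F = 1,
                          n_restarts = 1L, restart_epochs = 10L,
                          shuffle = TRUE, seed = 1L, verbose = 0L) {
  check_number(weight_decay, "weight_decay", lower = 0)
  check_number(n_restarts, "n_restarts", lower = 1, integer = TRUE)
  check_number(restart_epochs, "restart_epochs", lower = 1, integer = TRUE)
  check_number(epochs, "epochs", lower = 1, integer = TRUE)
  check_number(batch_size, "batch_size", lower = 1, integer = TRUE)
  check_number(learning_rate, "learning_rate", lower = 1e-12)
  check_number(lr_scale_E, "lr_scale_E", lower = 0)
  check_number(lr_scale_F, "lr_scale_F", lower = 0)
  check_number(seed, "seed", integer = TRUE)
  ctl <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              learning_rate = learning_rate,
              adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
              lr_decay_every = lr_decay_every,
              lr_decay_factor = lr_decay_factor,
              weight_decay = weight_decay,
              lr_scale_E = lr_scale_E, lr_scale_F = lr_scale_F,
              n_restarts = as.integer(n_restarts),
              restart_epochs = as.integer(restart_epochs),
              shuffle = isTRUE(shuffle), seed = as.integer(seed),
              verbose = as.integer(verbose))
  class(ctl) <- "panfc_control"
  ctl
}
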