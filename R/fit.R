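# Training objective and the model-fitting front end.

#' Positive-class weights for imbalanced heads
#'
#' For each head coordinate (column), the weight applied to positive examples
#' in the binary cross-entropy is the ratio of observed negatives to observed
#' positives, so that the total positive and negative mass balance. With a
#' 72% positive rate the positive weight is 28/72. A coordinate with zero
#' observed positives gets weight 1 with a warning.
#'
#' @param y numeric or integer matrix of 0/1 labels, `NA` = unobserved.
#' @return numeric vector of per-column positive-class weights.
#' @export
#' @examples
#' class_weights(cbind(c(1, 1, 0, 1), c(0, 0, 1, NA)))
class_weights <- function(y) {
  y <- as.matrix(y)
  vapply(seq_len(ncol(y)), function(j) {
    obs <- y[, j][!is.na(y[, j])]
    npos <- sum(obs == 1)
    nneg <- sum(obs == 0)
    if (npos == 0) {
      warning(sprintf("head coordinate %d has no observed positives; weight set to 1", j))
      return(1)
    }
    nneg / npos
  }, numeric(1))
}

#' Masked, class-weighted binary cross-entropy with logits
#'
#' Treats each of the l head coordinates as an independent binary problem:
#' per-entry loss `pos_weight * y * softplus(-z) + (1 - y) * softplus(z)`,
#' zeroed where the label is unobserved, averaged over all observed entries
#' in the batch. Changing the label value under a masked entry leaves both
#' the loss and the gradient bit-identical.
#'
#' @param logits `n x l` matrix of raw scores z.
#' @param y `n x l` matrix of 0/1 labels; `NA` allowed wherever `mask` is 0.
#' @param pos_weight positive-class weight per column (recycled if scalar).
#' @param mask optional 0/1 matrix of observed entries; defaults to
#'   `!is.na(y)`.
#' @return list with `loss` (scalar) and `grad` (`n x l`, gradient of the
#'   loss w.r.t. the logits; zero at masked entries).
#' @export
masked_weighted_bce <- function(logits, y, pos_weight = 1, mask = NULL) {
  logits <- as.matrix(logits); y <- as.matrix(y)
  if (!all(dim(logits) == dim(y)))
    stop_panfc("logits and labels must have matching dimensions")
  if (is.null(mask)) mask <- !is.na(y)
  mask <- (as.matrix(mask) != 0)
  n_obs <- sum(mask)
  if (n_obs == 0) stop_panfc("all labels are masked: loss undefined")
  pw <- matrix(rep(pos_weight, length.out = ncol(y)),
               nrow(y), ncol(y), byrow = TRUE)
  y0 <- ifelse(mask, y, 0)
  sp_pos <- function(z) log1p(exp(-abs(z))) + pmax(z, 0)   # softplus(z)
  elem <- pw * y0 * sp_pos(-logits) + (1 - y0) * sp_pos(logits)
  elem[!mask] <- 0
  grad <- (1 - y0) * nn_sigmoid(logits) - pw * y0 * nn_sigmoid(-logits)
  grad[!mask] <- 0
  list(loss = sum(elem) / n_obs, grad = grad / n_obs)
}

# masked mean-squared error for the severity-regression variant
masked_mse <- function(pred, y, mask = NULL) {
  pred <- as.matrix(pred); y <- as.matrix(y)
  if (is.null(mask)) mask <- !is.na(y)
  mask <- (as.matrix(mask) != 0)
  n_obs <- sum(mask)
  if (n_obs == 0) stop_panfc("all targets are masked: loss undefined")
  diff <- ifelse(mask, pred - y, 0)
  list(loss = sum(diff^2) / n_obs, grad = 2 * diff / n_obs)
}

#' Combine the two connectivity-path losses
#'
#' `L = lambda * L1 + (1 - lambda) * L2`, where `L1` is the loss of the
#' classifier read from the first connectivity matrix K and `L2` from the
#' attention-updated matrix K'. The same classifier (shared parameters)
#' produces both. Inference always uses K'.
#'
#' @param loss1,loss2 the two path losses.
#' @param lambda trade-off in `[0, 1]`.
#' @return list with `L1`, `L2`, `L`.
#' @export
combined_loss <- function(loss1, loss2, lambda) {
  check_number(lambda, "lambda", lower = 0, upper = 1)
  list(L1 = loss1, L2 = loss2, L = lambda * loss1 + (1 - lambda) * loss2)
}

#' Random subject-level train/test splits
#'
#' Draws `n_splits` independent random splits (repeated random subsampling,
#' not a partition): in each, `train_fraction` of the subjects form the
#' training set and the rest the test set. Deterministic given the seed.
#'
#' @param subject_ids character vector of subject identifiers.
#' @param n_splits number of random splits (default 5).
#' @param train_fraction fraction of subjects used for training (default 0.8).
#' @param seed integer seed.
#' @return list of `n_splits` lists with elements `train` and `test`
#'   (disjoint id vectors whose union is `subject_ids`).
#' @export
make_cv_splits <- function(subject_ids, n_splits = 5L, train_fraction = 0.8,
                           seed = 1L) {
  n <- length(subject_ids)
  if (n < 5L) stop_panfc("need at least 5 subjects to split")
  check_number(train_fraction, "train_fraction", lower = 1e-9, upper = 1 - 1e-9)
  n_train <- round(train_fraction * n)
  if (n_train < 1 || n_train >= n)
    stop_panfc("train_fraction leaves an empty train or test set")
  with_seed(seed, lapply(seq_len(n_splits), function(s) {
    tr <- sort(sample.int(n, n_train))
    list(train = subject_ids[tr], test = subject_ids[-tr])
  }))
}

# ---- label resolution ------------------------------------------------------

# Returns per-subject target matrix (NA = unobserved) for a head, in the
# order of dataset$subject_ids
head_targets <- function(dataset, head, timepoint = 1L) {
  lab <- dataset$labels
  switch(head,
    dx = as.matrix(lab[, c("dx_t1", "dx_t2", "dx_t3")]),
    caps = as.matrix(lab[, c("caps_t1", "caps_t2", "caps_t3")]),
    symptoms = {
      if (!timepoint %in% 1:3) stop_panfc("'timepoint' must be 1, 2 or 3")
      as.matrix(lab[, symptom_columns(timepoint)])
    },
    survival = matrix(lab$persists_t3, ncol = 1L,
                      dimnames = list(NULL, "persists_t3")),
    stop_panfc(sprintf("unknown head '%s'", head)))
}

symptom_codes <- function() {
  c(paste0("b", 1:5), paste0("c", 1:2), paste0("d", 1:7), paste0("e", 1:6))
}

symptom_columns <- function(timepoint) {
  paste0("sym_t", timepoint, "_", symptom_codes())
}

#' Fit the pairwise-attention connectivity network
#'
#' Trains the end-to-end model on a dataset of parcellated time series and
#' longitudinal labels, minimizing the dual objective
#' `L = lambda * L1 + (1 - lambda) * L2` (weighted, masked binary
#' cross-entropy of the classifier applied to the first and to the
#' attention-updated connectivity matrix) with Adam. Unobserved labels
#' (subject lost to follow-up) contribute nothing to loss or gradient.
#'
#' @param data a [panfc_dataset()] or the `$dataset` of a [simulate_cohort()]
#'   result (accepted directly).
#' @param head outcome to predict: `"dx"` (diagnosis at the three follow-up
#'   time-points, l = 3), `"symptoms"` (20 DSM-5 symptom bits at one
#'   time-point, l = 20), `"survival"` (persistence of a time-point-1
#'   diagnosis to time-point 3, l = 1, fitted on the T1-positive subset),
#'   or `"caps"` (continuous severity at the three time-points, masked MSE
#'   on training-set z-scores, l = 3).
#' @param timepoint which time-point's symptoms to predict (`head =
#'   "symptoms"` only).
#' @param config a [panfc_config()]; defaults to the reference architecture
#'   sized from the data.
#' @param control a [panfc_control()].
#' @param subset optional character vector of subject ids to train on
#'   (e.g. the train half of a split). Class weights and the severity scaler
#'   are computed on this subset only.
#' @param validation optional id vector; per-epoch validation loss is
#'   recorded in the history.
#' @return an object of class `"panfc"` with components `params`, `config`,
#'   `control`, `head`, `history` (one row per epoch), `class_weights`,
#'   `caps_scaler`, `region_names`, `subject_ids`.
#' @seealso [predict.panfc()], [panfc_cv()]
#' @export
panfc_fit <- function(data, head = c("dx", "symptoms", "survival", "caps"),
                      timepoint = 1L, config = NULL,
                      control = panfc_control(), subset = NULL,
                      validation = NULL) {
  head <- match.arg(head)
  dataset <- as_panfc_dataset(data)
  if (head == "survival" && is.null(dataset$no_survival_filter)) {
    task <- build_survival_task(dataset)
    dataset <- task$dataset
  }
  ids <- dataset$subject_ids
  if (!is.null(subset)) {
    missing_ids <- setdiff(subset, ids)
    if (length(missing_ids))
      stop_panfc("subset ids not in data: ", paste(head(missing_ids, 3L), collapse = ", "))
    ids <- intersect(ids, subset)
  }
  if (length(ids) == 0) stop_panfc("no subjects to train on")

  N <- nrow(dataset$subjects[[1L]])
  Tn <- ncol(dataset$subjects[[1L]])
  if (is.null(config)) {
    config <- panfc_config(n_regions = N, n_timepoints = Tn,
                           head_size = switch(head, dx = 3L, caps = 3L,
                                              symptoms = 20L, survival = 1L),
                           regression_mode = (head == "caps"))
  }
  if (config$n_regions != N || config$n_timepoints != Tn)
    stop_panfc("config dimensions do not match the data")
  expected_l <- switch(head, dx = 3L, caps = 3L, symptoms = 20L, survival = 1L)
  if (config$head_size != expected_l)
    stop_panfc(sprintf("head '%s' needs head_size %d, config has %d",
                       head, expected_l, config$head_size))
  if (head == "caps" && !config$regression_mode)
    stop_panfc("head 'caps' requires regression_mode = TRUE")

  Y <- head_targets(dataset, head, timepoint)
  Y <- Y[match(ids, dataset$subject_ids), , drop = FALSE]
  if (all(is.na(Y))) stop_panfc("no observed labels for this head")

  caps_scaler <- NULL
  pw <- NULL
  if (head == "caps") {
    mu <- colMeans(Y, na.rm = TRUE)
    sdv <- apply(Y, 2, stats::sd, na.rm = TRUE)
    sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
    caps_scaler <- list(mean = mu, sd = sdv)
    Y <- sweep(sweep(Y, 2, mu), 2, sdv, "/")
  } else {
    pw <- class_weights(Y)
  }

  X_all <- do.call(rbind, dataset$subjects[ids])
  n <- length(ids)

  Yval <- NULL; Xval <- NULL
  if (!is.null(validation)) {
    vids <- intersect(validation, dataset$subject_ids)
    Yval <- head_targets(dataset, head, timepoint)[
      match(vids, dataset$subject_ids), , drop = FALSE]
    if (head == "caps")
      Yval <- sweep(sweep(Yval, 2, caps_scaler$mean), 2, caps_scaler$sd, "/")
    Xval <- do.call(rbind, dataset$subjects[vids])
  }

  lr_scale <- c(E = control$lr_scale_E %||% 1, F = control$lr_scale_F %||% 1,
                C = 1)
  # with both upstream modules frozen, skip their gradient computation
  upstream_frozen <- lr_scale[["E"]] == 0 && lr_scale[["F"]] == 0

  # with frozen upstream modules the connectivity features of each subject
  # never change: compute them once per initialisation and train only the
  # classifier on them (identical arithmetic, large speed-up)
  frozen_features <- function(params) {
    N2 <- N * N
    Cin2 <- matrix(0, n, N2)
    Cin1 <- matrix(0, n, N2)
    for (start in seq(1L, n, by = 32L)) {
      b <- start:min(start + 31L, n)
      rows <- as.vector(outer(seq_len(N), (b - 1L) * N, `+`))
      fwd <- model_forward_batch(params, X_all[rows, , drop = FALSE],
                                 length(b), config, train = FALSE)
      Cin2[b, ] <- fwd$Cin
      Cin1[b, ] <- t(matrix(fwd$s1, N2, length(b)))
    }
    list(Cin2 = Cin2, Cin1 = Cin1)
  }

  # one contiguous run of epochs; resumable so that multi-restart selection
  # can continue the best warm-up
  train_segment <- function(params, state, epoch_seq, feat = NULL) {
    hist <- vector("list", length(epoch_seq))
    for (epoch in epoch_seq) {
      lr <- control$learning_rate /
        control$lr_decay_factor^floor((epoch - 1) / control$lr_decay_every)
      ord <- if (control$shuffle) sample.int(n) else seq_len(n)
      batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
      eL <- eL1 <- eL2 <- 0
      for (bix in seq_along(batches)) {
        b <- batches[[bix]]
        yb <- Y[b, , drop = FALSE]
        if (all(is.na(yb)))
          stop_panfc("a training batch has no observed labels; lower batch_size or check masks")
        loss_fn <- function(z) {
          if (config$regression_mode) masked_mse(z, yb)
          else masked_weighted_bce(z, yb, pos_weight = pw)
        }
        diverged <- function() {
          stop_panfc(sprintf("training diverged (non-finite loss) at epoch %d, batch %d",
                             epoch, bix))
        }
        if (!is.null(feat)) {
          # classifier-only training on cached connectivity features
          c2f <- c_forward(params, feat$Cin2[b, , drop = FALSE], config,
                           train = TRUE)
          if (config$no_reweighting) {
            r1 <- loss_fn(c2f$logits)
            L1 <- r1$loss; L2 <- NA_real_; L <- r1$loss
            if (!is.finite(L)) diverged()
            cb <- c_backward(params, c2f$cache, r1$grad)
            grads <- list(C = cb$grads)
          } else {
            r2 <- loss_fn(c2f$logits)
            c1f <- c_forward(params, feat$Cin1[b, , drop = FALSE], config,
                             train = TRUE)
            r1 <- loss_fn(c1f$logits)
            lam <- config$lambda
            L1 <- r1$loss; L2 <- r2$loss
            L <- lam * L1 + (1 - lam) * L2
            if (!is.finite(L)) diverged()
            gC <- NULL
            if (lam < 1) gC <- c_backward(params, c2f$cache,
                                          (1 - lam) * r2$grad)$grads
            if (lam > 0) {
              g1 <- c_backward(params, c1f$cache, lam * r1$grad)$grads
              gC <- if (is.null(gC)) g1 else par_add(gC, g1)
            }
            grads <- list(C = gC)
          }
        } else {
          rows <- as.vector(outer(seq_len(N), (b - 1L) * N, `+`))
          fwd <- model_forward_batch(params, X_all[rows, , drop = FALSE],
                                     length(b), config, train = TRUE,
                                     cache_upstream = !upstream_frozen)
          if (config$no_reweighting) {
            r1 <- loss_fn(fwd$logits)
            L1 <- r1$loss; L2 <- NA_real_; L <- r1$loss
            if (!is.finite(L)) diverged()
            grads <- model_backward_batch(params, fwd, config,
                                          dlogits1 = r1$grad)
          } else {
            r2 <- loss_fn(fwd$logits)                       # K' path
            Cin1 <- t(matrix(fwd$s1, N * N, length(b)))     # K path
            c1f <- c_forward(params, Cin1, config, train = TRUE)
            r1 <- loss_fn(c1f$logits)
            lam <- config$lambda
            L1 <- r1$loss; L2 <- r2$loss
            L <- lam * L1 + (1 - lam) * L2
            if (!is.finite(L)) diverged()
            grads <- model_backward_batch(
              params, fwd, config,
              dlogits1 = if (lam > 0) lam * r1$grad,
              dlogits2 = if (lam < 1) (1 - lam) * r2$grad,
              c1_cache = c1f$cache)
          }
        }
        for (comp in names(params)) {
          if (lr_scale[comp] == 0) next
          st <- adam_step(params[[comp]], grads[[comp]], state[[comp]],
                          lr * unname(lr_scale[comp]),
                          beta1 = control$adam_beta1,
                          beta2 = control$adam_beta2,
                          weight_decay = control$weight_decay %||% 0)
          params[[comp]] <- st$params; state[[comp]] <- st$state
        }
        eL <- eL + L; eL1 <- eL1 + L1; eL2 <- eL2 + L2
      }
      nb <- length(batches)
      val_loss <- NA_real_
      if (!is.null(Yval) && nrow(Yval) > 0) {
        zv <- predict_logits_internal(params, Xval, nrow(Yval), config)
        val_loss <- if (config$regression_mode) masked_mse(zv, Yval)$loss
                    else masked_weighted_bce(zv, Yval, pos_weight = pw)$loss
      }
      hist[[match(epoch, epoch_seq)]] <-
        data.frame(epoch = epoch, lr = lr, loss = eL / nb,
                   loss1 = eL1 / nb, loss2 = eL2 / nb, val_loss = val_loss)
      if (control$verbose > 0 && epoch %% control$verbose == 0)
        message(sprintf("epoch %3d  L = %.5f (L1 %.5f, L2 %.5f)",
                        epoch, eL / nb, eL1 / nb, eL2 / nb))
    }
    list(params = params, state = state, history = do.call(rbind, hist))
  }

  init_run <- function() {
    params <- panfc_init_params(config)
    feat <- if (upstream_frozen) frozen_features(params)
    if (isTRUE(config$calibrated_init)) {
      params <- if (!is.null(feat)) {
        calibrate_classifier_from(params, feat$Cin2[seq_len(min(n, 64L)), ,
                                                    drop = FALSE])
      } else {
        calibrate_classifier_init(params, X_all, n, config)
      }
    }
    list(params = params, feat = feat)
  }

  n_restarts <- max(1L, as.integer(control$n_restarts %||% 1L))
  warm_epochs <- min(control$epochs,
                     as.integer(control$restart_epochs %||% 10L))
  fitted <- if (n_restarts == 1L) {
    with_seed(control$seed, {
      ini <- init_run()
      train_segment(ini$params, lapply(ini$params, adam_init),
                    seq_len(control$epochs), feat = ini$feat)
    })
  } else {
    # several short warm-ups from different initialisations; the one with
    # the lowest training loss continues to the full epoch count (selection
    # uses the training set only)
    cands <- lapply(seq_len(n_restarts), function(r) {
      with_seed(control$seed + (r - 1L) * 1009L, {
        ini <- init_run()
        seg <- train_segment(ini$params, lapply(ini$params, adam_init),
                             seq_len(warm_epochs), feat = ini$feat)
        seg$rng <- get(".Random.seed", envir = globalenv())
        seg$feat <- ini$feat
        seg
      })
    })
    losses <- vapply(cands, function(s) s$history$loss[nrow(s$history)],
                     numeric(1))
    best <- cands[[which.min(losses)]]
    if (warm_epochs < control$epochs) {
      old_rng <- if (exists(".Random.seed", envir = globalenv(),
                           inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
      assign(".Random.seed", best$rng, envir = globalenv())
      on.exit(if (!is.null(old_rng))
        assign(".Random.seed", old_rng, envir = globalenv()), add = TRUE)
      seg2 <- train_segment(best$params, best$state,
                            (warm_epochs + 1L):control$epochs,
                            feat = best$feat)
      best$params <- seg2$params
      best$history <- rbind(best$history, seg2$history)
    }
    best$feat <- NULL
    best
  }

  structure(list(params = fitted$params, config = config, control = control,
                 head = head, timepoint = as.integer(timepoint),
                 history = fitted$history,
                 class_weights = pw, caps_scaler = caps_scaler,
                 region_names = dataset$region_names,
                 subject_ids = ids, version = "1",
                 call = match.call()),
            class = "panfc")
}

# batched evaluation-mode logits for stacked subject rows
predict_logits_internal <- function(params, Xrows, n_subjects, config,
                                    chunk = 64L) {
  N <- config$n_regions
  out <- NULL
  for (start in seq(1L, n_subjects, by = chunk)) {
    b <- start:min(start + chunk - 1L, n_subjects)
    rows <- as.vector(outer(seq_len(N), (b - 1L) * N, `+`))
    fwd <- model_forward_batch(params, Xrows[rows, , drop = FALSE],
                               length(b), config, train = FALSE)
    out <- rbind(out, fwd$logits)
  }
  out
}

#' Fit one independent binary model per time-point (ablation)
#'
#' Instead of a single three-label model, trains a separate single-logit
#' model for the diagnosis at each of the three time-points, all with the
#' same architecture and training protocol. The returned object predicts an
#' `n x 3` score matrix like the joint model, so the same evaluation code
#' applies.
#'
#' @inheritParams panfc_fit
#' @return object of class `"panfc_indep"`: a list of three `"panfc"` fits.
#' @export
panfc_fit_independent <- function(data, config = NULL,
                                  control = panfc_control(), subset = NULL) {
  dataset <- as_panfc_dataset(data)
  fits <- lapply(1:3, function(tp) {
    ds_t <- dataset
    # keep only this time-point's diagnosis as a single-label target
    lab <- ds_t$labels
    lab$persists_t3 <- lab[[paste0("dx_t", tp)]]
    ds_t$labels <- lab
    cfg <- config
    if (!is.null(cfg)) {
      cfg <- unclass(cfg)
      cfg$head_size <- 1L
      if (cfg$identity_E) cfg$embed_dim <- 32L  # recomputed from T inside
      cfg <- do.call(panfc_config, cfg)
    }
    ctl <- control
    ctl$seed <- control$seed + tp
    fit <- panfc_fit_single_label(ds_t, cfg, ctl, subset)
    fit
  })
  structure(list(fits = fits), class = "panfc_indep")
}

# single-logit fit against the label stored in labels$persists_t3
panfc_fit_single_label <- function(dataset, config, control, subset) {
  # masquerade as the survival head but without the T1-positive filtering:
  # temporarily mark every subject as eligible
  ds <- dataset
  fitlike <- panfc_fit(structure(list(subjects = ds$subjects,
                                      labels = ds$labels,
                                      region_names = ds$region_names,
                                      subject_ids = ds$subject_ids,
                                      no_survival_filter = TRUE),
                                 class = "panfc_dataset"),
                       head = "survival", config = config, control = control,
                       subset = subset)
  fitlike
}

#' @export
print.panfc <- function(x, ...) {
  cat(sprintf("Pairwise-attention connectivity model (head '%s', l = %d)\n",
              x$head, x$config$head_size))
  cat(sprintf("  trained on %d subjects, %d epochs; final loss %.5f\n",
              length(x$subject_ids), nrow(x$history),
              x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.panfc <- function(object, ...) {
  print(object$config)
  h <- object$history
  cat(sprintf("Training: %d epochs, final L = %.5f (L1 %.5f, L2 %.5f)\n",
              nrow(h), h$loss[nrow(h)], h$loss1[nrow(h)], h$loss2[nrow(h)]))
  if (!is.null(object$class_weights))
    cat("Positive-class weights:",
        paste(sprintf("%.3f", object$class_weights), collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.panfc <- function(object, ...) object$params

#' Plot the training history
#'
#' Draws the combined loss and, where applicable, the two path losses
#' against the epoch.
#'
#' @param x a fitted `"panfc"` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.panfc <- function(x, ...) {
  h <- x$history
  cols <- intersect(c("loss", "loss1", "loss2"), names(h))
  m <- as.matrix(h[, cols, drop = FALSE])
  graphics::matplot(h$epoch, m, type = "l", lty = 1:3, col = c(1, 2, 4),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", legend = cols, lty = 1:3, col = c(1, 2, 4),
                   bty = "n")
  invisible(x)
}

#' Predict from a fitted pairwise-attention model
#'
#' @param object a `"panfc"` fit.
#' @param newdata a [panfc_dataset()] (or cohort); for the survival head the
#'   eligible subset is selected automatically.
#' @param type `"prob"` (sigmoid scores; for the severity-regression variant,
#'   predictions on the original score scale), `"logits"`, `"connectivity"`
#'   (list of per-subject updated connectivity matrices), `"hidden"`
#'   (first classifier-layer feature matrix), or `"embedding"`.
#' @param subset optional subject ids to predict for.
#' @param ... unused.
#' @return matrix of scores (rownames = subject ids) or a named list for
#'   `type = "connectivity"` / `"embedding"`.
#' @export
predict.panfc <- function(object, newdata,
                          type = c("prob", "logits", "connectivity",
                                   "hidden", "embedding"),
                          subset = NULL, ...) {
  type <- match.arg(type)
  dataset <- as_panfc_dataset(newdata)
  if (object$head == "survival" && is.null(dataset$no_survival_filter)) {
    dataset <- build_survival_task(dataset)$dataset
  }
  ids <- dataset$subject_ids
  if (!is.null(subset)) ids <- intersect(ids, subset)
  if (!length(ids)) stop_panfc("no subjects to predict for")
  cfg <- object$config
  N <- cfg$n_regions

  if (type %in% c("connectivity", "embedding")) {
    out <- lapply(ids, function(id) {
      fw <- panfc_forward(dataset$subjects[[id]], object$params, cfg)
      if (type == "connectivity") {
        if (cfg$no_reweighting) fw$K else fw$Kprime
      } else fw$embeddings
    })
    names(out) <- ids
    return(out)
  }

  Xrows <- do.call(rbind, dataset$subjects[ids])
  if (type == "hidden") {
    hid <- NULL
    for (start in seq(1L, length(ids), by = 64L)) {
      b <- start:min(start + 63L, length(ids))
      rows <- as.vector(outer(seq_len(N), (b - 1L) * N, `+`))
      fwd <- model_forward_batch(object$params, Xrows[rows, , drop = FALSE],
                                 length(b), cfg, train = FALSE)
      hid <- rbind(hid, fwd$hidden)
    }
    rownames(hid) <- ids
    return(hid)
  }

  z <- predict_logits_internal(object$params, Xrows, length(ids), cfg)
  rownames(z) <- ids
  if (type == "logits") return(z)
  if (cfg$regression_mode) {
    sweep(sweep(z, 2, object$caps_scaler$sd, "*"), 2, object$caps_scaler$mean, "+")
  } else {
    nn_sigmoid(z)
  }
}

#' @export
predict.panfc_indep <- function(object, newdata, type = c("prob", "logits"),
                                subset = NULL, ...) {
  type <- match.arg(type)
  scores <- lapply(object$fits, function(f) {
    ds <- as_panfc_dataset(newdata)
    ds$no_survival_filter <- TRUE
    predict(f, ds, type = type, subset = subset)
  })
  out <- do.call(cbind, scores)
  colnames(out) <- paste0("dx_t", 1:3)
  out
}

#' @export
print.panfc_indep <- function(x, ...) {
  cat("Independent per-time-point models (3 x single-logit fits)\n")
  invisible(x)
}

#' Residuals of the severity-regression variant
#'
#' Observed minus predicted severity scores, on the original scale, `NA`
#' where the label is unobserved.
#'
#' @param object a `"panfc"` fit with `regression_mode = TRUE`.
#' @param data the dataset to evaluate against.
#' @param ... unused.
#' @export
residuals.panfc <- function(object, data, ...) {
  if (!object$config$regression_mode)
    stop_panfc("residuals are defined for the severity-regression variant only")
  dataset <- as_panfc_dataset(data)
  pred <- predict(object, dataset, type = "prob")
  obs <- head_targets(dataset, "caps")[
    match(rownames(pred), dataset$subject_ids), , drop = FALSE]
  structure(obs - pred, dimnames = dimnames(pred))
}
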