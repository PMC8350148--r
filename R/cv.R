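# Cross-validated evaluation and parameter-sensitivity sweeps.

#' Cross-validated model evaluation
#'
#' Repeats random 80/20 subject-level splits, fits the model on each training
#' set and scores the held-out subjects. Reports per-split and mean +/- SD
#' metrics for every head coordinate.
#'
#' @inheritParams panfc_fit
#' @param n_splits number of random splits (default 5).
#' @param train_fraction training fraction per split (default 0.8).
#' @param seed seed for the splits; each split's fit uses
#'   `control$seed + split index`.
#' @param independent fit the independent-per-time-point ablation instead of
#'   the joint three-label model (`head = "dx"` only).
#' @param keep_models retain the fitted models in the result.
#' @return object of class `"panfc_cv"`: list with `per_split` (metric rows
#'   per split), `summary` (mean and SD by head coordinate), `splits`, and
#'   optionally `models`.
#' @export
panfc_cv <- function(data, head = c("dx", "symptoms", "survival", "caps"),
                     timepoint = 1L, config = NULL,
                     control = panfc_control(),
                     n_splits = 5L, train_fraction = 0.8, seed = 1L,
                     independent = FALSE, keep_models = FALSE) {
  head <- match.arg(head)
  dataset <- as_panfc_dataset(data)
  if (head == "survival") dataset <- build_survival_task(dataset)$dataset
  if (independent && head != "dx")
    stop_panfc("the independent-per-time-point ablation applies to head = 'dx'")
  splits <- make_cv_splits(dataset$subject_ids, n_splits = n_splits,
                           train_fraction = train_fraction, seed = seed)
  per_split <- list()
  models <- list()
  for (s in seq_along(splits)) {
    sp <- splits[[s]]
    ctl <- control
    ctl$seed <- control$seed + s
    ds_fit <- dataset
    if (head == "survival") ds_fit$no_survival_filter <- TRUE
    fit <- if (independent) {
      panfc_fit_independent(ds_fit, config = config, control = ctl,
                            subset = sp$train)
    } else {
      panfc_fit(ds_fit, head = head, timepoint = timepoint, config = config,
                control = ctl, subset = sp$train)
    }
    ds_pred <- dataset
    ds_pred$no_survival_filter <- TRUE
    scores <- predict(fit, ds_pred, subset = sp$test)
    y <- head_targets(dataset, head, timepoint)
    y <- y[match(rownames(scores), dataset$subject_ids), , drop = FALSE]
    met <- evaluate_scores(scores, y, regression = (head == "caps"))
    met$split <- s
    per_split[[s]] <- met
    if (keep_models) models[[s]] <- fit
  }
  per_split <- do.call(rbind, per_split)
  metric_cols <- c("accuracy", "balanced_accuracy", "auc",
                   "average_precision", "mse")
  summ <- do.call(rbind, lapply(split(per_split, per_split$head), function(d) {
    v <- unlist(lapply(metric_cols, function(m) mean_sd(d[[m]])))
    names(v) <- paste(rep(metric_cols, each = 2L), c("mean", "sd"), sep = "_")
    cbind(data.frame(head = d$head[1L]), as.data.frame(as.list(v)))
  }))
  # keep rows in head order of the label matrix
  summ <- summ[match(unique(per_split$head), summ$head), ]
  rownames(summ) <- NULL
  structure(list(per_split = per_split, summary = summ, splits = splits,
                 head = head, independent = independent,
                 models = if (keep_models) models),
            class = "panfc_cv")
}

#' @export
print.panfc_cv <- function(x, digits = 3, ...) {
  cat(sprintf("Cross-validated evaluation (head '%s'%s, %d splits)\n",
              x$head, if (x$independent) ", independent per time-point" else "",
              length(x$splits)))
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Sensitivity sweep over beta or lambda
#'
#' Re-runs the full cross-validated evaluation at each grid value of the
#' attention parameter `beta` or the loss trade-off `lambda`, holding
#' everything else fixed.
#'
#' @inheritParams panfc_cv
#' @param param `"beta"` or `"lambda"`.
#' @param grid numeric vector of values in `[0, 1]`.
#' @param config a [panfc_config()] used as the template at every grid point.
#' @return data frame with one row per grid value and head coordinate:
#'   mean and SD of accuracy and AUC across splits.
#' @export
sensitivity_sweep <- function(data, param = c("beta", "lambda"), grid,
                              head = "dx", config, control = panfc_control(),
                              n_splits = 5L, train_fraction = 0.8, seed = 1L) {
  param <- match.arg(param)
  if (any(grid < 0 | grid > 1)) stop_panfc("grid values must lie in [0, 1]")
  rows <- list()
  for (v in grid) {
    cfg <- unclass(config)
    cfg[[param]] <- v
    if (cfg$identity_E) cfg$embed_dim <- 32L
    cfg <- do.call(panfc_config, cfg)
    cv <- panfc_cv(data, head = head, config = cfg, control = control,
                   n_splits = n_splits, train_fraction = train_fraction,
                   seed = seed)
    d <- cv$summary
    rows[[length(rows) + 1L]] <-
      data.frame(param = param, value = v, head = d$head,
                 accuracy_mean = d$accuracy_mean, accuracy_sd = d$accuracy_sd,
                 auc_mean = d$auc_mean, auc_sd = d$auc_sd)
  }
  do.call(rbind, rows)
}
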