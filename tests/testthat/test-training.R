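# Training objective, gradients, splits and the fitting loop.

test_that("class weights balance positive and negative mass", {
  # balanced head -> weight 1
  expect_equal(class_weights(matrix(c(1, 1, 0, 0), ncol = 1)), 1)
  # 72% positive -> 28/72
  y <- matrix(c(rep(1, 72), rep(0, 28)), ncol = 1)
  expect_equal(class_weights(y), 28 / 72)
  # counting oracle on random masked labels, per column
  set.seed(8)
  y <- matrix(rbinom(300, 1, 0.3), 100, 3)
  y[sample(300, 40)] <- NA
  w <- class_weights(y)
  for (j in 1:3) {
    obs <- y[, j][!is.na(y[, j])]
    expect_equal(w[j], sum(obs == 0) / sum(obs == 1))
  }
  # zero positives -> warning and weight 1
  expect_warning(w0 <- class_weights(matrix(c(0, 0, 0), ncol = 1)),
                 "no observed positives")
  expect_equal(w0, 1)
})

test_that("masked weighted BCE has its closed forms and masking contract", {
  # logit 0, label 1, weight 1 -> ln 2
  expect_equal(masked_weighted_bce(matrix(0), matrix(1))$loss, log(2))
  # balanced classes: weighted equals unweighted
  y <- matrix(c(1, 0, 1, 0), 2, 2)
  z <- matrix(rnorm(4), 2, 2)
  expect_equal(masked_weighted_bce(z, y, pos_weight = class_weights(y))$loss,
               masked_weighted_bce(z, y, pos_weight = 1)$loss,
               tolerance = 1e-10)
  # changing the value under a masked coordinate leaves loss and grad identical
  y2 <- matrix(c(1, NA, 0, 1, 0, NA), 2, 3)
  z2 <- matrix(rnorm(6), 2, 3)
  r_a <- masked_weighted_bce(z2, y2, pos_weight = c(1, 2, 0.5))
  y2b <- y2; y2b[is.na(y2)] <- 1
  r_b <- masked_weighted_bce(z2, y2b, pos_weight = c(1, 2, 0.5),
                             mask = !is.na(y2))
  expect_identical(r_a$loss, r_b$loss)
  expect_identical(r_a$grad, r_b$grad)
  expect_true(all(r_a$grad[is.na(y2)] == 0))
  # equality with the scalar double-loop implementation on a random batch
  set.seed(21)
  z3 <- matrix(rnorm(12), 4, 3)
  y3 <- matrix(rbinom(12, 1, 0.5), 4, 3)
  y3[c(2, 7)] <- NA
  pw <- c(0.4, 1, 2.5)
  expect_equal(masked_weighted_bce(z3, y3, pos_weight = pw)$loss,
               loop_bce(z3, y3, pw), tolerance = 1e-12)
  expect_error(masked_weighted_bce(z3, matrix(NA_real_, 4, 3)), "masked")
})

test_that("combined loss is the exact affine combination", {
  expect_equal(combined_loss(1.0, 0.5, 0.6)$L, 0.8)
  expect_equal(combined_loss(1.0, 0.5, 1)$L, 1.0)
  expect_equal(combined_loss(1.0, 0.5, 0)$L, 0.5)
  b <- combined_loss(2, 3, 0.25)
  expect_identical(b$L, 0.25 * b$L1 + 0.75 * b$L2)
})

test_that("analytic gradients match central finite differences", {
  variants <- list(
    full = list(),
    pearson = list(pearson_F = TRUE),
    identity = list(identity_E = TRUE),
    noreweight = list(no_reweighting = TRUE))
  for (vn in names(variants)) {
    cfg <- do.call(tiny_config, variants[[vn]])
    set.seed(11)
    params <- panfc_init_params(cfg)
    B <- 3L
    Xb <- matrix(rnorm(B * 4 * 16), B * 4, 16)
    Y <- matrix(rbinom(B * 3, 1, 0.5), B, 3)
    Y[1, 1] <- NA
    pw <- c(1.3, 1, 1)
    loss_of <- function(p) {
      fwd <- model_forward_batch(p, Xb, B, cfg, train = TRUE)
      if (cfg$no_reweighting)
        return(masked_weighted_bce(fwd$logits, Y, pos_weight = pw)$loss)
      r2 <- masked_weighted_bce(fwd$logits, Y, pos_weight = pw)
      c1f <- c_forward(p, t(matrix(fwd$s1, 16, B)), cfg, train = TRUE)
      r1 <- masked_weighted_bce(c1f$logits, Y, pos_weight = pw)
      cfg$lambda * r1$loss + (1 - cfg$lambda) * r2$loss
    }
    fwd <- model_forward_batch(params, Xb, B, cfg, train = TRUE)
    grads <- if (cfg$no_reweighting) {
      r1 <- masked_weighted_bce(fwd$logits, Y, pos_weight = pw)
      model_backward_batch(params, fwd, cfg, dlogits1 = r1$grad)
    } else {
      r2 <- masked_weighted_bce(fwd$logits, Y, pos_weight = pw)
      c1f <- c_forward(params, t(matrix(fwd$s1, 16, B)), cfg, train = TRUE)
      r1 <- masked_weighted_bce(c1f$logits, Y, pos_weight = pw)
      model_backward_batch(params, fwd, cfg,
                           dlogits1 = cfg$lambda * r1$grad,
                           dlogits2 = (1 - cfg$lambda) * r2$grad,
                           c1_cache = c1f$cache)
    }
    gvec <- par_unlist(grads)
    pvec <- par_unlist(params)
    expect_gt(max(abs(gvec)), 0)
    set.seed(31)
    idx <- sample(length(pvec), 25L)
    eps <- 1e-5
    num <- vapply(idx, function(i) {
      pp <- pvec; pp[i] <- pvec[i] + eps
      lp <- loss_of(par_relist(pp, params))
      pp[i] <- pvec[i] - eps
      (lp - loss_of(par_relist(pp, params))) / (2 * eps)
    }, numeric(1))
    rel <- abs(num - gvec[idx]) / pmax(1e-6, abs(num) + abs(gvec[idx]))
    expect_lt(max(rel), 1e-4)
  }
})

test_that("with lambda = 1 the gradient equals the first-path gradient", {
  cfg <- tiny_config(lambda = 1)
  set.seed(11)
  params <- panfc_init_params(cfg)
  B <- 3L
  Xb <- matrix(rnorm(B * 4 * 16), B * 4, 16)
  Y <- matrix(rbinom(9, 1, 0.5), 3, 3)
  fwd <- model_forward_batch(params, Xb, B, cfg, train = TRUE)
  c1f <- c_forward(params, t(matrix(fwd$s1, 16, B)), cfg, train = TRUE)
  r1 <- masked_weighted_bce(c1f$logits, Y)
  g_L <- model_backward_batch(params, fwd, cfg, dlogits1 = 1 * r1$grad,
                              dlogits2 = NULL, c1_cache = c1f$cache)
  # L1-only gradient, computed without any second-path contribution
  g_L1 <- model_backward_batch(params, fwd, cfg, dlogits1 = r1$grad,
                               c1_cache = c1f$cache)
  expect_equal(par_unlist(g_L), par_unlist(g_L1), tolerance = 1e-14)
})

test_that("cross-validation splits are disjoint, sized and reproducible", {
  ids <- sprintf("s%02d", 1:10)
  sp <- make_cv_splits(ids, n_splits = 4L, train_fraction = 0.8, seed = 2L)
  expect_length(sp, 4L)
  for (s in sp) {
    expect_length(s$train, 8L)
    expect_length(s$test, 2L)
    expect_length(intersect(s$train, s$test), 0L)
    expect_setequal(c(s$train, s$test), ids)
  }
  expect_identical(sp, make_cv_splits(ids, 4L, 0.8, seed = 2L))
  # full-cohort scale: 160 subjects -> 128 train / 32 test
  sp160 <- make_cv_splits(sprintf("s%03d", 1:160), 5L, 0.8, seed = 1L)
  expect_length(sp160[[1]]$train, 128L)
  expect_length(sp160[[1]]$test, 32L)
  expect_error(make_cv_splits(ids[1:3]), "at least 5")
})

test_that("training decreases the loss and is seed-reproducible", {
  cohort <- small_cohort(n_subjects = 24L, effect = 2,
                         prevalence_t1 = 0.5, prevalence_t2 = 0.5,
                         prevalence_t3 = 0.5, dropout_t2 = 0, dropout_t3 = 0)
  cfg <- panfc_config(n_regions = 6L, n_timepoints = 32L, embed_dim = 4L,
                      head_size = 3L, conv_filters = c(2, 2, 4, 4, 4, 4),
                      f_hidden = c(8, 4), c_hidden = c(10, 6), dropout = 0.1)
  ctl <- panfc_control(epochs = 8L, batch_size = 8L, learning_rate = 1e-3,
                       seed = 7L)
  fit <- panfc_fit(cohort, head = "dx", config = cfg, control = ctl)
  h <- fit$history
  expect_identical(nrow(h), 8L)
  expect_true(all(is.finite(h$loss)))
  # smoothed trend: second half no worse than the first
  expect_lte(mean(h$loss[5:8]), mean(h$loss[1:4]) + 1e-6)
  # bit-identical reproduction under the same seed
  fit2 <- panfc_fit(cohort, head = "dx", config = cfg, control = ctl)
  expect_identical(fit$history, fit2$history)
  expect_identical(par_unlist(fit$params), par_unlist(fit2$params))
})

test_that("learning-rate schedule decays by the configured factor", {
  cohort <- small_cohort(n_subjects = 12L)
  cfg <- panfc_config(n_regions = 6L, n_timepoints = 32L, embed_dim = 3L,
                      head_size = 3L, conv_filters = c(2, 2, 2, 2, 2, 2),
                      f_hidden = c(4, 3), c_hidden = c(6, 4), dropout = 0)
  ctl <- panfc_control(epochs = 5L, batch_size = 6L, learning_rate = 1e-3,
                       lr_decay_every = 2L, lr_decay_factor = 10, seed = 1L)
  fit <- panfc_fit(cohort, head = "dx", config = cfg, control = ctl)
  expect_equal(fit$history$lr, 1e-3 / 10^floor((0:4) / 2))
})

test_that("severity regression beats the mean predictor on held-out data", {
  cohort <- small_cohort(n_subjects = 40L, effect = 2.5,
                         prevalence_t1 = 0.5, prevalence_t2 = 0.5,
                         prevalence_t3 = 0.5, dropout_t2 = 0, dropout_t3 = 0)
  ds <- cohort$dataset
  cfg <- panfc_config(n_regions = 6L, n_timepoints = 32L, embed_dim = 4L,
                      head_size = 3L, conv_filters = c(2, 2, 4, 4, 4, 4),
                      f_hidden = c(8, 4), c_hidden = c(10, 6), dropout = 0,
                      regression_mode = TRUE, pearson_F = TRUE,
                      identity_E = TRUE)
  ctl <- panfc_control(epochs = 40L, batch_size = 10L, learning_rate = 3e-3,
                       seed = 2L)
  sp <- make_cv_splits(ds$subject_ids, n_splits = 1L, seed = 4L)[[1]]
  fit <- panfc_fit(ds, head = "caps", config = cfg, control = ctl,
                   subset = sp$train)
  pred <- predict(fit, ds, subset = sp$test)
  obs <- as.matrix(ds$labels[match(rownames(pred), ds$labels$subject_id),
                             paste0("caps_t", 1:3)])
  # competitor: the training-set mean per time-point
  mu <- fit$caps_scaler$mean
  mse_fit <- mean((pred - obs)^2, na.rm = TRUE)
  mse_mean <- mean((matrix(mu, nrow(obs), 3, byrow = TRUE) - obs)^2,
                   na.rm = TRUE)
  expect_lt(mse_fit, mse_mean)
  # residuals are observed minus predicted on the original scale
  res <- residuals(fit, ds)
  expect_equal(res[rownames(pred), ], obs - pred, ignore_attr = TRUE)
})

test_that("a diverging configuration aborts with diagnostics", {
  cohort <- small_cohort(n_subjects = 12L)
  cfg <- panfc_config(n_regions = 6L, n_timepoints = 32L, embed_dim = 3L,
                      head_size = 3L, conv_filters = c(2, 2, 2, 2, 2, 2),
                      f_hidden = c(4, 3), c_hidden = c(6, 4), dropout = 0,
                      regression_mode = TRUE)
  # an absurd step size overflows the squared-error loss within an epoch
  ctl <- panfc_control(epochs = 3L, batch_size = 6L, learning_rate = 1e100,
                       seed = 1L)
  expect_error(panfc_fit(cohort, head = "caps", config = cfg, control = ctl),
               "diverged")
})
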