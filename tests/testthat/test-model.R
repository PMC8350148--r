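# Forward-pass operations of the pairwise-attention network.

test_that("attention weights follow the aggregation formula", {
  # fixture with off-diagonal row sums (0.75, 1.5, 1.25)
  K <- rbind(c(0.9, 0.50, 0.25),
             c(0.7, 0.1, 0.80),
             c(0.65, 0.60, 0.4))
  expect_equal(attention_weights(K, beta = 0.9), c(0.975, 1.05, 1.025),
               tolerance = 1e-12)
  # degenerate cases: all-zero scores give the floor, beta = 1 gives ones
  expect_equal(attention_weights(matrix(0, 5, 5), 0.3), rep(0.3, 5))
  expect_equal(attention_weights(matrix(runif(16), 4, 4), 1), rep(1, 4))
  expect_error(attention_weights(K, 1.2), "beta")
})

test_that("region embedding is shared across regions and shaped N x d", {
  cfg <- tiny_config()
  params <- tiny_params(cfg)
  x <- random_subject(cfg)
  x[2, ] <- x[1, ]                     # identical series
  emb <- embed_regions(x, params, cfg)
  expect_identical(dim(emb), c(4L, 3L))
  expect_equal(emb[1, ], emb[2, ])     # shared parameters => same embedding
  expect_true(all(is.finite(emb)))
})

test_that("identity extractor returns the raw series", {
  cfg <- tiny_config(identity_E = TRUE)
  params <- tiny_params(cfg)
  x <- random_subject(cfg)
  expect_equal(cfg$embed_dim, cfg$n_timepoints)
  expect_equal(embed_regions(x, params, cfg), x, ignore_attr = TRUE)
})

test_that("series too short for the four poolings is rejected", {
  expect_error(tiny_config(n_timepoints = 8L), "T >= 16")
  expect_silent(tiny_config(n_timepoints = 16L))
  cfg <- tiny_config()
  params <- tiny_params(cfg)
  expect_error(embed_regions(matrix(rnorm(4 * 8), 4, 8), params, cfg),
               "length")
})

test_that("default architecture produces the reference shapes", {
  cfg <- panfc_config(n_regions = 117L, n_timepoints = 300L)
  params <- panfc_init_params(cfg, seed = 1L)
  x <- matrix(rnorm(117 * 300), 117, 300)
  emb <- embed_regions(x, params, cfg)
  expect_identical(dim(emb), c(117L, 32L))
  # classifier reads the flattened 117^2 matrix through a width-100 layer
  expect_identical(dim(params$C$l1$W), c(13689L, 100L))
})

test_that("head size controls the number of logits", {
  for (l in c(1L, 3L, 20L)) {
    cfg <- tiny_config(head_size = l)
    fw <- panfc_forward(random_subject(cfg), tiny_params(cfg), cfg)
    expect_length(fw$logits, l)
  }
  expect_error(tiny_config(head_size = 5L), "head_size")
})

test_that("batched pairwise connectivity matches the pair-loop oracle", {
  for (seed in 1:3) {
    cfg <- tiny_config(n_regions = 5L, embed_dim = 4L)
    params <- tiny_params(cfg, seed = seed)
    set.seed(seed + 100)
    emb <- matrix(rnorm(20), 5, 4)
    K <- pairwise_connectivity(emb, params, cfg)
    expect_equal(K, loop_connectivity(emb, params, cfg), tolerance = 1e-12)
    expect_true(all(K > 0 & K < 1))
  }
})

test_that("constant embeddings give a constant connectivity matrix", {
  cfg <- tiny_config()
  params <- tiny_params(cfg)
  emb <- matrix(1, 4, 3)
  K <- pairwise_connectivity(emb, params, cfg)
  expect_equal(max(K) - min(K), 0)
})

test_that("Pearson ablation equals the closed-form sample correlation", {
  cfg <- tiny_config(pearson_F = TRUE, embed_dim = 6L)
  params <- tiny_params(cfg)
  set.seed(4)
  emb <- matrix(rnorm(24), 4, 6)
  K <- pairwise_connectivity(emb, params, cfg)
  # hand-coded formula
  for (i in 1:4) for (j in 1:4) {
    a <- emb[i, ] - mean(emb[i, ]); b <- emb[j, ] - mean(emb[j, ])
    expect_equal(K[i, j], sum(a * b) / sqrt(sum(a^2) * sum(b^2)),
                 tolerance = 1e-10)
  }
})

test_that("reweighting scales rows and composes with F as the update formula", {
  cfg <- tiny_config()
  params <- tiny_params(cfg)
  emb <- matrix(rnorm(12), 4, 3)
  expect_equal(reweight_embeddings(emb, rep(1, 4)), emb)
  out <- reweight_embeddings(emb[1:2, ], c(2, 0))
  expect_equal(out[1, ], 2 * emb[1, ])
  expect_equal(out[2, ], rep(0, 3))
  # k'_ij = F([w_i e_i, w_j e_j]) via the loop oracle
  w <- c(0.9, 1.1, 1.4, 1.05)
  K2 <- pairwise_connectivity(reweight_embeddings(emb, w), params, cfg)
  expect_equal(K2, loop_connectivity(emb * w, params, cfg), tolerance = 1e-12)
})

test_that("beta = 1 collapses the updated matrix onto the first one", {
  for (seed in 1:50) {
    cfg <- tiny_config(beta = 1)
    params <- tiny_params(cfg, seed = seed)
    fw <- panfc_forward(random_subject(cfg, seed = seed), params, cfg)
    expect_equal(fw$Kprime, fw$K, tolerance = 1e-12)
  }
})

test_that("forward pass returns consistent intermediates and weight bounds", {
  cfg <- tiny_config(n_regions = 6L)
  params <- tiny_params(cfg)
  x <- random_subject(cfg)
  fw <- panfc_forward(x, params, cfg)
  N <- 6L
  expect_identical(dim(fw$K), c(N, N))
  expect_identical(dim(fw$Kprime), c(N, N))
  N <- 6
  expect_true(all(fw$K > 0 & fw$K < 1))
  expect_length(fw$hidden, cfg$c_hidden[1])
  expect_true(all(fw$weights >= cfg$beta - 1e-12))
  expect_true(all(fw$weights <= cfg$beta + (1 - cfg$beta) * (N - 1) + 1e-12))
  expect_equal(fw$weights, attention_weights(fw$K, cfg$beta), tolerance = 1e-12)
  expect_equal(fw$Kprime,
               pairwise_connectivity(
                 reweight_embeddings(fw$embeddings, fw$weights), params, cfg),
               tolerance = 1e-12)
})

test_that("no-reweighting ablation classifies on the first matrix", {
  cfg <- tiny_config(no_reweighting = TRUE)
  params <- tiny_params(cfg)
  fw <- panfc_forward(random_subject(cfg), params, cfg)
  expect_null(fw$Kprime)
  expect_length(fw$logits, 3L)
})

test_that("permuting regions permutes K, K' and the weights covariantly", {
  cfg <- tiny_config(n_regions = 5L)
  params <- tiny_params(cfg)
  x <- random_subject(cfg)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  fw <- panfc_forward(x, params, cfg)
  fwp <- panfc_forward(x[perm, ], params, cfg)
  expect_equal(fwp$K, fw$K[perm, perm], tolerance = 1e-12)
  expect_equal(fwp$Kprime, fw$Kprime[perm, perm], tolerance = 1e-12)
  expect_equal(fwp$weights, fw$weights[perm], tolerance = 1e-12)
})
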