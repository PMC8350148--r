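# Shared fixtures: tiny configurations and small synthetic datasets, all
# built in code at test time.

tiny_config <- function(...) {
  args <- list(n_regions = 4L, n_timepoints = 16L, embed_dim = 3L,
               head_size = 3L, conv_filters = c(2L, 2L, 3L, 3L, 3L, 3L),
               f_hidden = c(4L, 3L), c_hidden = c(9L, 7L), dropout = 0)
  do.call(panfc_config, utils::modifyList(args, list(...)))
}

tiny_params <- function(config, seed = 11L) panfc_init_params(config, seed = seed)

random_subject <- function(config, seed = 1L) {
  set.seed(seed)
  m <- matrix(rnorm(config$n_regions * config$n_timepoints),
              config$n_regions, config$n_timepoints)
  rownames(m) <- paste0("region_", seq_len(config$n_regions))
  m
}

small_cohort <- function(n_subjects = 30L, n_regions = 6L, t_len = 32L,
                         effect = 0, seed = 3L, ...) {
  simulate_cohort(cohort_config(
    n_subjects = n_subjects, n_regions = n_regions,
    n_timepoints_signal = t_len, planted_pairs = rbind(c(1L, 2L)),
    effect_strength = effect, seed = seed, ...))
}

# brute-force loop evaluation of F on each ordered pair of embedding rows
loop_connectivity <- function(emb, params, config) {
  N <- nrow(emb)
  K <- matrix(NA_real_, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      u <- matrix(c(emb[i, ], emb[j, ]), nrow = 1L)
      if (config$pearson_F) {
        K[i, j] <- suppressWarnings(stats::cor(emb[i, ], emb[j, ]))
      } else {
        h1 <- pmax(u %*% params$F$l1$W + rep(params$F$l1$b, each = 1L), 0)
        h2 <- pmax(h1 %*% params$F$l2$W + rep(params$F$l2$b, each = 1L), 0)
        z <- h2 %*% params$F$l3$W + params$F$l3$b
        K[i, j] <- 1 / (1 + exp(-z))
      }
    }
  }
  K
}

# independent scalar implementation of the masked weighted BCE
loop_bce <- function(logits, y, pw) {
  tot <- 0; n_obs <- 0L
  for (i in seq_len(nrow(y))) {
    for (j in seq_len(ncol(y))) {
      if (is.na(y[i, j])) next
      p <- 1 / (1 + exp(-logits[i, j]))
      tot <- tot + if (y[i, j] == 1) -pw[j] * log(p) else -log(1 - p)
      n_obs <- n_obs + 1L
    }
  }
  tot / n_obs
}

# brute-force Benjamini-Hochberg step-up adjusted p-values
bh_bruteforce <- function(p) {
  m <- length(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    ri <- sum(p <= p[i])                   # rank with max-tie convention
    cand <- vapply(seq_len(m), function(k) {
      rk <- sum(p <= p[k])
      if (p[k] >= p[i]) m * p[k] / rk else Inf
    }, numeric(1))
    adj[i] <- min(1, min(cand))
  }
  adj
}

# brute-force DSM-5 cluster rule on one 20-bit vector
clusters_bruteforce <- function(v) {
  c(B = as.integer(sum(v[1:5]) >= 1L),
    C = as.integer(sum(v[6:7]) >= 1L),
    D = as.integer(sum(v[8:14]) >= 2L),
    E = as.integer(sum(v[15:20]) >= 2L))
}
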