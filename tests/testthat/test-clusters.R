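# DSM-5 cluster mapping, dominance, features and the survival task.

test_that("cluster mapping applies the minimum-count rules", {
  expect_equal(symptoms_to_clusters(rep(0L, 20L)),
               c(B = 0L, C = 0L, D = 0L, E = 0L))
  # one B symptom and one D symptom: B met, D needs two
  v <- rep(0L, 20L); v[1] <- 1L; v[8] <- 1L
  expect_equal(symptoms_to_clusters(v), c(B = 1L, C = 0L, D = 0L, E = 0L))
  expect_error(symptoms_to_clusters(rep(0L, 19L)), "20")
  expect_error(symptoms_to_clusters(c(rep(0L, 19L), 2L)), "0/1")
})

test_that("cluster mapping agrees with brute force on 1000 random vectors", {
  set.seed(14)
  V <- matrix(rbinom(20000, 1L, runif(20000, 0.05, 0.6)), 1000, 20)
  got <- symptoms_to_clusters(V)
  want <- t(apply(V, 1, clusters_bruteforce))
  expect_identical(unname(got), unname(want))
})

test_that("cluster mapping is monotone under symptom addition", {
  set.seed(15)
  for (r in 1:200) {
    v <- rbinom(20, 1, 0.3)
    cl <- symptoms_to_clusters(v)
    off <- which(v == 0)
    if (!length(off)) next
    v2 <- v; v2[sample(off, 1)] <- 1L
    cl2 <- symptoms_to_clusters(v2)
    expect_true(all(cl2 >= cl))
  }
})

test_that("dominance handles ties, unique maxima and planted profiles", {
  # one subject meets everything, the rest nothing: four tied percentiles
  S <- rbind(rep(1L, 20L), matrix(0L, 5, 20))
  dom <- dominant_cluster(S)
  expect_true(is.na(dom$dominant[1]))
  # a subject uniquely maxing cluster C
  S2 <- matrix(0L, 6, 20)
  S2[1, 6:7] <- 1L
  dom2 <- dominant_cluster(S2)
  expect_identical(as.character(dom2$dominant[1]), "C")
  # planted single-cluster profiles are recovered
  set.seed(16)
  crit <- cluster_criteria()
  n_per <- 30L
  S3 <- NULL; truth <- NULL
  for (q in 1:4) {
    block <- matrix(rbinom(n_per * 20L, 1L, 0.05), n_per, 20L)
    idx <- crit$from[q]:crit$to[q]
    block[, idx] <- rbinom(n_per * length(idx), 1L, 0.9)
    S3 <- rbind(S3, block)
    truth <- c(truth, rep(crit$cluster[q], n_per))
  }
  dom3 <- dominant_cluster(S3)
  recovered <- mean(as.character(dom3$dominant) == truth, na.rm = TRUE)
  expect_gte(recovered, 0.9)
  # scores are the met fraction
  expect_equal(dom3$score_B, rowMeans(S3[, 1:5]))
})

test_that("dominance is invariant to subject relabeling", {
  set.seed(17)
  S <- matrix(rbinom(20 * 20, 1, 0.4), 20, 20)
  perm <- sample(20)
  d1 <- dominant_cluster(S)
  d2 <- dominant_cluster(S[perm, ])
  expect_equal(d2$pct_B, d1$pct_B[perm])
  expect_identical(as.character(d2$dominant), as.character(d1$dominant)[perm])
})

test_that("hidden features have the configured width and are deterministic", {
  cohort <- small_cohort(n_subjects = 12L, prevalence_t1 = 0.6,
                         prevalence_t2 = 0.5, prevalence_t3 = 0.4,
                         dropout_t2 = 0, dropout_t3 = 0)
  ds <- cohort$dataset
  # duplicate one subject's series under a new id
  ds2 <- ds
  ds2$subjects <- c(ds$subjects, list(dup01 = ds$subjects[[1]]))
  lab <- ds$labels
  lab2 <- rbind(lab, transform(lab[1, ], subject_id = "dup01"))
  ds2 <- panfc_dataset(ds2$subjects, lab2, ds$region_names)
  cfg <- panfc_config(n_regions = 6L, n_timepoints = 32L, embed_dim = 3L,
                      head_size = 20L, conv_filters = c(2, 2, 2, 2, 2, 2),
                      f_hidden = c(4, 3), c_hidden = c(100, 6), dropout = 0)
  ctl <- panfc_control(epochs = 2L, batch_size = 6L, seed = 1L)
  fit <- panfc_fit(ds2, head = "symptoms", timepoint = 1L, config = cfg,
                   control = ctl)
  feats <- extract_hidden_features(fit, ds2)
  expect_identical(ncol(feats), 100L)
  expect_equal(feats["dup01", ], feats[ds$subject_ids[1], ])
})

test_that("2-D embedding keeps duplicated points coincident", {
  set.seed(18)
  X <- matrix(rnorm(30 * 8), 30, 8)
  X[30, ] <- X[1, ]              # exact duplicate
  Y <- embed_2d(X, seed = 1L, perplexity = 5, n_iter = 120L)
  expect_identical(dim(Y), c(30L, 2L))
  expect_lt(max(abs(Y[30, ] - Y[1, ])), 1e-8)
  # nearby feature clusters stay closer than far ones
  A <- matrix(rnorm(40 * 6, mean = 0), 40, 6)
  A[21:40, 1] <- A[21:40, 1] + 12
  Y2 <- embed_2d(A, seed = 2L, perplexity = 8, n_iter = 200L)
  within <- mean(dist(Y2[1:20, ])) + mean(dist(Y2[21:40, ]))
  between <- mean(as.matrix(dist(Y2))[1:20, 21:40])
  expect_gt(between, within / 2)
})

test_that("survival task selects t1-positive subjects with observed t3", {
  cohort <- small_cohort(n_subjects = 60L, prevalence_t1 = 0.7,
                         prevalence_t2 = 0.5, prevalence_t3 = 0.3,
                         dropout_t2 = 0.2, dropout_t3 = 0.1, seed = 6L)
  ds <- cohort$dataset
  task <- build_survival_task(ds)
  lab <- ds$labels
  want <- lab$subject_id[!is.na(lab$dx_t1) & lab$dx_t1 == 1L &
                           !is.na(lab$dx_t3)]
  expect_identical(task$subject_ids, want)
  # labels: still positive at t3 -> 1, remitted -> 0
  expect_identical(unname(task$labels),
                   lab$dx_t3[match(want, lab$subject_id)])
  # a subject with masked t3 is excluded
  masked <- lab$subject_id[is.na(lab$dx_t3) & lab$dx_t1 == 1L]
  expect_length(intersect(task$subject_ids, masked), 0L)
})
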