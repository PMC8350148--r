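# Synthetic cohort generator.

test_that("identical config and seed give byte-identical cohorts", {
  cfg <- cohort_config(n_subjects = 10L, n_regions = 5L,
                       n_timepoints_signal = 40L, planted_pairs = rbind(c(1, 2)),
                       effect_strength = 1, seed = 77L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$dataset$subjects, b$dataset$subjects)
  expect_identical(a$dataset$labels, b$dataset$labels)
  expect_identical(a$trajectory, b$trajectory)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_cohort(cohort_config(n_subjects = 6L, n_regions = 3L,
                                          n_timepoints_signal = 20L,
                                          planted_pairs = rbind(c(1, 2)))))
  expect_identical(runif(1), before)
})

test_that("configuration errors are caught", {
  expect_error(cohort_config(planted_pairs = rbind(c(0, 2))), "out of range")
  expect_error(cohort_config(planted_pairs = rbind(c(5, 2))), "i < j")
  expect_error(cohort_config(n_regions = 10, planted_pairs = rbind(c(1, 11))),
               "out of range")
  expect_error(cohort_config(planted_pairs = rbind(c(1, 2), c(1, 2))),
               "distinct")
  expect_error(cohort_config(prevalence_t1 = 1.2), "prevalence_t1")
  expect_error(cohort_config(prevalence_t1 = 0.2, prevalence_t2 = 0.5,
                             prevalence_t3 = 0.1), "remission")
})

test_that("realized t1 prevalence is inside the binomial 99% interval of 72%", {
  cfg <- cohort_config(n_subjects = 200L, n_regions = 4L,
                       n_timepoints_signal = 24L, planted_pairs = rbind(c(1, 2)),
                       prevalence_t1 = 0.72, seed = 11L)
  cohort <- simulate_cohort(cfg)
  k <- sum(cohort$dataset$labels$dx_t1)
  ci <- qbinom(c(0.005, 0.995), 200L, 0.72)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("marginal prevalences converge to the configuration at n = 2000", {
  cfg <- cohort_config(n_subjects = 2000L, n_regions = 2L,
                       n_timepoints_signal = 20L, planted_pairs = rbind(c(1, 2)),
                       prevalence_t1 = 0.72, prevalence_t2 = 0.29,
                       prevalence_t3 = 0.23, dropout_t2 = 0, dropout_t3 = 0,
                       seed = 5L)
  lab <- simulate_cohort(cfg)$dataset$labels
  expect_lt(abs(mean(lab$dx_t1) - 0.72), 0.03)
  expect_lt(abs(mean(lab$dx_t2) - 0.29), 0.03)
  expect_lt(abs(mean(lab$dx_t3) - 0.23), 0.03)
})

test_that("diagnosis trajectories follow the remission pattern", {
  cohort <- small_cohort(n_subjects = 60L, dropout_t2 = 0, dropout_t3 = 0)
  lab <- cohort$dataset$labels
  # monotone: positive at t2 implies positive at t1; t3 implies t2
  expect_true(all(lab$dx_t1[lab$dx_t2 == 1] == 1))
  expect_true(all(lab$dx_t2[lab$dx_t3 == 1] == 1))
  expect_identical(cohort$chronic, lab$dx_t3 == 1)
  # persistence label defined exactly on t1-positive subjects
  expect_identical(is.na(lab$persists_t3), lab$dx_t1 == 0L)
})

test_that("planted coupling shows up in the planted pair and only there", {
  # 5 regions, pair (1,2), strong effect, no autocorrelation: the group
  # difference in sample correlation must exceed that of all other pairs,
  # checked against a brute-force correlation over all 10 pairs
  cfg <- cohort_config(n_subjects = 80L, n_regions = 5L,
                       n_timepoints_signal = 100L,
                       planted_pairs = rbind(c(1L, 2L)), effect_strength = 2,
                       ar_coefficient = 0, prevalence_t1 = 0.5,
                       prevalence_t2 = 0.5, prevalence_t3 = 0.5,
                       dropout_t2 = 0, dropout_t3 = 0, seed = 21L)
  cohort <- simulate_cohort(cfg)
  ds <- cohort$dataset
  pairs <- which(upper.tri(matrix(0, 5, 5)), arr.ind = TRUE)
  diffs <- apply(pairs, 1, function(pr) {
    r <- vapply(ds$subject_ids, function(id) {
      stats::cor(ds$subjects[[id]][pr[1], ], ds$subjects[[id]][pr[2], ])
    }, numeric(1))
    abs(mean(r[cohort$chronic]) - mean(r[!cohort$chronic]))
  })
  planted_row <- which(pairs[, 1] == 1 & pairs[, 2] == 2)
  expect_identical(which.max(diffs), planted_row)
  expect_gt(diffs[planted_row], 0.5)
  # z-scoring removes marginal amplitude differences
  v <- vapply(ds$subject_ids, function(id) var(ds$subjects[[id]][1, ]),
              numeric(1))
  expect_equal(unname(v), rep(1, 80), tolerance = 1e-9)
})

test_that("zero effect leaves planted-pair correlations at the null", {
  pvals <- vapply(1:25, function(r) {
    cohort <- small_cohort(n_subjects = 40L, effect = 0, seed = 100L + r,
                           prevalence_t1 = 0.5, prevalence_t2 = 0.4,
                           prevalence_t3 = 0.3, dropout_t2 = 0, dropout_t3 = 0)
    ds <- cohort$dataset
    rho <- vapply(ds$subject_ids, function(id)
      stats::cor(ds$subjects[[id]][1, ], ds$subjects[[id]][2, ]), numeric(1))
    if (sum(cohort$chronic) < 2 || sum(!cohort$chronic) < 2) return(NA_real_)
    stats::t.test(rho[cohort$chronic], rho[!cohort$chronic])$p.value
  }, numeric(1))
  pvals <- pvals[!is.na(pvals)]
  # p-values behave like a null sample: no excess of small values
  expect_lte(sum(pvals < 0.05), qbinom(0.995, length(pvals), 0.05))
})

test_that("every diagnosed subject satisfies all four cluster rules", {
  cohort <- small_cohort(n_subjects = 80L, dropout_t2 = 0.2, dropout_t3 = 0.2)
  lab <- cohort$dataset$labels
  for (tp in 1:3) {
    dxp <- which(!is.na(lab[[paste0("dx_t", tp)]]) &
                   lab[[paste0("dx_t", tp)]] == 1L)
    sym <- as.matrix(lab[dxp, paste0("sym_t", tp, "_",
                                     c(paste0("b", 1:5), paste0("c", 1:2),
                                       paste0("d", 1:7), paste0("e", 1:6)))])
    cl <- symptoms_to_clusters(sym)
    expect_true(all(cl == 1L))
  }
})

test_that("severity scores are monotone in diagnosis on average", {
  cohort <- small_cohort(n_subjects = 300L, dropout_t2 = 0, dropout_t3 = 0,
                         seed = 9L)
  lab <- cohort$dataset$labels
  for (tp in 1:3) {
    caps <- lab[[paste0("caps_t", tp)]]
    dx <- lab[[paste0("dx_t", tp)]]
    expect_gt(mean(caps[dx == 1]), mean(caps[dx == 0]))
  }
})
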