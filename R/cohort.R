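# Synthetic cohort generator.
#
# The generator emulates the statistical structure the model and the edge
# statistics assume: stationary AR(1) regional signals, group-dependent
# coupling confined to a planted set of region pairs (a shared latent signal
# injected into both members of each pair for chronic cases, so the group
# signal lives purely in pairwise coupling, not in marginal amplitude once
# series are z-scored), longitudinal diagnosis trajectories with a remission
# pattern, DSM-5-consistent symptom vectors, severity scores monotone in
# diagnosis, and monotone longitudinal dropout.

#' Configuration of a synthetic cohort
#'
#' Defaults mirror a typical acute-trauma cohort: 160 subjects, 117 regions, 300 signal
#' samples, diagnosis prevalences 72% / 29% / 23% at the three time-points,
#' dropout 25/160 between t1 and t2 and 5/135 more between t2 and t3.
#'
#' @param n_subjects number of subjects.
#' @param n_regions number of parcellated regions.
#' @param n_timepoints_signal samples per regional series (T).
#' @param prevalence_t1,prevalence_t2,prevalence_t3 diagnosis prevalences;
#'   under the remission pattern they must be non-increasing.
#' @param planted_pairs two-column matrix (or list of length-2 vectors) of
#'   1-based region index pairs `i < j` carrying group-dependent coupling;
#'   `NULL` draws `n_planted` distinct pairs at random (seeded).
#' @param n_planted number of pairs drawn when `planted_pairs` is `NULL`.
#' @param effect_strength gain of the shared latent signal injected into
#'   both members of each planted pair for chronic cases (0 = no effect; the
#'   planted-pair correlation for chronic cases is
#'   `effect_strength^2 / (1 + effect_strength^2)`).
#' @param ar_coefficient AR(1) coefficient of every signal component, in
#'   (-1, 1).
#' @param noise_sd innovation standard deviation of the regional AR noise.
#' @param dropout_t2 probability a subject is lost to follow-up at t2 (and
#'   hence also at t3: dropout is monotone).
#' @param dropout_t3 probability a t2-observed subject is lost at t3.
#' @param remission_pattern if `TRUE` (default) diagnoses follow the
#'   monotone trajectory control / remit-early / remit-late / chronic; if
#'   `FALSE` the three diagnoses are drawn independently and "chronic" means
#'   positive at all three time-points.
#' @param standardize z-score each regional series before returning
#'   (mirroring standard practice; `FALSE` keeps the raw scale).
#' @param amplitude_confound optional extra marginal-variance factor applied
#'   to chronic cases' planted regions (default 1 = none), for studying
#'   amplitude-driven shortcuts.
#' @param seed integer seed; cohorts are byte-identical given the same
#'   configuration and seed.
#' @return object of class `"panfc_cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 160L, n_regions = 117L,
                          n_timepoints_signal = 300L,
                          prevalence_t1 = 0.72, prevalence_t2 = 0.29,
                          prevalence_t3 = 0.23,
                          planted_pairs = NULL, n_planted = 10L,
                          effect_strength = 1.5,
                          ar_coefficient = 0.3, noise_sd = 1,
                          dropout_t2 = 25 / 160, dropout_t3 = 5 / 135,
                          remission_pattern = TRUE,
                          standardize = TRUE,
                          amplitude_confound = 1,
                          seed = 1L) {
  check_number(n_subjects, "n_subjects", lower = 4, integer = TRUE)
  check_number(n_regions, "n_regions", lower = 2, integer = TRUE)
  check_number(n_timepoints_signal, "n_timepoints_signal", lower = 2,
               integer = TRUE)
  for (nm in c("prevalence_t1", "prevalence_t2", "prevalence_t3",
               "dropout_t2", "dropout_t3")) {
    check_number(get(nm), nm, lower = 0, upper = 1)
  }
  check_number(effect_strength, "effect_strength", lower = 0)
  check_number(ar_coefficient, "ar_coefficient", lower = -0.999, upper = 0.999)
  check_number(noise_sd, "noise_sd", lower = 1e-12)
  check_number(seed, "seed", integer = TRUE)
  if (isTRUE(remission_pattern) &&
      !(prevalence_t3 <= prevalence_t2 && prevalence_t2 <= prevalence_t1))
    stop_panfc("remission pattern needs prevalence_t3 <= prevalence_t2 <= prevalence_t1")

  if (!is.null(planted_pairs)) {
    pp <- if (is.matrix(planted_pairs)) planted_pairs
          else do.call(rbind, planted_pairs)
    if (ncol(pp) != 2L) stop_panfc("'planted_pairs' must be pairs of region indices")
    if (any(pp < 1 | pp > n_regions))
      stop_panfc("planted pair index out of range 1..n_regions")
    if (any(pp[, 1L] >= pp[, 2L]))
      stop_panfc("planted pairs must satisfy i < j")
    if (anyDuplicated(paste(pp[, 1L], pp[, 2L])))
      stop_panfc("planted pairs must be distinct")
    planted_pairs <- unname(pp)
  } else {
    check_number(n_planted, "n_planted", lower = 0, integer = TRUE)
    if (n_planted > n_regions * (n_regions - 1) / 2)
      stop_panfc("n_planted exceeds the number of region pairs")
  }

  cfg <- list(n_subjects = as.integer(n_subjects),
              n_regions = as.integer(n_regions),
              n_timepoints_signal = as.integer(n_timepoints_signal),
              prevalence_t1 = prevalence_t1, prevalence_t2 = prevalence_t2,
              prevalence_t3 = prevalence_t3,
              planted_pairs = planted_pairs, n_planted = as.integer(n_planted),
              effect_strength = effect_strength,
              ar_coefficient = ar_coefficient, noise_sd = noise_sd,
              dropout_t2 = dropout_t2, dropout_t3 = dropout_t3,
              remission_pattern = isTRUE(remission_pattern),
              standardize = isTRUE(standardize),
              amplitude_confound = amplitude_confound,
              seed = as.integer(seed))
  class(cfg) <- "panfc_cohort_config"
  cfg
}

# stationary AR(1): x_t = phi x_{t-1} + eps, eps ~ N(0, sd^2),
# x_0 drawn from the stationary distribution
ar1_series <- function(n_series, t_len, phi, sd) {
  innov <- matrix(stats::rnorm(n_series * t_len, sd = sd), n_series, t_len)
  out <- innov
  out[, 1L] <- innov[, 1L] / sqrt(1 - phi^2)
  if (t_len > 1L) {
    for (t in 2:t_len) out[, t] <- phi * out[, t - 1L] + innov[, t]
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws a cohort under a [cohort_config()]. Subject trajectories are
#' control / remit-early (diagnosed at t1 only) / remit-late (t1 and t2) /
#' chronic (all three time-points) with probabilities chosen so the marginal
#' prevalences match the configuration. Chronic cases carry the planted
#' pairwise coupling: each planted pair shares its own latent AR(1) signal,
#' injected into both member regions with gain `effect_strength`. A latent
#' chronicity severity drives both the severity scores and the persistence
#' label, so the survival head has learnable signal. Diagnosed subjects'
#' 20-bit symptom vectors always satisfy the four DSM-5 cluster criteria
#' (B >= 1 of 5, C >= 1 of 2, D >= 2 of 7, E >= 2 of 6); non-diagnosed
#' subjects carry sub-threshold symptom noise. Dropout is monotone and all
#' entries of a dropped time-point are unobserved (`NA`).
#'
#' @param config a [cohort_config()].
#' @return object of class `"panfc_cohort"`: a list with `dataset` (a
#'   [panfc_dataset()]), `config`, `planted_pairs` (realized set), and
#'   per-subject ground truth `trajectory` ("control", "remit_early",
#'   "remit_late", "chronic") and `chronic`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "panfc_cohort_config"))
    stop_panfc("'config' must come from cohort_config()")
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_subjects; N <- cfg$n_regions; Tn <- cfg$n_timepoints_signal
  ids <- sprintf("sub%03d", seq_len(n))
  region_names <- sprintf("region_%03d", seq_len(N))

  pp <- cfg$planted_pairs
  if (is.null(pp)) {
    all_pairs <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
    pick <- sample.int(nrow(all_pairs), cfg$n_planted)
    pp <- unname(all_pairs[pick, , drop = FALSE])   # row < col, i.e. i < j
    pp <- pp[order(pp[, 1L], pp[, 2L]), , drop = FALSE]
  }

  # trajectories: probabilities (control, remit_early, remit_late, chronic)
  p1 <- cfg$prevalence_t1; p2 <- cfg$prevalence_t2; p3 <- cfg$prevalence_t3
  if (cfg$remission_pattern) {
    probs <- c(control = 1 - p1, remit_early = p1 - p2,
               remit_late = p2 - p3, chronic = p3)
    traj <- sample(names(probs), n, replace = TRUE, prob = probs)
    dx <- cbind(dx_t1 = as.integer(traj != "control"),
                dx_t2 = as.integer(traj %in% c("remit_late", "chronic")),
                dx_t3 = as.integer(traj == "chronic"))
  } else {
    dx <- cbind(dx_t1 = stats::rbinom(n, 1, p1),
                dx_t2 = stats::rbinom(n, 1, p2),
                dx_t3 = stats::rbinom(n, 1, p3))
    traj <- ifelse(rowSums(dx) == 3L, "chronic",
                   ifelse(dx[, 1L] == 1L, "remitting", "control"))
  }
  chronic <- traj == "chronic"

  # time series: AR(1) noise everywhere; chronic cases share a per-pair
  # latent signal on the planted pairs
  subjects <- vector("list", n)
  names(subjects) <- ids
  g <- cfg$effect_strength
  for (s in seq_len(n)) {
    m <- ar1_series(N, Tn, cfg$ar_coefficient, cfg$noise_sd)
    if (chronic[s] && nrow(pp) > 0 && g > 0) {
      lat <- ar1_series(nrow(pp), Tn, cfg$ar_coefficient, cfg$noise_sd)
      for (q in seq_len(nrow(pp))) {
        m[pp[q, 1L], ] <- m[pp[q, 1L], ] + g * lat[q, ]
        m[pp[q, 2L], ] <- m[pp[q, 2L], ] + g * lat[q, ]
      }
      if (cfg$amplitude_confound != 1) {
        regs <- unique(as.vector(pp))
        m[regs, ] <- m[regs, ] * cfg$amplitude_confound
      }
    }
    if (cfg$standardize) {
      mu <- rowMeans(m)
      sdv <- sqrt(rowSums((m - mu)^2) / (Tn - 1L))
      sdv[sdv < 1e-12] <- 1
      m <- (m - mu) / sdv
    }
    rownames(m) <- region_names
    subjects[[s]] <- m
  }

  # severity: latent chronicity drives level and persistence
  sev_latent <- 10 * chronic + stats::rnorm(n, sd = 3)
  caps <- sapply(1:3, function(tp) {
    20 + 30 * dx[, tp] + sev_latent + stats::rnorm(n, sd = 5)
  })
  colnames(caps) <- paste0("caps_t", 1:3)

  # DSM-5 symptoms per time-point
  sym <- matrix(NA_integer_, n, 60L)
  colnames(sym) <- unlist(lapply(1:3, symptom_columns))
  for (tp in 1:3) {
    cols <- 20L * (tp - 1L) + seq_len(20L)
    for (s in seq_len(n)) {
      sym[s, cols] <- draw_symptoms(dx[s, tp] == 1L)
    }
  }

  # monotone dropout
  lost_t2 <- stats::runif(n) < cfg$dropout_t2
  lost_t3 <- lost_t2 | (stats::runif(n) < cfg$dropout_t3)
  dx_obs <- dx; caps_obs <- caps; sym_obs <- sym
  dx_obs[lost_t2, 2L] <- NA_integer_; dx_obs[lost_t3, 3L] <- NA_integer_
  caps_obs[lost_t2, 2L] <- NA_real_;  caps_obs[lost_t3, 3L] <- NA_real_
  sym_obs[lost_t2, 21:40] <- NA_integer_
  sym_obs[lost_t3, 41:60] <- NA_integer_

  persists <- ifelse(dx_obs[, 1L] == 1L & !is.na(dx_obs[, 3L]),
                     dx_obs[, 3L], NA_integer_)

  labels <- data.frame(subject_id = ids, dx_obs, caps_obs, sym_obs,
                       persists_t3 = persists, check.names = FALSE,
                       stringsAsFactors = FALSE)

  structure(list(dataset = panfc_dataset(subjects, labels, region_names),
                 config = cfg,
                 planted_pairs = pp,
                 trajectory = traj,
                 chronic = chronic,
                 dropout = cbind(lost_t2 = lost_t2, lost_t3 = lost_t3)),
            class = "panfc_cohort")
}

# one 20-bit DSM-5 symptom vector; diagnosed vectors satisfy all four
# cluster minima, non-diagnosed vectors are sub-threshold noise
draw_symptoms <- function(diagnosed, p_pos = 0.7, p_neg = 0.15) {
  p <- if (diagnosed) p_pos else p_neg
  v <- stats::rbinom(20L, 1L, p)
  if (diagnosed) {
    crit <- cluster_criteria()
    for (q in seq_len(nrow(crit))) {
      idx <- crit$from[q]:crit$to[q]
      short <- crit$min_count[q] - sum(v[idx])
      if (short > 0) {
        off <- idx[v[idx] == 0L]
        v[off[seq_len(short)]] <- 1L
      }
    }
  }
  v
}

#' @export
print.panfc_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d planted pairs (effect %.2g)\n",
              x$config$n_subjects, nrow(x$planted_pairs),
              x$config$effect_strength))
  print(x$dataset)
  invisible(x)
}

#' Write a cohort to a directory
#'
#' Emits `regions.txt`, `labels.csv`, one `ts_<subject_id>.tsv` per subject
#' and a `manifest.json` recording the file list, seed and ground truth, in
#' the formats read back by [read_cohort_dir()].
#'
#' @param cohort a [simulate_cohort()] result.
#' @param directory output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  if (!inherits(cohort, "panfc_cohort"))
    stop_panfc("'cohort' must come from simulate_cohort()")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  ds <- cohort$dataset
  write_region_names(ds$region_names, file.path(directory, "regions.txt"))
  write_labels(ds$labels, file.path(directory, "labels.csv"))
  files <- character(0)
  for (id in ds$subject_ids) {
    f <- paste0("ts_", id, ".tsv")
    write_timeseries(ds$subjects[[id]], file.path(directory, f))
    files <- c(files, f)
  }
  manifest <- list(n_subjects = length(ds$subject_ids),
                   seed = cohort$config$seed,
                   timeseries_files = files,
                   labels_file = "labels.csv",
                   regions_file = "regions.txt",
                   planted_pairs = cohort$planted_pairs)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
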