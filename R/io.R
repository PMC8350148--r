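# Reading and writing parcellated time series, label tables, region lists
# and model bundles.
#
# On-disk orientation: time-series files store one row per TIMEPOINT with a
# header row of region names (long, human-inspectable). In memory the matrix
# is regions x timepoints, matching the per-region indexing of the model.
# Missing labels are empty cells in the CSV and NA in memory; masks are
# derived from NA, never from sentinel numbers.

#' Assemble a dataset of subjects and labels
#'
#' @param subjects named list of `N x T` matrices (names = subject ids,
#'   rownames = region names). All subjects must share the region set and
#'   ordering.
#' @param labels data frame with columns `subject_id`, `dx_t1..dx_t3`,
#'   `caps_t1..caps_t3`, the 60 symptom columns `sym_t{1..3}_{b1..e6}` and
#'   `persists_t3`; `NA` marks an unobserved entry.
#' @param region_names canonical region-name vector; defaults to the first
#'   subject's rownames.
#' @return object of class `"panfc_dataset"`.
#' @export
panfc_dataset <- function(subjects, labels, region_names = NULL) {
  if (!length(subjects)) stop_panfc("no subjects")
  if (is.null(names(subjects)) || anyDuplicated(names(subjects)))
    stop_panfc("'subjects' must be a named list with unique subject ids")
  subjects <- lapply(subjects, as_subject_matrix)
  if (is.null(region_names)) region_names <- rownames(subjects[[1L]])
  if (is.null(region_names))
    region_names <- paste0("region_", seq_len(nrow(subjects[[1L]])))
  if (anyDuplicated(region_names)) stop_panfc("region names must be unique")
  N <- length(region_names)
  for (id in names(subjects)) {
    m <- subjects[[id]]
    if (nrow(m) != N)
      stop_panfc(sprintf("subject '%s' has %d regions, expected %d", id, nrow(m), N))
    if (!is.null(rownames(m)) && !identical(rownames(m), region_names))
      stop_panfc(sprintf("subject '%s' region names/order differ from the canonical list", id))
    rownames(subjects[[id]]) <- region_names
  }
  labels <- validate_labels(labels, names(subjects))
  structure(list(subjects = subjects,
                 labels = labels,
                 region_names = region_names,
                 subject_ids = names(subjects)),
            class = "panfc_dataset")
}

label_column_names <- function() {
  c("subject_id", paste0("dx_t", 1:3), paste0("caps_t", 1:3),
    unlist(lapply(1:3, symptom_columns)), "persists_t3")
}

validate_labels <- function(labels, subject_ids) {
  labels <- as.data.frame(labels)
  need <- label_column_names()
  missing_cols <- setdiff(need, names(labels))
  if (length(missing_cols))
    stop_panfc("label table is missing columns: ",
               paste(head(missing_cols, 5L), collapse = ", "))
  extra <- setdiff(names(labels), need)
  if (length(extra)) {
    warning("ignoring unknown label columns: ", paste(extra, collapse = ", "))
    labels <- labels[, need]
  }
  labels <- labels[match(subject_ids, labels$subject_id), need]
  if (anyNA(labels$subject_id))
    stop_panfc("every subject needs a label row; missing: ",
               paste(head(setdiff(subject_ids, labels$subject_id), 3L), collapse = ", "))
  for (col in grep("^(dx_|sym_|persists)", need, value = TRUE)) {
    v <- labels[[col]]
    bad <- !is.na(v) & !(v %in% c(0, 1))
    if (any(bad))
      stop_panfc(sprintf("column '%s' must be 0/1 or missing; offending row %d (value %s)",
                         col, which(bad)[1L], format(v[which(bad)[1L]])))
    labels[[col]] <- as.integer(v)
  }
  # a symptom observed at a time-point implies the diagnosis there is observed
  for (tp in 1:3) {
    sym_obs <- rowSums(!is.na(labels[, symptom_columns(tp)])) > 0
    dx_missing <- is.na(labels[[paste0("dx_t", tp)]])
    if (any(sym_obs & dx_missing))
      stop_panfc(sprintf("subject '%s': symptoms observed at t%d but diagnosis missing",
                         labels$subject_id[which(sym_obs & dx_missing)[1L]], tp))
  }
  rownames(labels) <- NULL
  labels
}

as_panfc_dataset <- function(data) {
  if (inherits(data, "panfc_dataset")) return(data)
  if (inherits(data, "panfc_cohort")) return(data$dataset)
  stop_panfc("expected a panfc_dataset or panfc_cohort")
}

#' @export
print.panfc_dataset <- function(x, ...) {
  m <- x$subjects[[1L]]
  cat(sprintf("panfc_dataset: %d subjects, %d regions x %d timepoints\n",
              length(x$subjects), nrow(m), ncol(m)))
  for (tp in 1:3) {
    dx <- x$labels[[paste0("dx_t", tp)]]
    cat(sprintf("  t%d: %d observed, %.0f%% positive\n", tp, sum(!is.na(dx)),
                100 * mean(dx, na.rm = TRUE)))
  }
  invisible(x)
}

# ---- time series -----------------------------------------------------------

#' Read one subject's parcellated time series
#'
#' Accepts TSV (default) or CSV: a header row of unique region names and one
#' row per timepoint. Returns the transposed regions-x-timepoints matrix with
#' region names as rownames, preserving the header order.
#'
#' @param path file path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @return `N x T` numeric matrix.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop_panfc("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "numeric", comment.char = "")
  if (anyDuplicated(names(df)))
    stop_panfc(sprintf("%s: duplicate region name in header: '%s'",
                       path, names(df)[anyDuplicated(names(df))]))
  m <- as.matrix(df)
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad))
    stop_panfc(sprintf("%s: non-finite value at timepoint %d, region '%s'",
                       path, bad[1L, 1L], colnames(m)[bad[1L, 2L]]))
  t(m)
}

#' Write one subject's time series
#'
#' Inverse of [read_timeseries()]: rows = timepoints, header = region names.
#'
#' @param x `N x T` matrix with region rownames.
#' @param path output path (`.csv` switches to comma separation).
#' @export
write_timeseries <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- t(x)
  # 17 significant digits round-trip IEEE doubles exactly
  chr <- sprintf("%.17g", m)
  dim(chr) <- dim(m)
  lines <- c(paste(rownames(x), collapse = sep),
             apply(chr, 1L, paste, collapse = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Read a label table
#'
#' CSV with the documented column schema (`subject_id`, `dx_t1..3`,
#' `caps_t1..3`, `sym_t1_b1 .. sym_t3_e6`, `persists_t3`). Empty cells become
#' `NA` (unobserved); symptom and diagnosis columns are validated as 0/1;
#' unknown columns are dropped with a warning. The 20 symptom columns per
#' time-point map positionally to the DSM-5 order B1-B5, C1-C2, D1-D7, E1-E6.
#'
#' @param path CSV path.
#' @return data frame keyed by `subject_id`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_panfc("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(subject_id = "character"),
                        na.strings = c("", "NA"))
  need <- label_column_names()
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_panfc(sprintf("%s: missing label columns: %s", path,
                       paste(head(missing_cols, 5L), collapse = ", ")))
  extra <- setdiff(names(df), need)
  if (length(extra)) {
    warning(sprintf("%s: ignoring unknown columns: %s", path,
                    paste(extra, collapse = ", ")))
    df <- df[, need]
  }
  for (col in grep("^(dx_|sym_|persists)", need, value = TRUE)) {
    v <- df[[col]]
    bad <- !is.na(v) & !(v %in% c(0, 1))
    if (any(bad))
      stop_panfc(sprintf("%s: column '%s' row %d: value %s is not 0/1",
                         path, col, which(bad)[1L], format(v[which(bad)[1L]])))
  }
  df
}

#' Write a label table
#'
#' @param labels data frame in the [read_labels()] schema.
#' @param path CSV path; `NA` is written as an empty cell.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read / write a region-name list
#'
#' One region name per line (e.g. atlas labels), order significant.
#'
#' @param path text file path.
#' @return character vector.
#' @export
read_region_names <- function(path) {
  if (!file.exists(path)) stop_panfc("no such file: ", path)
  nm <- readLines(path, warn = FALSE)
  nm <- nm[nzchar(nm)]
  if (anyDuplicated(nm)) stop_panfc(path, ": duplicate region names")
  nm
}

#' @rdname read_region_names
#' @param region_names character vector to write.
#' @export
write_region_names <- function(region_names, path) {
  writeLines(region_names, path)
  invisible(path)
}

#' Read a cohort directory
#'
#' Loads the layout written by [write_cohort()]: `regions.txt`, `labels.csv`
#' and one `ts_<subject_id>.tsv` per subject (enumerated from the manifest
#' when present, otherwise by listing). Region names in every time-series
#' header are cross-validated against the canonical list; a mismatch is an
#' error.
#'
#' @param directory cohort directory.
#' @return a [panfc_dataset()].
#' @export
read_cohort_dir <- function(directory) {
  if (!dir.exists(directory)) stop_panfc("no such directory: ", directory)
  region_names <- read_region_names(file.path(directory, "regions.txt"))
  labels <- read_labels(file.path(directory, "labels.csv"))
  manifest_path <- file.path(directory, "manifest.json")
  files <- if (file.exists(manifest_path)) {
    jsonlite::fromJSON(manifest_path)$timeseries_files
  } else {
    sort(list.files(directory, pattern = "^ts_.*\\.tsv$"))
  }
  subjects <- list()
  for (f in files) {
    id <- sub("^ts_(.*)\\.tsv$", "\\1", basename(f))
    m <- read_timeseries(file.path(directory, f))
    if (!identical(rownames(m), region_names))
      stop_panfc(sprintf("%s: region names disagree with regions.txt", f))
    subjects[[id]] <- m
  }
  panfc_dataset(subjects, labels, region_names)
}

# ---- model bundles ---------------------------------------------------------

#' Save / load a fitted model bundle
#'
#' The bundle stores the architecture configuration, the learned parameters,
#' the training control (including the seed), class weights, the severity
#' scaler, the training subject ids and a format version.
#'
#' @param fit a `"panfc"` or `"panfc_indep"` object.
#' @param path file path (RDS container).
#' @export
save_panfc <- function(fit, path) {
  if (!inherits(fit, c("panfc", "panfc_indep")))
    stop_panfc("'fit' must be a panfc or panfc_indep object")
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_panfc
#' @return `load_panfc()` returns the fitted object.
#' @export
load_panfc <- function(path) {
  if (!file.exists(path)) stop_panfc("no such file: ", path)
  fit <- readRDS(path)
  if (!inherits(fit, c("panfc", "panfc_indep")))
    stop_panfc(path, " does not contain a panfc model bundle")
  fit
}
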