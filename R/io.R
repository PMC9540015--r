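# Reading and writing the cohort tables and pipeline artifacts.
#
# One canonical wide CSV dialect throughout: comma-separated, UTF-8, "."
# decimal, empty cell = missing. Sex is encoded F/M; group and laterality
# are lowercase enums. Round-trips are lossless to 15 significant digits.

.meta_cols <- c("subject_id", "center", "group", "laterality",
                "age", "sex", "icv")

validate_cohort <- function(df) {
  reg <- feature_registry()
  missing_cols <- setdiff(c(.meta_cols, reg$name), names(df))
  if (length(missing_cols)) {
    stop("cohort table is missing mandatory columns: ",
         paste(utils::head(missing_cols, 5), collapse = ", "),
         if (length(missing_cols) > 5) ", ...")
  }
  unknown <- setdiff(names(df), c(.meta_cols, reg$name))
  if (length(unknown)) {
    stop("cohort table has unknown columns: ",
         paste(utils::head(unknown, 5), collapse = ", "),
         "; expected only subject metadata and the 156 registry features")
  }
  if (anyDuplicated(df$subject_id)) stop("duplicate subject IDs")
  if (!all(df$group %in% c("control", "case"))) {
    stop("group must be 'control' or 'case'")
  }
  if (!all(df$laterality %in% c("left", "right", "none"))) {
    stop("laterality must be 'left', 'right', or 'none'")
  }
  bad <- df$group == "case" & df$laterality == "none"
  if (any(bad)) {
    stop("case rows must carry a laterality (left/right): ",
         paste(utils::head(df$subject_id[bad], 3), collapse = ", "))
  }
  bad <- df$group == "control" & df$laterality != "none"
  if (any(bad)) stop("control rows must have laterality 'none'")
  if (any(!is.finite(df$age)) || any(df$age <= 0)) stop("age must be positive")
  if (any(!is.finite(df$icv)) || any(df$icv <= 0)) stop("icv must be positive")
  for (f in reg$name) {
    if (!is.numeric(df[[f]])) stop("non-numeric feature column: ", f)
  }
  invisible(df)
}

#' Read a cohort table from CSV
#'
#' Reads the wide one-row-per-subject table (metadata plus the 156 registry
#' features), validates the schema, and returns a typed data.frame. Empty
#' cells become `NA`. Unknown columns are rejected.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       center = "character",
                                       sex = "character"))
  validate_cohort(df)
  df
}

#' Write a cohort table to CSV
#'
#' @param df cohort data.frame (validated before writing).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(df, path) {
  validate_cohort(df)
  utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

# Format numeric columns at 15 significant digits for lossless round-trips.
format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      x <- format(df[[j]], digits = 15, trim = TRUE, scientific = FALSE)
      x[is.na(df[[j]])] <- NA
      df[[j]] <- x
    }
  }
  df
}

#' Write a simulated cohort with its truth sidecar
#'
#' Writes the subject table (`cohort.csv`), the clinical table
#' (`clinical.csv`), a truth sidecar (`truth.csv`: subject_id, latent_stage,
#' laterality) and the ground-truth sequence (`truth_sequence.json`).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(cohort$data, file.path(dir, "cohort.csv"))
  utils::write.csv(format_num_df(cohort$clinical),
                   file.path(dir, "clinical.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  truth <- data.frame(subject_id = names(cohort$truth$stage),
                      latent_stage = unname(cohort$truth$stage),
                      laterality = unname(cohort$truth$laterality))
  utils::write.csv(truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(cohort$truth$sequence,
                       file.path(dir, "truth_sequence.json"))
  invisible(dir)
}

#' Read the clinical table
#'
#' @param path CSV with columns `subject_id`, `age_at_onset`, `duration`,
#'   `drug_resistant`.
#' @return data.frame with a logical `drug_resistant` column.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  need <- c("subject_id", "age_at_onset", "duration", "drug_resistant")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("clinical table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df$drug_resistant <- as.logical(df$drug_resistant)
  df
}

#' Write fitted model artifacts
#'
#' Writes `sequence.json` (ordered events plus log-likelihood), `pvd.csv`
#' (events x positions, labeled), and `stages.csv` (per-subject stage with
#' the per-stage log-likelihood vector).
#'
#' @param sequence an `ebm_sequence` (see [ebm_fit()]).
#' @param pvd positional-variance matrix from [bootstrap_pvd()], or `NULL`.
#' @param stages a `stage_assignment` data.frame from [stage_subjects()],
#'   or `NULL`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(sequence, pvd = NULL, stages = NULL, dir) {
  if (length(sequence$sequence) == 0) {
    stop("empty event sequence: nothing to write")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(sequence = sequence$sequence, log_likelihood = sequence$log_likelihood),
    file.path(dir, "sequence.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(pvd)) {
    m <- matrix(as.numeric(pvd), nrow(pvd), ncol(pvd),
                dimnames = dimnames(pvd))
    out <- data.frame(event = rownames(m), m, check.names = FALSE)
    utils::write.csv(out, file.path(dir, "pvd.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  if (!is.null(stages)) {
    utils::write.csv(format_num_df(stages), file.path(dir, "stages.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a staged-subjects table written by [write_results()]
#'
#' @param path `stages.csv` path.
#' @return data.frame with `subject_id`, `group`, `stage`, and the
#'   per-stage log-likelihood columns.
#' @export
read_stages <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(subject_id = "character"))
}
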