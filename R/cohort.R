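#' Construct a validated cohort object
#'
#' A cohort bundles three tables keyed by `subject_id`: one row of baseline
#' covariates per subject, a long table of functional assessments (total
#' FIM plus the three domain scores at up to nine timepoints), and one exit
#' record per subject describing the last attended timepoint and the reason
#' follow-up ended.
#'
#' @param covariates data.frame with columns `subject_id`, `gender`
#'   (`"M"`/`"F"`), `age_at_event_months`, `etiology` (`"traumatic"`,
#'   `"anoxic"`, `"other_nontraumatic"`), `age_at_admission_months`,
#'   `los_days`, `coma_days`, `event_to_discharge_days`, `dcn`, `epilepsy`
#'   (booleans as 0/1 or logical).
#' @param series data.frame with columns `subject_id`, `timepoint`
#'   (`admission`, `discharge`, `Y1`..`Y7`), `total`, `selfcare`,
#'   `mobility`, `cognition`. Missing visits are absent rows.
#' @param exits data.frame with columns `subject_id`, `last_timepoint`,
#'   `reason` (`in_service`, `death`, `recovery`, `opt_out`, `censored`).
#' @param validate run full invariant validation (default `TRUE`).
#'
#' @return An object of class `"abi_cohort"`: a list with elements
#'   `covariates`, `series`, `exits`, rows sorted by subject and timepoint.
#' @export
new_cohort <- function(covariates, series, exits, validate = TRUE) {
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  series <- as.data.frame(series, stringsAsFactors = FALSE)
  exits <- as.data.frame(exits, stringsAsFactors = FALSE)

  req_cov <- c("subject_id", "gender", "age_at_event_months", "etiology",
               "age_at_admission_months", "los_days", "coma_days",
               "event_to_discharge_days", "dcn", "epilepsy")
  req_ser <- c("subject_id", "timepoint", "total", "selfcare", "mobility",
               "cognition")
  req_ex <- c("subject_id", "last_timepoint", "reason")
  check_columns(covariates, req_cov, "covariates")
  check_columns(series, req_ser, "series")
  check_columns(exits, req_ex, "exits")

  covariates$subject_id <- as.character(covariates$subject_id)
  series$subject_id <- as.character(series$subject_id)
  exits$subject_id <- as.character(exits$subject_id)
  # canonical storage types, so cohorts compare identical after a CSV trip
  for (b in c("dcn", "epilepsy", "los_days", "coma_days",
              "event_to_discharge_days")) {
    covariates[[b]] <- as.integer(covariates[[b]])
  }
  for (a in c("age_at_event_months", "age_at_admission_months")) {
    covariates[[a]] <- as.numeric(covariates[[a]])
  }
  for (d in c("total", "selfcare", "mobility", "cognition")) {
    series[[d]] <- as.integer(series[[d]])
  }

  covariates <- covariates[order(covariates$subject_id), req_cov,
                           drop = FALSE]
  series <- series[order(series$subject_id,
                         match(series$timepoint, TIMEPOINTS)), req_ser,
                   drop = FALSE]
  exits <- exits[order(exits$subject_id), req_ex, drop = FALSE]
  rownames(covariates) <- rownames(series) <- rownames(exits) <- NULL

  cohort <- structure(list(covariates = covariates, series = series,
                           exits = exits),
                      class = "abi_cohort")
  if (validate) validate_cohort(cohort)
  cohort
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("schema error in %s table: missing column(s) %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate cohort invariants
#'
#' Checks the shared key set across the three tables, score bounds
#' (total 18-126, selfcare 8-56, mobility 5-35, cognition 5-35), the exact
#' domain-sum identity, mandatory admission and discharge assessments,
#' uniqueness of (subject, timepoint), non-negative durations, the exit
#' record's consistency with the observed series, and category levels.
#'
#' @param cohort an `"abi_cohort"` object.
#' @return `cohort`, invisibly; signals an error naming the subject and the
#'   violated rule otherwise.
#' @export
validate_cohort <- function(cohort) {
  cov <- cohort$covariates
  ser <- cohort$series
  ex <- cohort$exits

  ids <- sort(unique(cov$subject_id))
  if (anyDuplicated(cov$subject_id)) {
    stop("validation error: duplicated subject_id in covariates table",
         call. = FALSE)
  }
  if (!identical(ids, sort(unique(ser$subject_id))) && nrow(cov) > 0L) {
    stop("validation error: covariates and series subject_id sets differ",
         call. = FALSE)
  }
  if (!identical(ids, sort(ex$subject_id))) {
    stop("validation error: covariates and exits subject_id sets differ",
         call. = FALSE)
  }

  bad <- function(id, rule) {
    stop(sprintf("validation error for subject %s: %s", id, rule),
         call. = FALSE)
  }

  if (nrow(cov) > 0L) {
    if (!all(cov$gender %in% c("M", "F"))) {
      bad(cov$subject_id[!cov$gender %in% c("M", "F")][1L],
          "gender must be M or F")
    }
    if (!all(cov$etiology %in% ETIOLOGIES)) {
      bad(cov$subject_id[!cov$etiology %in% ETIOLOGIES][1L],
          "unknown etiology category")
    }
    num_rules <- list(
      c("age_at_event_months", "age at event must be non-negative"),
      c("coma_days", "coma_days must be non-negative"),
      c("event_to_discharge_days",
        "event_to_discharge_days must be non-negative")
    )
    for (r in num_rules) {
      v <- cov[[r[1L]]]
      if (anyNA(v) || any(v < 0)) bad(cov$subject_id[which(is.na(v) | v < 0)[1L]], r[2L])
    }
    if (any(cov$los_days <= 0)) {
      bad(cov$subject_id[cov$los_days <= 0][1L], "los_days must be > 0")
    }
    if (any(cov$age_at_admission_months < cov$age_at_event_months)) {
      bad(cov$subject_id[cov$age_at_admission_months <
                           cov$age_at_event_months][1L],
          "age_at_admission must be >= age_at_event")
    }
    if (!all(cov$dcn %in% 0:1) || !all(cov$epilepsy %in% 0:1)) {
      bad(cov$subject_id[!(cov$dcn %in% 0:1 & cov$epilepsy %in% 0:1)][1L],
          "dcn and epilepsy must be 0/1")
    }
  }

  if (nrow(ser) > 0L) {
    if (!all(ser$timepoint %in% TIMEPOINTS)) {
      bad(ser$subject_id[!ser$timepoint %in% TIMEPOINTS][1L],
          "unknown timepoint")
    }
    key <- paste(ser$subject_id, ser$timepoint)
    if (anyDuplicated(key)) {
      bad(ser$subject_id[duplicated(key)][1L],
          "duplicate (subject, timepoint) row")
    }
    for (dom in names(FIM_BOUNDS)) {
      b <- FIM_BOUNDS[[dom]]
      v <- ser[[dom]]
      low <- which(v < b[1L])
      if (length(low) > 0L) {
        bad(ser$subject_id[low[1L]],
            sprintf("%s below scale floor %d", dom, b[1L]))
      }
      high <- which(v > b[2L])
      if (length(high) > 0L) {
        bad(ser$subject_id[high[1L]],
            sprintf("%s above scale ceiling %d", dom, b[2L]))
      }
    }
    mism <- which(ser$total != ser$selfcare + ser$mobility + ser$cognition)
    if (length(mism) > 0L) bad(ser$subject_id[mism[1L]], "domain sum mismatch")
  }

  # admission and discharge are always assessed; exit record must cover the
  # observed series and use a known reason
  if (!all(ex$reason %in% EXIT_REASONS)) {
    bad(ex$subject_id[!ex$reason %in% EXIT_REASONS][1L],
        "unknown exit reason")
  }
  if (!all(ex$last_timepoint %in% TIMEPOINTS)) {
    bad(ex$subject_id[!ex$last_timepoint %in% TIMEPOINTS][1L],
        "unknown last_timepoint")
  }
  if (length(ids) > 0L) {
    tp_idx <- split(match(ser$timepoint, TIMEPOINTS), ser$subject_id)
    last_idx <- match(ex$last_timepoint, TIMEPOINTS)
    names(last_idx) <- ex$subject_id
    for (id in ids) {
      idx <- tp_idx[[id]]
      if (!all(c(1L, 2L) %in% idx)) {
        bad(id, "admission and discharge assessments are mandatory")
      }
      if (max(idx) > last_idx[[id]]) {
        bad(id, "observation after last_timepoint")
      }
    }
    ev <- ex$reason %in% c("death", "recovery", "opt_out")
    if (any(ev & ex$last_timepoint == "Y7")) {
      bad(ex$subject_id[ev & ex$last_timepoint == "Y7"][1L],
          "exit event reason requires last_timepoint before Y7")
    }
    if (any(ex$reason == "in_service" & ex$last_timepoint != "Y7")) {
      bad(ex$subject_id[ex$reason == "in_service" &
                          ex$last_timepoint != "Y7"][1L],
          "in_service requires last_timepoint Y7")
    }
  }
  invisible(cohort)
}

#' @export
print.abi_cohort <- function(x, ...) {
  n <- nrow(x$covariates)
  cat(sprintf("<abi_cohort> %d subjects, %d functional assessments\n",
              n, nrow(x$series)))
  if (n > 0L) {
    tab <- table(factor(x$exits$reason, levels = EXIT_REASONS))
    cat("exit reasons:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort an `"abi_cohort"`.
#' @return integer count.
#' @export
n_subjects <- function(cohort) nrow(cohort$covariates)

#' Subject identifiers of a cohort
#' @param cohort an `"abi_cohort"`.
#' @return character vector, sorted.
#' @export
subject_ids <- function(cohort) cohort$covariates$subject_id

#' Restrict a cohort to a subset of subjects
#'
#' @param cohort an `"abi_cohort"`.
#' @param ids character vector of subject ids; all must exist.
#' @return the sub-cohort, an `"abi_cohort"`.
#' @export
subset_cohort <- function(cohort, ids) {
  missing <- setdiff(ids, subject_ids(cohort))
  if (length(missing) > 0L) {
    stop("unknown subject id(s): ", paste(head(missing, 3L), collapse = ", "),
         call. = FALSE)
  }
  new_cohort(cohort$covariates[cohort$covariates$subject_id %in% ids, ],
             cohort$series[cohort$series$subject_id %in% ids, ],
             cohort$exits[cohort$exits$subject_id %in% ids, ],
             validate = FALSE)
}

#' Read a cohort from a directory of CSV files
#'
#' Expects `covariates.csv`, `fim_long.csv` and `exits.csv` in `path`,
#' UTF-8, comma-separated, with mandatory header rows, following the
#' long-format schema documented in [new_cohort()]. Missing visits are
#' absent rows, never sentinel values.
#'
#' @param path directory containing the three files.
#' @return a validated `"abi_cohort"`.
#' @export
read_cohort <- function(path) {
  files <- file.path(path, c("covariates.csv", "fim_long.csv", "exits.csv"))
  absent <- files[!file.exists(files)]
  if (length(absent) > 0L) {
    stop("cohort file(s) not found: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  cov <- read.csv(files[1L], colClasses = c(subject_id = "character"),
                  stringsAsFactors = FALSE)
  ser <- read.csv(files[2L], colClasses = c(subject_id = "character"),
                  stringsAsFactors = FALSE)
  ex <- read.csv(files[3L], colClasses = c(subject_id = "character"),
                 stringsAsFactors = FALSE)
  for (d in names(FIM_BOUNDS)) if (d %in% names(ser)) ser[[d]] <- as.integer(ser[[d]])
  new_cohort(cov, ser, ex)
}

#' Write a cohort to a directory of CSV files
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(c, dir))`
#' reproduces `c` exactly. Booleans are written as 0/1; missing visits are
#' omitted rows.
#'
#' @param cohort an `"abi_cohort"`.
#' @param path output directory, created if needed.
#' @return invisibly, the character vector of the three file paths.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", path, call. = FALSE)
  }
  files <- file.path(path, c("covariates.csv", "fim_long.csv", "exits.csv"))
  write.csv(cohort$covariates, files[1L], row.names = FALSE, quote = FALSE)
  write.csv(cohort$series, files[2L], row.names = FALSE, quote = FALSE)
  write.csv(cohort$exits, files[3L], row.names = FALSE, quote = FALSE)
  invisible(files)
}

# number of completed yearly follow-up intervals implied by a timepoint:
# admission/discharge -> 0, Yk -> k
completed_intervals <- function(timepoint) {
  pmax(0L, match(timepoint, TIMEPOINTS) - 2L)
}
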