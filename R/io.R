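# CSV dialects and JSON round-trips. The trial table header is fixed so that
# downstream tooling can rely on column order.

TRIAL_COLUMNS <- c("participant_id", "condition", "phase", "block_index",
                   "direction", "feedback_level", "target_x_px",
                   "true_stop_x_px", "estimate_x_px", "sweeps",
                   "reaction_time_s", "estimation_time_s", "excluded",
                   "excluded_reason")

PARTICIPANT_COLUMNS <- c("participant_id", "performance_sd_px",
                         "self_prior_sd_px", "agent_prior_sd_px",
                         "agent_prior_flat", "optimism_score")

#' Write a trial table CSV
#'
#' Fixed-dialect CSV with the exact documented header; extra columns are
#' dropped with a warning.
#'
#' @param trials trial data frame.
#' @param path output path.
#' @export
write_trials <- function(trials, path) {
  miss <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(miss) > 0) {
    stop_input("trial table missing column(s): ", paste(miss, collapse = ", "))
  }
  extra <- setdiff(names(trials), TRIAL_COLUMNS)
  if (length(extra) > 0) {
    warning("dropping non-dialect column(s): ", paste(extra, collapse = ", "))
  }
  utils::write.csv(trials[TRIAL_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trial table CSV
#'
#' Validates the exact header and column types; parse problems are reported
#' with the offending column name.
#'
#' @param path CSV path.
#' @return A trial data frame.
#' @export
read_trials <- function(path) {
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  miss <- setdiff(TRIAL_COLUMNS, header)
  if (length(miss) > 0) {
    stop_input("trial CSV header missing column(s): ",
               paste(miss, collapse = ", "))
  }
  if (!identical(header, TRIAL_COLUMNS)) {
    stop_input("trial CSV columns out of order; expected: ",
               paste(TRIAL_COLUMNS, collapse = ","))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(
                          participant_id = "character",
                          condition = "character",
                          phase = "character",
                          block_index = "integer",
                          direction = "integer",
                          feedback_level = "character",
                          target_x_px = "numeric",
                          true_stop_x_px = "numeric",
                          estimate_x_px = "numeric",
                          sweeps = "integer",
                          reaction_time_s = "numeric",
                          estimation_time_s = "numeric",
                          excluded = "logical",
                          excluded_reason = "character"))
  df$excluded_reason[is.na(df$excluded_reason)] <- ""
  for (col in c("true_stop_x_px", "estimate_x_px")) {
    if (any(is.na(df[[col]]))) {
      bad <- which(is.na(df[[col]]))[1]
      stop_input(sprintf("column %s: missing/unparseable value at data row %d",
                         col, bad))
    }
  }
  df
}

#' Write / read the participant table CSV
#'
#' @param participants participant data frame.
#' @param path CSV path.
#' @export
write_participants <- function(participants, path) {
  miss <- setdiff(PARTICIPANT_COLUMNS, names(participants))
  if (length(miss) > 0) {
    stop_input("participant table missing column(s): ",
               paste(miss, collapse = ", "))
  }
  utils::write.csv(participants[PARTICIPANT_COLUMNS], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_participants
#' @export
read_participants <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(PARTICIPANT_COLUMNS, names(df))
  if (length(miss) > 0) {
    stop_input("participant CSV missing column(s): ",
               paste(miss, collapse = ", "))
  }
  df
}

#' Read / write cohort configuration JSON
#'
#' @param spec a [cohort_spec()].
#' @param path JSON path.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(cohort_spec, x[setdiff(names(x), character())])
}

#' Serialize an analysis report to JSON
#'
#' @param report a named list (as produced by [run_experiment()]).
#' @param path JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, na = "null")
  invisible(path)
}

# short deterministic fingerprint of a config for provenance blocks
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  sprintf("%08x", str_hash31(as.character(s)))
}
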