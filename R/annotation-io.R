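#' Read and write boundary-annotation tables
#'
#' The annotation table is the package's central exchange format: one row
#' per annotator's placement of one boundary (onset or offset) of one word
#' token, with modality and speaking-rate labels. Enum columns are
#' validated on read and the offending row is named on failure; the
#' round trip through `write_annotations_csv()` is lossless.
#'
#' Schema: `token_id, trial_id, position, label, speaker_id, rate,
#' modality, annotator_id, boundary, time_ms`.
#'
#' @param path File path.
#' @return `read_annotations_csv()` returns a tibble with the schema
#'   above; `write_annotations_csv()` returns `path` invisibly.
#' @export
read_annotations_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          token_id = readr::col_character(),
                          trial_id = readr::col_character(),
                          position = readr::col_integer(),
                          label = readr::col_character(),
                          speaker_id = readr::col_character(),
                          rate = readr::col_character(),
                          modality = readr::col_character(),
                          annotator_id = readr::col_character(),
                          boundary = readr::col_character(),
                          time_ms = readr::col_double()))
  validate_annotations(df)
}

#' @rdname read_annotations_csv
#' @param annotations A tibble in the annotation schema.
#' @export
write_annotations_csv <- function(annotations, path) {
  validate_annotations(annotations)
  readr::write_csv(annotations, path)
  invisible(path)
}

#' Validate an annotation table
#'
#' Checks the schema columns, the enum fields (`modality`, `boundary`,
#' `rate`), non-negative times, and uniqueness of
#' `(token_id, annotator_id, modality, boundary)`.
#'
#' @param annotations A data frame in the annotation schema.
#' @return The validated tibble (invisibly usable in a pipe).
#' @export
validate_annotations <- function(annotations) {
  assert_cols(annotations,
              c("token_id", "modality", "annotator_id", "boundary", "time_ms"),
              "annotation table")
  assert_enum(annotations$modality, MODALITY_LEVELS, "modality")
  assert_enum(annotations$boundary, BOUNDARY_LEVELS, "boundary")
  if ("rate" %in% names(annotations)) {
    assert_enum(annotations$rate, RATE_LEVELS, "rate")
  }
  if (any(annotations$time_ms < 0, na.rm = TRUE)) {
    abort(sprintf("negative time_ms in row %d",
                  which(annotations$time_ms < 0)[1]))
  }
  key <- paste(annotations$token_id, annotations$annotator_id,
               annotations$modality, annotations$boundary)
  if (anyDuplicated(key)) {
    abort(sprintf(
      "duplicate annotation for (token, annotator, modality, boundary) in row %d",
      anyDuplicated(key)))
  }
  as_tibble(annotations)
}

#' Read and write per-interaction timing logs
#'
#' One row per annotator interaction with a word candidate (triage or
#' retrim pass) or with a whole baseline trial. Schema: `unit_id,
#' annotator_id, modality, task, t_start_s, t_end_s, outcome`.
#' `t_end_s >= t_start_s` is enforced, as is the constraint that
#' `task = "baseline_trial"` only occurs in the baseline modality.
#'
#' @param path File path.
#' @return A tibble in the timing schema; the writer returns `path`
#'   invisibly.
#' @export
read_timing_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          unit_id = readr::col_character(),
                          annotator_id = readr::col_character(),
                          modality = readr::col_character(),
                          task = readr::col_character(),
                          t_start_s = readr::col_double(),
                          t_end_s = readr::col_double(),
                          outcome = readr::col_character()))
  validate_timing(df)
}

#' @rdname read_timing_csv
#' @param timing A tibble in the timing schema.
#' @export
write_timing_csv <- function(timing, path) {
  validate_timing(timing)
  readr::write_csv(timing, path)
  invisible(path)
}

#' @rdname read_timing_csv
#' @export
validate_timing <- function(timing) {
  assert_cols(timing,
              c("unit_id", "annotator_id", "modality", "task",
                "t_start_s", "t_end_s", "outcome"),
              "timing table")
  assert_enum(timing$modality, MODALITY_LEVELS, "modality")
  assert_enum(timing$task, TASK_LEVELS, "task")
  assert_enum(timing$outcome, OUTCOME_LEVELS, "outcome")
  bad <- which(timing$t_end_s < timing$t_start_s)
  if (length(bad) > 0) {
    abort(sprintf("t_end_s < t_start_s in row %d", bad[1]))
  }
  bad <- which(timing$task == "baseline_trial" & timing$modality != "baseline")
  if (length(bad) > 0) {
    abort(sprintf("task 'baseline_trial' outside baseline modality in row %d", bad[1]))
  }
  as_tibble(timing)
}
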