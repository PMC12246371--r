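trial_schema_cols <- c("participant_id", "session", "condition", "valence",
                       "word", "block", "response", "rt")

validate_trials <- function(trials, context = "trials") {
  missing <- setdiff(trial_schema_cols, names(trials))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing columns: %s", context,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad_resp <- which(!trials$response %in% c(0L, 1L))
  if (length(bad_resp) > 0) {
    stop(sprintf("%s: `response` must be 0 or 1 (first bad row %d)",
                 context, bad_resp[1]), call. = FALSE)
  }
  bad_rt <- which(!(trials$rt > 0))
  if (length(bad_rt) > 0) {
    stop(sprintf("%s: `rt` must be > 0 (first bad row %d)",
                 context, bad_rt[1]), call. = FALSE)
  }
  bad_cond <- which(!trials$condition %in% c("blue_enriched", "blue_depleted"))
  if (length(bad_cond) > 0) {
    stop(sprintf("%s: unknown `condition` (first bad row %d)",
                 context, bad_cond[1]), call. = FALSE)
  }
  bad_val <- which(!trials$valence %in% c("positive", "negative"))
  if (length(bad_val) > 0) {
    stop(sprintf("%s: unknown `valence` (first bad row %d)",
                 context, bad_val[1]), call. = FALSE)
  }
  invisible(trials)
}

#' Write trials to delimited text
#'
#' Writes the eight schema columns (`participant_id, session, condition,
#' valence, word, block, response, rt`) as UTF-8 CSV with a header row.
#' Extra columns (e.g. participant covariates) are dropped so that a written
#' file always matches the interchange schema.
#'
#' @param trials A trials tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  if (nrow(trials) > 0) validate_trials(trials, "write_trials")
  readr::write_csv(trials[, intersect(trial_schema_cols, names(trials))], path)
  invisible(path)
}

#' Read trials from delimited text
#'
#' Reads a trial CSV written by [write_trials()] (or any file in the same
#' schema), validating column presence, the binary response coding and
#' positive reaction times. Validation failures name the offending data line.
#'
#' @param path Input file path.
#' @return A trials tibble.
#' @export
read_trials <- function(path) {
  trials <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      session = readr::col_integer(),
      condition = readr::col_character(),
      valence = readr::col_character(),
      word = readr::col_character(),
      block = readr::col_integer(),
      response = readr::col_integer(),
      rt = readr::col_double()
    ),
    progress = FALSE
  )
  if (nrow(trials) == 0) return(trials)
  # report file line numbers (line 1 is the header)
  err <- tryCatch({ validate_trials(trials, basename(path)); NULL },
                  error = function(e) conditionMessage(e))
  if (!is.null(err)) {
    m <- regmatches(err, regexpr("first bad row \\d+", err))
    if (length(m) == 1) {
      row <- as.integer(sub("first bad row ", "", m))
      err <- sub("first bad row \\d+", sprintf("line %d", row + 1L), err)
    }
    stop(err, call. = FALSE)
  }
  trials
}
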