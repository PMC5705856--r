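checkin_cols <- c("dyad_id", "arm", "checkin_index", "day", "source", "symptom", "rating")

#' Write check-in records to CSV
#'
#' Long format, one row per rating (ten rows per check-in), UTF-8, header
#' `dyad_id,arm,checkin_index,day,source,symptom,rating`. The round trip
#' through [read_checkins()] is lossless.
#'
#' @param records Check-in tibble as produced by [generate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_checkins <- function(records, path) {
  missing_cols <- setdiff(checkin_cols, names(records))
  if (length(missing_cols)) {
    stop_data("records lack required columns: ", paste(missing_cols, collapse = ", "))
  }
  readr::write_csv(records[checkin_cols], path)
  invisible(path)
}

#' Read check-in records from CSV
#'
#' Parses and validates the long check-in schema written by
#' [write_checkins()]. Malformed rows (rating outside 0-10, unknown arm or
#' source) raise a data error naming the offending file row; a check-in
#' whose symptom set is incomplete or duplicated is likewise an error (the
#' instrument forces completion of all ten items).
#'
#' @param path CSV file path.
#' @return A check-in tibble.
#' @export
read_checkins <- function(path) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      dyad_id = readr::col_character(),
      arm = readr::col_character(),
      checkin_index = readr::col_integer(),
      day = readr::col_integer(),
      source = readr::col_character(),
      symptom = readr::col_character(),
      rating = readr::col_integer()
    ),
    progress = FALSE
  )
  missing_cols <- setdiff(checkin_cols, names(x))
  if (length(missing_cols)) {
    stop_data("file lacks required columns: ", paste(missing_cols, collapse = ", "))
  }
  x <- x[checkin_cols]
  if (nrow(x) == 0L) return(x)
  # file row numbers: +1 for the header line
  bad <- which(is.na(x$rating) | x$rating < 0L | x$rating > 10L)
  if (length(bad)) {
    stop_data(
      "rating outside 0-10 at file row(s) ",
      paste(utils::head(bad + 1L, 5L), collapse = ", ")
    )
  }
  bad <- which(!x$arm %in% c("CONTROL", "ALERT"))
  if (length(bad)) stop_data("unknown arm at file row(s) ", paste(utils::head(bad + 1L, 5L), collapse = ", "))
  bad <- which(!x$source %in% c("PRETEST", "ONLINE"))
  if (length(bad)) stop_data("unknown source at file row(s) ", paste(utils::head(bad + 1L, 5L), collapse = ", "))
  per_checkin <- dplyr::count(x, .data$dyad_id, .data$checkin_index, name = "n_symptoms")
  off <- dplyr::filter(per_checkin, .data$n_symptoms != 10L)
  if (nrow(off)) {
    stop_data(
      "check-in with missing or duplicated symptoms: dyad ", off$dyad_id[1L],
      ", check-in ", off$checkin_index[1L], " has ", off$n_symptoms[1L], " ratings (expected 10)"
    )
  }
  dup <- dplyr::count(x, .data$dyad_id, .data$checkin_index, .data$symptom, name = "n")
  dup <- dplyr::filter(dup, .data$n > 1L)
  if (nrow(dup)) {
    stop_data(
      "duplicate rating: dyad ", dup$dyad_id[1L], ", check-in ", dup$checkin_index[1L],
      ", symptom ", dup$symptom[1L]
    )
  }
  x
}
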