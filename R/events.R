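#' @importFrom rlang .data
NULL

event_columns <- c(
  "onset", "duration", "trial_id", "session", "modality",
  "physical_level", "rating", "rating_onset", "rating_duration"
)

#' Validate an event table
#'
#' Events follow the BIDS events dialect: `onset`/`duration` lead the columns,
#' all times are seconds from session start (0-based). One row per stimulus
#' with its modality (`pain`/`tactile`), physical level (`low`/`high`),
#' perceived-intensity rating on the 0-10 scale, and the onset/duration of the
#' trial's rating period.
#'
#' @param events A data frame with the event columns (see Details).
#' @return The validated events as a tibble, ordered by (session, onset).
#' @export
validate_events <- function(events) {
  events <- tibble::as_tibble(events)
  missing <- setdiff(event_columns, names(events))
  if (length(missing))
    stop("missing event column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(events$rating) | events$rating < 0 | events$rating > 10)
  if (length(bad))
    stop(sprintf("rating outside [0, 10] at row %d", bad[1]), call. = FALSE)
  dup <- which(duplicated(events$trial_id))
  if (length(dup))
    stop(sprintf("duplicate trial_id at row %d", dup[1]), call. = FALSE)
  if (!all(events$modality %in% c("pain", "tactile")))
    stop("modality must be 'pain' or 'tactile'", call. = FALSE)
  bad <- which(events$rating_onset <= events$onset)
  if (length(bad))
    stop(sprintf("rating_onset must follow the stimulus onset (row %d)", bad[1]),
         call. = FALSE)
  dplyr::arrange(events, .data$session, .data$onset)
}

#' Read / write an events table (tab-separated)
#'
#' Lossless round-trip of the per-stimulus event records driving every
#' analysis. See [validate_events()] for the column contract.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A validated events tibble.
#' @export
read_events <- function(path) {
  events <- readr::read_tsv(
    path,
    col_types = readr::cols(
      trial_id = readr::col_character(),
      session = readr::col_integer(),
      modality = readr::col_character(),
      physical_level = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  validate_events(events)
}

#' @param events An events tibble (validated on write).
#' @rdname read_events
#' @export
write_events <- function(events, path) {
  events <- validate_events(events)
  first <- intersect(c("onset", "duration"), names(events))
  events <- dplyr::relocate(events, dplyr::all_of(first))
  readr::write_tsv(events, path, progress = FALSE)
  invisible(path)
}
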