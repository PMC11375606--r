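#' Default fixation report column mapping
#'
#' Maps internal field names to the column names of a Data-Viewer-style
#' tab-separated fixation report.
#' @return Named character vector.
#' @export
default_fixation_columns <- function() {
  c(trial_label = "TRIAL_LABEL",
    onset_ms = "CURRENT_FIX_START",
    offset_ms = "CURRENT_FIX_END",
    x_px = "CURRENT_FIX_X",
    y_px = "CURRENT_FIX_Y")
}

empty_fixations <- function(with_label = FALSE) {
  out <- tibble(onset_ms = integer(0), offset_ms = integer(0),
                x_px = numeric(0), y_px = numeric(0),
                off_screen = logical(0), aoi_label = character(0))
  if (with_label) out <- tibble(trial_label = character(0), out)
  out
}

#' Read a tab-separated fixation event report
#'
#' Parses a Data-Viewer-style fixation report: one row per fixation with a
#' trial label, start/end time in ms and gaze position in screen pixels.
#' Times are rounded to integer milliseconds (the recordings are sampled at
#' 1,000 Hz, so milliseconds are exact). Fixations whose gaze position lies
#' outside the screen are flagged in the `off_screen` column, never dropped:
#' downstream denominators depend on completeness.
#'
#' @param path Path to the TSV file. A header row is required.
#' @param column_map Named character vector mapping the internal names
#'   `trial_label`, `onset_ms`, `offset_ms`, `x_px`, `y_px` to the file's
#'   column names; see [default_fixation_columns()].
#' @param screen Screen size in pixels, `c(width_px, height_px)`.
#' @return A tibble with columns `trial_label`, `onset_ms`, `offset_ms`,
#'   `x_px`, `y_px`, `off_screen`, `aoi_label` (initially `NA`), sorted by
#'   trial label and onset. A header-only file yields zero rows.
#' @export
read_fixation_report <- function(path, column_map = default_fixation_columns(),
                                 screen = SCREEN_DEFAULT) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  raw <- read.delim(path, sep = "\t", colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE)
  needed <- default_fixation_columns()
  map <- needed
  map[names(column_map)] <- column_map
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols) > 0) {
    abort_format(sprintf("fixation report '%s' lacks mapped column(s): %s",
                         path, paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0) return(empty_fixations(with_label = TRUE))

  num_field <- function(field) {
    col <- map[[field]]
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals))
    if (length(bad) > 0) {
      abort_parse(sprintf(
        "non-numeric value '%s' in column '%s' at data row %d of '%s'",
        raw[[col]][bad[1]], col, bad[1], path))
    }
    vals
  }
  out <- tibble(
    trial_label = raw[[map[["trial_label"]]]],
    onset_ms = as_ms(num_field("onset_ms")),
    offset_ms = as_ms(num_field("offset_ms")),
    x_px = num_field("x_px"),
    y_px = num_field("y_px"))
  bad_dur <- which(out$offset_ms <= out$onset_ms)
  if (length(bad_dur) > 0) {
    abort_validation(sprintf(
      "fixation at data row %d has offset <= onset", bad_dur[1]))
  }
  out$off_screen <- out$x_px < 0 | out$x_px > screen[["width_px"]] |
    out$y_px < 0 | out$y_px > screen[["height_px"]]
  out$aoi_label <- NA_character_
  out[order(out$trial_label, out$onset_ms), ]
}

#' Write fixation events as a tab-separated report
#'
#' Inverse of [read_fixation_report()]: writes the `trial_label`,
#' `onset_ms`, `offset_ms`, `x_px`, `y_px` columns under the mapped header
#' names. Derived columns (`off_screen`, `aoi_label`) are not written.
#'
#' @param fixations Tibble as returned by [read_fixation_report()].
#' @param path Output file path.
#' @param column_map As in [read_fixation_report()].
#' @return `path`, invisibly.
#' @export
write_fixation_report <- function(fixations, path,
                                  column_map = default_fixation_columns()) {
  map <- default_fixation_columns()
  map[names(column_map)] <- column_map
  df <- as.data.frame(fixations[, names(map)])
  names(df) <- unname(map)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compose the trial label used in fixation reports
#'
#' Trials are keyed as `"<participant_id>__<picture_id>"` in combined
#' fixation reports.
#' @param participant_id,picture_id Character scalars/vectors.
#' @return Character vector of labels.
#' @export
make_trial_label <- function(participant_id, picture_id) {
  paste0(participant_id, "__", picture_id)
}
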