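#' Assign fixations to AOIs
#'
#' Labels each fixation with the AOI polygon containing its gaze position
#' (boundary points count as inside), after optional uniform outward
#' buffering of every polygon so that fixations recorded in the proximity of
#' a target are still attributed to it. Regions are tested in configuration
#' order and the first containing region wins (packaged layouts do not
#' overlap). Fixations outside the screen are flagged `off_screen` and left
#' unlabeled; fixations inside no region get `NA`.
#'
#' @param fixations Fixation tibble (`onset_ms`, `offset_ms`, `x_px`,
#'   `y_px`, ...).
#' @param config An [aoi_config()] for the trial's picture.
#' @param buffer_px Non-negative outward buffer in pixels (default 0; the
#'   packaged synthetic polygons are pre-buffered).
#' @return The fixation tibble with `aoi_label` and `off_screen` filled.
#' @export
assign_fixations <- function(fixations, config, buffer_px = 0) {
  stopifnot(inherits(config, "aoi_config"))
  fixations <- as_tibble(fixations)
  n <- nrow(fixations)
  fixations$aoi_label <- rep(NA_character_, n)
  if (n == 0) {
    fixations$off_screen <- logical(0)
    return(fixations)
  }
  x <- fixations$x_px; y <- fixations$y_px
  off <- x < 0 | x > config$screen[["width_px"]] |
    y < 0 | y > config$screen[["height_px"]]
  fixations$off_screen <- off
  label <- rep(NA_character_, n)
  todo <- which(!off)
  for (region in config$regions) {
    if (length(todo) == 0) break
    hit <- point_in_region(x[todo], y[todo], region, buffer_px = buffer_px)
    label[todo[hit]] <- region$label
    todo <- todo[!hit]
  }
  fixations$aoi_label <- label
  fixations
}

#' Pre-speech window of one utterance
#'
#' The planning window for utterance `i` runs from the onset of the previous
#' utterance to the onset of utterance `i` (half-open, `[start, end)`): in
#' incremental speech planning, the upcoming utterance is prepared while the
#' current one is produced. For the first utterance the window starts at
#' picture onset (trial time 0), since the first description is planned from
#' stimulus onset. Consecutive windows therefore tile
#' `[0, last utterance onset)` without gaps or overlap.
#'
#' @param trial A [trial_record()].
#' @param i Utterance index, 1-based.
#' @return List with `utterance_index`, `start_ms`, `end_ms`.
#' @export
prespeech_window <- function(trial, i) {
  stopifnot(inherits(trial, "trial_record"))
  n <- nrow(trial$utterances)
  if (!is.numeric(i) || length(i) != 1 || i < 1 || i > n) {
    abort_domain(sprintf("utterance index %s out of range 1..%d",
                         format(i), n))
  }
  i <- as.integer(i)
  start <- if (i == 1L) 0L else trial$utterances$onset_ms[i - 1L]
  list(utterance_index = i, start_ms = start,
       end_ms = trial$utterances$onset_ms[i])
}

#' Pre-speech windows of all utterances
#' @param trial A [trial_record()].
#' @return Tibble with one row per utterance.
#' @export
prespeech_windows <- function(trial) {
  n <- nrow(trial$utterances)
  if (n == 0) {
    return(tibble(utterance_index = integer(0), start_ms = integer(0),
                  end_ms = integer(0)))
  }
  tibble(utterance_index = seq_len(n),
         start_ms = c(0L, trial$utterances$onset_ms[-n]),
         end_ms = trial$utterances$onset_ms)
}

#' Pre-speech fixation count and duration
#'
#' For each AOI-related utterance (one whose content describes a specific
#' AOI, marked by a non-missing `aoi_label`), counts the fixations on that
#' same AOI whose onset falls in the utterance's pre-speech window, and sums
#' their durations. Utterances that do not describe an AOI (e.g. personal
#' commentary) contribute neither counts nor denominator. Totals are
#' divided by the number of AOI-related utterances.
#'
#' Fixation membership is decided by onset-in-window (fixations are atomic
#' events in Data-Viewer-style reports); `duration_mode = "onset"` credits
#' the full fixation duration, `"truncate"` clips it at the window end.
#' Windows are half-open, so a fixation starting exactly at an utterance
#' onset belongs to the next window.
#'
#' @param trial A [trial_record()] whose fixations carry `aoi_label`s (see
#'   [assign_fixations()]).
#' @param duration_mode `"onset"` (default) or `"truncate"`.
#' @return Object of class `prespeech_result`: list with `per_utterance`
#'   (tibble: `utterance_index`, `aoi_label`, `start_ms`, `end_ms`, `n_fix`,
#'   `dur_ms`; `NA` rows for non-AOI utterances), `n_aoi_utterances`,
#'   `count_total`, `dur_total`, `count_per_utt`, `dur_per_utt`. With no
#'   AOI-related utterances the aggregates are `NA` (undefined, not zero).
#' @export
prespeech_metrics <- function(trial, duration_mode = c("onset", "truncate")) {
  stopifnot(inherits(trial, "trial_record"))
  duration_mode <- match.arg(duration_mode)
  win <- prespeech_windows(trial)
  u <- trial$utterances
  fx <- trial$fixations
  n <- nrow(u)
  n_fix <- rep(NA_integer_, n)
  dur_ms <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(u$aoi_label[i])) next
    sel <- !is.na(fx$aoi_label) & fx$aoi_label == u$aoi_label[i] &
      fx$onset_ms >= win$start_ms[i] & fx$onset_ms < win$end_ms[i]
    n_fix[i] <- sum(sel)
    dur <- if (duration_mode == "onset") {
      fx$offset_ms[sel] - fx$onset_ms[sel]
    } else {
      pmin(fx$offset_ms[sel], win$end_ms[i]) - fx$onset_ms[sel]
    }
    dur_ms[i] <- sum(dur)
  }
  aoi_idx <- which(!is.na(u$aoi_label))
  n_aoi <- length(aoi_idx)
  count_total <- if (n_aoi > 0) sum(n_fix[aoi_idx]) else NA_integer_
  dur_total <- if (n_aoi > 0) sum(dur_ms[aoi_idx]) else NA_real_
  structure(list(
    per_utterance = tibble(utterance_index = u$index,
                           aoi_label = u$aoi_label,
                           start_ms = win$start_ms, end_ms = win$end_ms,
                           n_fix = n_fix, dur_ms = dur_ms),
    n_aoi_utterances = n_aoi,
    count_total = count_total,
    dur_total = dur_total,
    count_per_utt = if (n_aoi > 0) count_total / n_aoi else NA_real_,
    dur_per_utt = if (n_aoi > 0) dur_total / n_aoi else NA_real_),
    class = "prespeech_result")
}

#' @export
print.prespeech_result <- function(x, ...) {
  cat(sprintf(
    "<prespeech_result> %d AOI-related utterances; count/utt = %s, dur/utt = %s ms\n",
    x$n_aoi_utterances,
    format(x$count_per_utt, digits = 4), format(x$dur_per_utt, digits = 6)))
  invisible(x)
}
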