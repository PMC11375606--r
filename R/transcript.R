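# Domain containers: annotated tokens, timed utterances and the per-trial
# record combining speech and gaze streams.

TOKEN_FLAGS <- c("intelligible", "ciu", "sentence_ending_particle",
                 "conjunction", "conjunctive_suffix", "intonation_shift_after",
                 "contextually_connected_to_next")
TOKEN_COLUMNS <- c("surface", "lemma", "pos", TOKEN_FLAGS,
                   "pause_after_ms", "onset_ms", "offset_ms")

#' Build an annotated token tibble
#'
#' Convenience constructor for token streams. All annotation flags (part of
#' speech, intelligibility, CIU status, boundary markers) are inputs
#' produced by trained coders or by the synthetic generator; the pipeline
#' never infers them from text.
#'
#' @param surface Surface forms (character).
#' @param lemma Lemmas; default the surface forms.
#' @param pos Part of speech, one of `"common_noun"`, `"proper_noun"`,
#'   `"pronoun"`, `"main_verb"`, `"aux_verb"`, `"other"`.
#' @param intelligible,ciu,sentence_ending_particle,conjunction,conjunctive_suffix,intonation_shift_after,contextually_connected_to_next
#'   Logical annotation flags, recycled to length. A CIU must be one of the
#'   intelligible counted words, so `ciu` implies `intelligible`.
#' @param pause_after_ms Silent pause after each token, ms (>= 0).
#' @param onset_ms,offset_ms Token times on the trial clock (ms; picture
#'   onset = 0). Defaults lay tokens out contiguously at 400 ms each.
#' @return Tibble with one row per token.
#' @export
make_tokens <- function(surface, lemma = surface, pos = "other",
                        intelligible = TRUE, ciu = FALSE,
                        sentence_ending_particle = FALSE,
                        conjunction = FALSE,
                        conjunctive_suffix = FALSE,
                        intonation_shift_after = FALSE,
                        contextually_connected_to_next = FALSE,
                        pause_after_ms = 0,
                        onset_ms = NULL, offset_ms = NULL) {
  n <- length(surface)
  if (is.null(onset_ms)) onset_ms <- (seq_len(n) - 1L) * 400L
  if (is.null(offset_ms)) offset_ms <- onset_ms + 350L
  tok <- tibble(
    surface = as.character(surface),
    lemma = rep_len(as.character(lemma), n),
    pos = rep_len(as.character(pos), n),
    intelligible = rep_len(as_flag(intelligible), n),
    ciu = rep_len(as_flag(ciu), n),
    sentence_ending_particle = rep_len(as_flag(sentence_ending_particle), n),
    conjunction = rep_len(as_flag(conjunction), n),
    conjunctive_suffix = rep_len(as_flag(conjunctive_suffix), n),
    intonation_shift_after = rep_len(as_flag(intonation_shift_after), n),
    contextually_connected_to_next =
      rep_len(as_flag(contextually_connected_to_next), n),
    pause_after_ms = rep_len(as_ms(pause_after_ms, "pause_after_ms"), n),
    onset_ms = as_ms(onset_ms, "onset_ms"),
    offset_ms = as_ms(offset_ms, "offset_ms"))
  validate_tokens(tok)
  tok
}

validate_tokens <- function(tok) {
  check_enum(tok$pos, PRESPEECH_POS, "pos")
  bad <- which(tok$ciu & !tok$intelligible)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      paste0("token %d ('%s') is flagged as a CIU but not intelligible; ",
             "CIUs are a subset of the counted intelligible words"),
      bad[1], tok$surface[bad[1]]))
  }
  if (isTRUE(any(tok$offset_ms < tok$onset_ms))) {
    abort_validation("token offset_ms earlier than onset_ms")
  }
  if (anyNA(tok$pause_after_ms) ||
      isTRUE(any(tok$pause_after_ms < 0))) {
    abort_validation("pause_after_ms must be present and non-negative")
  }
  invisible(tok)
}

#' Assemble a trial record
#'
#' One participant x picture session: timed utterances with their annotated
#' tokens, the fixation stream and the total task duration. All times are
#' integer milliseconds on a per-trial clock starting at picture onset.
#'
#' @param participant_id Participant identifier.
#' @param group `"younger"` or `"older"`.
#' @param picture_id `"han_river"` or `"beach"`.
#' @param task_duration_ms Total task duration (ms, > 0).
#' @param utterances Tibble with columns `index` (1-based), `onset_ms`,
#'   `offset_ms` and optional `aoi_label` (`NA` for utterances that do not
#'   describe a specific AOI).
#' @param tokens Tibble of token rows (see [make_tokens()]) with an
#'   additional `utterance` index column.
#' @param fixations Optional tibble of fixation events (`onset_ms`,
#'   `offset_ms`, `x_px`, `y_px`, optional `off_screen`, `aoi_label`).
#' @param validate Run [validate_trial()] (default `TRUE`).
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(participant_id, group, picture_id, task_duration_ms,
                         utterances, tokens, fixations = NULL,
                         validate = TRUE) {
  utterances <- as_tibble(utterances)
  if (!"aoi_label" %in% names(utterances)) {
    utterances$aoi_label <- NA_character_
  }
  utterances$index <- as.integer(utterances$index)
  utterances$onset_ms <- as_ms(utterances$onset_ms)
  utterances$offset_ms <- as_ms(utterances$offset_ms)
  utterances$aoi_label <- as.character(utterances$aoi_label)
  utterances <- utterances[, c("index", "onset_ms", "offset_ms", "aoi_label")]
  tokens <- as_tibble(tokens)
  tokens$utterance <- as.integer(tokens$utterance)
  tokens <- tokens[, c("utterance", TOKEN_COLUMNS)]
  if (is.null(fixations)) fixations <- empty_fixations()
  fixations <- as_tibble(fixations)
  if (!"off_screen" %in% names(fixations)) fixations$off_screen <- FALSE
  if (!"aoi_label" %in% names(fixations)) fixations$aoi_label <- NA_character_
  fixations <- fixations[, c("onset_ms", "offset_ms", "x_px", "y_px",
                             "off_screen", "aoi_label")]
  fixations$onset_ms <- as_ms(fixations$onset_ms)
  fixations$offset_ms <- as_ms(fixations$offset_ms)
  trial <- structure(
    list(participant_id = as.character(participant_id),
         group = group, picture_id = picture_id,
         task_duration_ms = as_ms(task_duration_ms),
         utterances = utterances, tokens = tokens, fixations = fixations),
    class = "trial_record")
  if (validate) validate_trial(trial)
  trial
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf(
    "<trial_record> %s (%s) x %s: %d utterances, %d tokens, %d fixations, %.1f s\n",
    x$participant_id, x$group, x$picture_id, nrow(x$utterances),
    nrow(x$tokens), nrow(x$fixations), x$task_duration_ms / 1000))
  invisible(x)
}

#' Validate a trial record
#'
#' Enforces the container invariants: factor levels; positive task duration;
#' utterance onsets strictly increasing and intervals non-overlapping;
#' utterance onset/offset equal to their first/last token times; the
#' CIU-implies-intelligible subset rule; non-negative pauses; fixation
#' durations positive; all times within `[0, task_duration_ms]`; and, when
#' an AOI configuration is supplied, utterance AOI labels that name one of
#' its regions.
#'
#' @param trial A [trial_record()].
#' @param aoi_config Optional [aoi_config()] to check AOI labels against.
#' @return `trial`, invisibly; aborts with a validation error otherwise.
#' @export
validate_trial <- function(trial, aoi_config = NULL) {
  stopifnot(inherits(trial, "trial_record"))
  check_enum(trial$group, PRESPEECH_GROUPS, "group")
  check_enum(trial$picture_id, PRESPEECH_PICTURES, "picture_id")
  if (trial$task_duration_ms <= 0) {
    abort_validation("task_duration_ms must be positive")
  }
  u <- trial$utterances
  tok <- trial$tokens
  validate_tokens(tok)
  if (nrow(u) > 0) {
    if (!identical(u$index, seq_len(nrow(u)))) {
      abort_validation("utterance indices must be 1..n in order")
    }
    if (any(diff(u$onset_ms) <= 0)) {
      abort_validation("utterance onsets must be strictly increasing")
    }
    if (any(u$offset_ms[-nrow(u)] > u$onset_ms[-1])) {
      abort_validation("utterance intervals overlap")
    }
    uid <- tok$utterance
    if (is.unsorted(uid) || !identical(sort(unique(uid)), u$index)) {
      abort_validation(
        "tokens must cover utterances 1..n contiguously and in order")
    }
    first_idx <- which(!duplicated(uid))
    last_idx <- which(!duplicated(uid, fromLast = TRUE))
    bad <- which(u$onset_ms != tok$onset_ms[first_idx] |
                   u$offset_ms != tok$offset_ms[last_idx])
    if (length(bad) > 0) {
      abort_validation(sprintf(
        "utterance %d timing does not match its first/last token", bad[1]))
    }
  } else if (nrow(tok) > 0) {
    abort_validation("tokens present but no utterances")
  }
  times <- c(u$onset_ms, u$offset_ms, tok$onset_ms, tok$offset_ms,
             trial$fixations$onset_ms, trial$fixations$offset_ms)
  if (length(times) > 0 &&
      (min(times) < 0 || max(times) > trial$task_duration_ms)) {
    abort_validation("utterance/fixation times fall outside [0, task_duration_ms]")
  }
  fx <- trial$fixations
  if (nrow(fx) > 0 && any(fx$offset_ms <= fx$onset_ms)) {
    abort_validation("fixation with offset <= onset")
  }
  if (!is.null(aoi_config)) {
    lab <- u$aoi_label[!is.na(u$aoi_label)]
    bad <- setdiff(lab, aoi_labels(aoi_config))
    if (length(bad) > 0) {
      abort_validation(sprintf(
        "utterance AOI label(s) not in the %s configuration: %s",
        aoi_config$picture_id, paste(unique(bad), collapse = ", ")))
    }
  }
  invisible(trial)
}

#' Read a trial transcript from YAML
#'
#' A transcript document carries one trial: `participant_id`, `group`,
#' `picture_id`, `task_duration_ms` and an `utterances` list, each utterance
#' holding `onset_ms`, `offset_ms`, an optional `aoi_label` and a `tokens`
#' list with the full token annotation (see [make_tokens()]). Utterance
#' boundary times are measured input (checked against audio in ms), never
#' recomputed here.
#'
#' @param path Path to a YAML transcript.
#' @return A validated [trial_record()] without fixations.
#' @export
read_transcript <- function(path) {
  doc <- yaml::read_yaml(path)
  for (field in c("participant_id", "group", "picture_id",
                  "task_duration_ms", "utterances")) {
    if (is.null(doc[[field]])) {
      abort_format(sprintf("transcript '%s' lacks required field '%s'",
                           path, field))
    }
  }
  utt_rows <- list(); tok_rows <- list()
  for (i in seq_along(doc$utterances)) {
    u <- doc$utterances[[i]]
    utt_rows[[i]] <- tibble(
      index = i,
      onset_ms = u$onset_ms %||% NA_integer_,
      offset_ms = u$offset_ms %||% NA_integer_,
      aoi_label = u$aoi_label %||% NA_character_)
    toks <- lapply(u$tokens, function(tk) {
      row <- lapply(TOKEN_COLUMNS, function(col) tk[[col]])
      names(row) <- TOKEN_COLUMNS
      as_tibble(row)
    })
    tk <- bind_rows(toks)
    tk$utterance <- i
    tok_rows[[i]] <- tk
  }
  utterances <- bind_rows(utt_rows)
  tokens <- bind_rows(tok_rows)
  if (anyNA(utterances$onset_ms) || anyNA(utterances$offset_ms)) {
    abort_format(sprintf("transcript '%s' has utterances without timing", path))
  }
  for (fl in TOKEN_FLAGS) tokens[[fl]] <- as_flag(tokens[[fl]], fl)
  tokens$pause_after_ms <- as_ms(tokens$pause_after_ms, "pause_after_ms")
  tokens$onset_ms <- as_ms(tokens$onset_ms)
  tokens$offset_ms <- as_ms(tokens$offset_ms)
  trial_record(doc$participant_id, doc$group, doc$picture_id,
               doc$task_duration_ms, utterances, tokens, validate = TRUE)
}

#' Write a trial transcript to YAML
#'
#' Inverse of [read_transcript()]; fixations are not part of the transcript
#' schema and are written separately via [write_fixation_report()].
#'
#' @param trial A [trial_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(trial, path) {
  stopifnot(inherits(trial, "trial_record"))
  utterances <- lapply(trial$utterances$index, function(i) {
    u <- trial$utterances[i, ]
    tk <- trial$tokens[trial$tokens$utterance == i, TOKEN_COLUMNS]
    out <- list(onset_ms = u$onset_ms, offset_ms = u$offset_ms)
    if (!is.na(u$aoi_label)) out$aoi_label <- u$aoi_label
    out$tokens <- lapply(seq_len(nrow(tk)), function(j) as.list(tk[j, ]))
    out
  })
  doc <- list(participant_id = trial$participant_id,
              group = trial$group,
              picture_id = trial$picture_id,
              task_duration_ms = trial$task_duration_ms,
              utterances = utterances)
  yaml::write_yaml(doc, path)
  invisible(path)
}
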