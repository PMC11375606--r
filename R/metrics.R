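#' Word and CIU counts for a trial
#'
#' The word count is the number of tokens intelligible in context (accuracy
#' and relevance are not required at this stage); the CIU count is the
#' number of those words additionally flagged as accurate, relevant and
#' informative about the stimulus. Non-word fillers carry
#' `intelligible = FALSE` and therefore never enter either count.
#'
#' @param trial A [trial_record()].
#' @return List with `word_count` and `ciu_count`.
#' @export
lexical_counts <- function(trial) {
  stopifnot(inherits(trial, "trial_record"))
  list(word_count = sum(trial$tokens$intelligible),
       ciu_count = sum(trial$tokens$ciu))
}

rate_per_minute <- function(count, task_duration_ms) {
  if (task_duration_ms <= 0) {
    abort_domain("task_duration_ms must be positive to compute a rate")
  }
  count * 60000 / task_duration_ms
}

#' Correct Information Units per minute
#'
#' CIU count normalised by the task duration in minutes — the
#' informativeness measure of connected speech.
#' @param trial A [trial_record()].
#' @return Numeric rate (CIUs/min).
#' @export
cius_per_minute <- function(trial) {
  rate_per_minute(lexical_counts(trial)$ciu_count, trial$task_duration_ms)
}

#' Words per minute
#'
#' Intelligible-word count normalised by the task duration in minutes; used
#' to rule out speech-rate differences as a confound of the gaze measures.
#' @param trial A [trial_record()].
#' @return Numeric rate (words/min).
#' @export
words_per_minute <- function(trial) {
  rate_per_minute(lexical_counts(trial)$word_count, trial$task_duration_ms)
}

#' Noun and verb type/token counts
#'
#' Productivity measures. Among the intelligible tokens of a trial, nouns
#' (common nouns, proper nouns and pronouns — pronouns pattern with content
#' nouns in Korean case marking and reference) and verbs (main and auxiliary
#' verbs — auxiliaries are semantically independent verbs in serial verb
#' constructions) are tallied as tokens (occurrences) and types (distinct
#' lemmas per class within the trial). Per-utterance variants divide by the
#' trial's utterance count to offset sheer utterance volume.
#'
#' @param trial A [trial_record()].
#' @param type_key Field used for type identity: `"lemma"` (default;
#'   inflected forms of one word count once) or `"surface"`.
#' @return One-row tibble with `nouns_token`, `nouns_type`, `verbs_token`,
#'   `verbs_type` and their `_per_utt` variants (NA when the trial has no
#'   utterances and no tokens).
#' @export
nv_counts <- function(trial, type_key = c("lemma", "surface")) {
  stopifnot(inherits(trial, "trial_record"))
  type_key <- match.arg(type_key)
  tok <- trial$tokens[trial$tokens$intelligible, ]
  n_utt <- nrow(trial$utterances)
  nouns <- tok[tok$pos %in% NOUN_POS, ]
  verbs <- tok[tok$pos %in% VERB_POS, ]
  raw <- tibble(
    nouns_token = nrow(nouns),
    nouns_type = length(unique(nouns[[type_key]])),
    verbs_token = nrow(verbs),
    verbs_type = length(unique(verbs[[type_key]])))
  if (n_utt == 0) {
    if (raw$nouns_token + raw$verbs_token > 0) {
      abort_validation("trial has tokens but no utterances; cannot normalise")
    }
    per <- raw
    per[1, ] <- NA_real_
  } else {
    per <- raw / n_utt
  }
  names(per) <- paste0(names(raw), "_per_utt")
  tibble(raw, per)
}

#' Per-trial dependent measures
#'
#' Computes the full row of dependent measures for one trial:
#' informativeness (CIUs/min), productivity (noun/verb types and tokens per
#' utterance), the pre-speech fixation statistics (when fixations and an
#' AOI configuration are available) and words per minute.
#'
#' @param trial A [trial_record()].
#' @param aoi_config Optional [aoi_config()]; when supplied, fixations are
#'   (re-)assigned to AOIs before the pre-speech statistics are computed.
#'   When omitted, existing `aoi_label`s on the fixations are used; if the
#'   trial has no fixations the gaze columns are `NA`.
#' @param buffer_px Outward AOI buffer passed to [assign_fixations()].
#' @param duration_mode Fixation duration crediting, see
#'   [prespeech_metrics()].
#' @return One-row tibble (`participant_id`, `group`, `picture_id`,
#'   `cius_per_min`, noun/verb per-utterance counts,
#'   `prespeech_count_per_utt`, `prespeech_dur_per_utt`, `wpm`).
#' @export
trial_metrics <- function(trial, aoi_config = NULL, buffer_px = 0,
                          duration_mode = c("onset", "truncate")) {
  duration_mode <- match.arg(duration_mode)
  nv <- nv_counts(trial)
  pre_count <- NA_real_
  pre_dur <- NA_real_
  if (!is.null(aoi_config)) {
    trial$fixations <- assign_fixations(trial$fixations, aoi_config,
                                        buffer_px = buffer_px)
  }
  if (nrow(trial$fixations) > 0 || any(!is.na(trial$utterances$aoi_label))) {
    pre <- prespeech_metrics(trial, duration_mode = duration_mode)
    pre_count <- pre$count_per_utt
    pre_dur <- pre$dur_per_utt
  }
  tibble(participant_id = trial$participant_id,
         group = trial$group,
         picture_id = trial$picture_id,
         cius_per_min = cius_per_minute(trial),
         nouns_token_per_utt = nv$nouns_token_per_utt,
         nouns_type_per_utt = nv$nouns_type_per_utt,
         verbs_token_per_utt = nv$verbs_token_per_utt,
         verbs_type_per_utt = nv$verbs_type_per_utt,
         prespeech_count_per_utt = pre_count,
         prespeech_dur_per_utt = pre_dur,
         wpm = words_per_minute(trial))
}

#' Dependent measures for a set of trials
#'
#' @param trials List of [trial_record()] objects.
#' @param aoi_configs Named list of [aoi_config()] objects keyed by
#'   `picture_id`, or `NULL` to use the packaged defaults, or `NA` to skip
#'   AOI assignment (gaze columns then rely on existing labels).
#' @inheritParams trial_metrics
#' @return Tibble with one row per trial.
#' @export
cohort_metrics <- function(trials, aoi_configs = NULL, buffer_px = 0,
                           duration_mode = c("onset", "truncate")) {
  duration_mode <- match.arg(duration_mode)
  if (is.null(aoi_configs)) aoi_configs <- default_aoi_configs()
  rows <- lapply(trials, function(tr) {
    cfg <- if (is.list(aoi_configs)) aoi_configs[[tr$picture_id]] else NULL
    trial_metrics(tr, aoi_config = cfg, buffer_px = buffer_px,
                  duration_mode = duration_mode)
  })
  bind_rows(rows)
}

METRICS_COLUMNS <- c("participant_id", "group", "picture_id", "cius_per_min",
                     "nouns_token_per_utt", "nouns_type_per_utt",
                     "verbs_token_per_utt", "verbs_type_per_utt",
                     "prespeech_count_per_utt", "prespeech_dur_per_utt",
                     "wpm")

#' Write a metrics table as CSV
#'
#' Fixed column order: participant, group, picture, CIUs/min, noun/verb
#' tokens and types per utterance, pre-speech fixation count and duration
#' per utterance, words per minute.
#'
#' @param metrics Tibble as returned by [cohort_metrics()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  missing_cols <- setdiff(METRICS_COLUMNS, names(metrics))
  if (length(missing_cols) > 0) {
    abort_format(sprintf("metrics table lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  write.csv(as.data.frame(metrics[, METRICS_COLUMNS]), path,
            row.names = FALSE)
  invisible(path)
}
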