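#' Segmentation configuration
#'
#' Thresholds of the utterance segmentation rules: the silent-pause
#' threshold (a pause of *more than* this many milliseconds between words
#' forces an utterance boundary; default 2,000 ms) and the conjunctive-suffix
#' limit (lacking an intonation shift or over-threshold pause, an utterance
#' extends only to this many conjunctive suffixes; default 2).
#'
#' @param pause_threshold_ms Positive pause threshold in ms.
#' @param conjunctive_suffix_limit Positive integer suffix limit.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(pause_threshold_ms = 2000,
                                conjunctive_suffix_limit = 2) {
  if (!is.numeric(pause_threshold_ms) || pause_threshold_ms <= 0) {
    abort_config("pause_threshold_ms must be positive")
  }
  if (!is.numeric(conjunctive_suffix_limit) || conjunctive_suffix_limit < 1) {
    abort_config("conjunctive_suffix_limit must be >= 1")
  }
  structure(list(pause_threshold_ms = pause_threshold_ms,
                 conjunctive_suffix_limit = as.integer(conjunctive_suffix_limit)),
            class = "segmentation_config")
}

#' Segment an annotated token stream into utterances
#'
#' Applies the Korean-convention segmentation rules to a flat token stream:
#'
#' 1. An utterance ends after a token carrying a sentence-ending particle,
#'    unless that token is flagged as contextually connected to the next
#'    word (a coder judgment, supplied as input).
#' 2. A conjunction opens a new utterance: the stream breaks immediately
#'    before a token flagged as a conjunction, and the new utterance runs to
#'    the next sentence-ending particle.
#' 3. A silent pause of more than `pause_threshold_ms` between words always
#'    ends the utterance (a pause of exactly the threshold does not).
#' 4. Once a conjunctive suffix has occurred in the current utterance, the
#'    utterance ends at the first subsequent intonation shift or
#'    over-threshold pause; lacking both, it ends after the
#'    `conjunctive_suffix_limit`-th conjunctive suffix. The suffix count
#'    restarts at every utterance boundary.
#'
#' When several rules fire at the same junction the pause rule takes
#' precedence over the sentence-ending rule, which takes precedence over the
#' suffix rule; precedence only matters for the sentence-ending rule's
#' continuation exception, which an over-threshold pause overrides.
#'
#' @param tokens Token tibble (see [make_tokens()]); marker flags and
#'   `pause_after_ms` must be present and non-missing.
#' @param config A [segmentation_config()].
#' @return The token tibble with an added integer `utterance` column.
#'   Flattening the result reproduces the input tokens in order. An empty
#'   input yields an empty result.
#' @export
segment_utterances <- function(tokens, config = segmentation_config()) {
  stopifnot(inherits(config, "segmentation_config"))
  tokens <- as_tibble(tokens)
  tokens$utterance <- NULL
  n <- nrow(tokens)
  if (n == 0) {
    tokens$utterance <- integer(0)
    return(tokens[, c("utterance", names(tokens)[names(tokens) != "utterance"])])
  }
  if (anyNA(tokens$pause_after_ms)) {
    abort_validation("pause_after_ms missing: timing-dependent segmentation rules cannot fire")
  }
  validate_tokens(tokens)
  breaks <- logical(n)
  suffix_count <- 0L
  for (i in seq_len(n)) {
    if (tokens$conjunctive_suffix[i]) suffix_count <- suffix_count + 1L
    br <-
      tokens$pause_after_ms[i] > config$pause_threshold_ms ||          # R3
      (tokens$sentence_ending_particle[i] &&
         !tokens$contextually_connected_to_next[i]) ||                 # R1
      (suffix_count >= 1L && tokens$intonation_shift_after[i]) ||      # R4a
      (tokens$conjunctive_suffix[i] &&
         suffix_count >= config$conjunctive_suffix_limit) ||           # R4b
      (i < n && tokens$conjunction[i + 1L])                            # R2
    if (br || i == n) {
      breaks[i] <- TRUE
      suffix_count <- 0L
    }
  }
  ids <- cumsum(c(1L, head(as.integer(breaks), -1)))
  tokens$utterance <- ids
  tokens[, c("utterance", setdiff(names(tokens), "utterance"))]
}

#' Build an utterance table from segmented tokens
#'
#' @param tokens Token tibble with an `utterance` column (as returned by
#'   [segment_utterances()] or stored in a [trial_record()]).
#' @return Tibble with `index`, `onset_ms`, `offset_ms`, `n_tokens`,
#'   `aoi_label` (`NA`; AOI mapping is a coder judgment).
#' @export
build_utterances <- function(tokens) {
  if (nrow(tokens) == 0) {
    return(tibble(index = integer(0), onset_ms = integer(0),
                  offset_ms = integer(0), n_tokens = integer(0),
                  aoi_label = character(0)))
  }
  ids <- sort(unique(tokens$utterance))
  rows <- lapply(seq_along(ids), function(k) {
    tk <- tokens[tokens$utterance == ids[k], ]
    tibble(index = k, onset_ms = tk$onset_ms[1],
           offset_ms = tk$offset_ms[nrow(tk)],
           n_tokens = nrow(tk), aoi_label = NA_character_)
  })
  bind_rows(rows)
}

#' Re-segment a trial and compare against its stored boundaries
#'
#' Runs the rule engine over the trial's flat token stream and reports
#' whether the recomputed boundaries agree with the utterance boundaries
#' stored in the transcript (which are coder-supplied input).
#'
#' @param trial A [trial_record()].
#' @param config A [segmentation_config()].
#' @return List with `identical` (flag), `n_stored`, `n_recomputed`, and
#'   `diff`, a tibble of token positions after which exactly one of the two
#'   segmentations places a boundary.
#' @export
resegment_trial <- function(trial, config = segmentation_config()) {
  stopifnot(inherits(trial, "trial_record"))
  tok <- trial$tokens
  seg <- segment_utterances(tok[, TOKEN_COLUMNS], config)
  stored_breaks <- which(diff(c(tok$utterance, Inf)) != 0)
  new_breaks <- which(diff(c(seg$utterance, Inf)) != 0)
  only_stored <- setdiff(stored_breaks, new_breaks)
  only_new <- setdiff(new_breaks, stored_breaks)
  diff_tbl <- bind_rows(
    tibble(token_position = only_stored, boundary_in = "transcript"),
    tibble(token_position = only_new, boundary_in = "rules"))
  list(identical = nrow(diff_tbl) == 0,
       n_stored = length(stored_breaks),
       n_recomputed = length(new_breaks),
       diff = diff_tbl)
}
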