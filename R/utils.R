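# Condition helpers: every user-facing failure is a classed condition so the
# CLI can map validation errors and runtime errors to distinct exit codes.

prespeech_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "prespeech_error"), ...)
}

abort_validation <- function(message, ...) {
  prespeech_abort(message, "prespeech_validation_error", ...)
}
abort_format <- function(message, ...) {
  prespeech_abort(message, "prespeech_format_error", ...)
}
abort_parse <- function(message, ...) {
  prespeech_abort(message, "prespeech_parse_error", ...)
}
abort_geometry <- function(message, ...) {
  prespeech_abort(message, "prespeech_geometry_error", ...)
}
abort_config <- function(message, ...) {
  prespeech_abort(message, "prespeech_config_error", ...)
}
abort_domain <- function(message, ...) {
  prespeech_abort(message, "prespeech_domain_error", ...)
}
abort_design <- function(message, ...) {
  prespeech_abort(message, "prespeech_design_error", ...)
}

# Factor levels of the study design and the token part-of-speech inventory.
PRESPEECH_GROUPS <- c("younger", "older")
PRESPEECH_PICTURES <- c("han_river", "beach")
PRESPEECH_POS <- c("common_noun", "proper_noun", "pronoun",
                   "main_verb", "aux_verb", "other")
NOUN_POS <- c("common_noun", "proper_noun", "pronoun")
VERB_POS <- c("main_verb", "aux_verb")
AOI_ROLES <- c("active_agent", "static_object")

# Default screen geometry of the recording setup (pixels, origin top-left).
SCREEN_DEFAULT <- c(width_px = 1680, height_px = 1050)

as_ms <- function(x, what = "time") {
  if (length(x) == 0) return(integer(0))
  if (!is.numeric(x)) abort_format(sprintf("%s must be numeric", what))
  as.integer(round(x))
}

as_flag <- function(x, what = "flag") {
  x <- as.logical(x)
  if (anyNA(x)) abort_format(sprintf("%s contains missing values", what))
  x
}

check_enum <- function(x, levels, what) {
  bad <- setdiff(unique(x), levels)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "invalid %s value(s): %s (expected one of %s)",
      what, paste(bad, collapse = ", "), paste(levels, collapse = ", ")))
  }
  invisible(x)
}
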