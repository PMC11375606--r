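Package: prespeech
Title: Gaze-Speech Alignment and Connected-Speech Metrics for Picture
    Description Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing connected speech elicited by picture
    description tasks alongside concurrent eye tracking.  Reads timed,
    token-annotated transcripts, fixation event reports and area-of-interest
    (AOI) polygon configurations; segments token streams into utterances with
    Korean-convention rules (sentence-ending particles, conjunctions, pauses
    over two seconds, conjunctive suffixes); scores informativeness (Correct
    Information Units per minute) and productivity (noun and verb types and
    tokens per utterance); assigns fixations to AOIs and computes pre-speech
    fixation counts and durations in the window from the previous utterance
    onset to the current utterance onset; and fits two-by-two and
    two-by-two-by-two mixed-design analyses of variance with partial eta
    squared effect sizes.  A synthetic-cohort generator with eye-voice-span
    coupled fixations supports end-to-end validation and power analysis when
    participant data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    mgcv,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
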