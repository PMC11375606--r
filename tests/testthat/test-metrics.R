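# build a minimal trial directly from token flags
flag_trial <- function(intelligible, ciu, pos = NULL, lemma = NULL,
                       n_utt = 1, task_duration_ms = 60000) {
  n <- length(intelligible)
  if (is.null(pos)) pos <- rep("other", n)
  if (is.null(lemma)) lemma <- paste0("w", seq_len(n))
  per <- ceiling(n / n_utt)
  utt <- rep(seq_len(n_utt), each = per)[seq_len(n)]
  onsets <- (seq_len(n) - 1L) * 400L
  offsets <- onsets + 350L
  tokens <- make_tokens(lemma, lemma = lemma, pos = pos,
                        intelligible = intelligible, ciu = ciu,
                        sentence_ending_particle = c(diff(utt) == 1, TRUE),
                        onset_ms = onsets, offset_ms = offsets)
  tokens$utterance <- utt
  first <- which(!duplicated(utt)); last <- which(!duplicated(utt, fromLast = TRUE))
  trial_record("P01", "younger", "beach", task_duration_ms,
               utterances = tibble::tibble(index = seq_len(n_utt),
                                           onset_ms = onsets[first],
                                           offset_ms = offsets[last]),
               tokens = tokens)
}

test_that("word and CIU counts follow the intelligible-word subset rule", {
  tr <- flag_trial(intelligible = rep(c(TRUE, FALSE), c(8, 2)),
                   ciu = rep(c(TRUE, FALSE), c(5, 5)))
  expect_equal(lexical_counts(tr), list(word_count = 8, ciu_count = 5))
  tr0 <- flag_trial(intelligible = rep(FALSE, 4), ciu = rep(FALSE, 4))
  expect_equal(lexical_counts(tr0), list(word_count = 0, ciu_count = 0))
})

test_that("rates normalise counts by task duration in minutes", {
  tr <- flag_trial(intelligible = rep(TRUE, 30), ciu = rep(TRUE, 30),
                   task_duration_ms = 60000)
  expect_equal(cius_per_minute(tr), 30)
  tr2 <- flag_trial(intelligible = rep(TRUE, 45), ciu = rep(TRUE, 45),
                    task_duration_ms = 90000)
  expect_equal(cius_per_minute(tr2), 30)  # scale invariance
  expect_equal(words_per_minute(tr), 30)
  tr$task_duration_ms <- 0L
  expect_error(cius_per_minute(tr), class = "prespeech_domain_error")
})

test_that("noun/verb tallies count tokens and distinct lemmas per class", {
  tr <- flag_trial(intelligible = rep(TRUE, 4), ciu = rep(FALSE, 4),
                   pos = c("common_noun", "common_noun", "main_verb",
                           "aux_verb"),
                   lemma = c("dog", "dog", "run", "give"))
  nv <- nv_counts(tr)
  expect_equal(nv$nouns_token, 2)
  expect_equal(nv$nouns_type, 1)
  expect_equal(nv$verbs_token, 2)
  expect_equal(nv$verbs_type, 2)
  expect_equal(nv$nouns_token_per_utt, 2)

  # the same tokens over two utterances halve the per-utterance values
  tr2 <- flag_trial(intelligible = rep(TRUE, 4), ciu = rep(FALSE, 4),
                    pos = c("common_noun", "common_noun", "main_verb",
                            "aux_verb"),
                    lemma = c("dog", "dog", "run", "give"), n_utt = 2)
  nv2 <- nv_counts(tr2)
  expect_equal(nv2$nouns_token_per_utt, 1)
  expect_equal(nv2$verbs_type_per_utt, 1)
})

test_that("random trials match brute-force tallies and count invariants", {
  withr::local_seed(31)
  for (rep in 1:150) {
    n <- sample(5:60, 1)
    pos <- sample(c("common_noun", "proper_noun", "pronoun", "main_verb",
                    "aux_verb", "other"), n, replace = TRUE)
    lemma <- sample(paste0("lem", 1:12), n, replace = TRUE)
    intel <- runif(n) < 0.8
    ciu <- intel & runif(n) < 0.6
    tr <- flag_trial(intel, ciu, pos, lemma, n_utt = sample(1:4, 1),
                     task_duration_ms = sample(30000:120000, 1))
    lc <- lexical_counts(tr)
    expect_equal(lc$word_count, sum(intel))
    expect_equal(lc$ciu_count, sum(ciu))
    expect_lte(lc$ciu_count, lc$word_count)
    expect_lte(lc$word_count, n)
    expect_equal(cius_per_minute(tr), sum(ciu) * 60000 / tr$task_duration_ms)
    nv <- nv_counts(tr)
    noun_sel <- intel & pos %in% c("common_noun", "proper_noun", "pronoun")
    verb_sel <- intel & pos %in% c("main_verb", "aux_verb")
    expect_equal(nv$nouns_token, sum(noun_sel))
    expect_equal(nv$nouns_type, length(unique(lemma[noun_sel])))
    expect_equal(nv$verbs_token, sum(verb_sel))
    expect_equal(nv$verbs_type, length(unique(lemma[verb_sel])))
    expect_lte(nv$nouns_type, max(nv$nouns_token, 1))
    n_utt <- nrow(tr$utterances)
    expect_equal(nv$verbs_token_per_utt, nv$verbs_token / n_utt)
  }
})
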