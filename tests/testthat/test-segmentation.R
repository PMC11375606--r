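test_that("single clause with a final sentence-ending particle stays whole", {
  tok <- make_tokens(c("ai-ka", "kong-ul", "cha-yo"),
                     sentence_ending_particle = c(FALSE, FALSE, TRUE))
  seg <- segment_utterances(tok)
  expect_equal(seg$utterance, rep(1L, 3))
})

test_that("pauses split only when strictly above the two-second threshold", {
  tok <- make_tokens(c("a", "b"), pause_after_ms = c(2500, 0))
  expect_equal(segment_utterances(tok)$utterance, c(1L, 2L))
  tok2 <- make_tokens(c("a", "b"), pause_after_ms = c(2000, 0))
  expect_equal(segment_utterances(tok2)$utterance, c(1L, 1L))
})

test_that("marker rules fire as stated", {
  # conjunction opens a new utterance (and closes the preceding one)
  tok <- make_tokens(c("a", "b", "geu-rigo", "d"),
                     conjunction = c(FALSE, FALSE, TRUE, FALSE),
                     sentence_ending_particle = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(segment_utterances(tok)$utterance, c(1L, 1L, 2L, 2L))

  # contextually connected words extend past a sentence-ending particle
  tok <- make_tokens(c("a", "b", "c"),
                     sentence_ending_particle = c(TRUE, FALSE, TRUE),
                     contextually_connected_to_next = c(TRUE, FALSE, FALSE))
  expect_equal(segment_utterances(tok)$utterance, rep(1L, 3))
  # ... but an over-threshold pause at the same junction still splits
  tok$pause_after_ms <- c(2600L, 0L, 0L)
  expect_equal(segment_utterances(tok)$utterance, c(1L, 2L, 2L))

  # after a conjunctive suffix, an intonation shift ends the utterance
  tok <- make_tokens(c("a", "b", "c", "d"),
                     conjunctive_suffix = c(TRUE, FALSE, FALSE, FALSE),
                     intonation_shift_after = c(FALSE, TRUE, FALSE, FALSE),
                     sentence_ending_particle = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(segment_utterances(tok)$utterance, c(1L, 1L, 2L, 2L))
  # ... an intonation shift with no preceding suffix does not
  tok$conjunctive_suffix <- rep(FALSE, 4)
  expect_equal(segment_utterances(tok)$utterance, rep(1L, 4))

  # without a shift or pause, the second conjunctive suffix ends it
  tok <- make_tokens(c("a", "b", "c", "d"),
                     conjunctive_suffix = c(TRUE, FALSE, TRUE, FALSE),
                     sentence_ending_particle = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(segment_utterances(tok)$utterance, c(1L, 1L, 1L, 2L))
})

test_that("random marker streams match the independent scanner", {
  withr::local_seed(21)
  for (rep in 1:300) {
    tok <- rand_marker_stream(sample(1:40, 1))
    seg <- segment_utterances(tok)
    expect_equal(seg$utterance, seg_oracle(tok),
                 info = sprintf("stream %d", rep))
    # token conservation and well-formed utterances
    expect_equal(seg[, names(tok)], tok)
    u <- build_utterances(seg)
    expect_true(all(u$n_tokens >= 1))
    expect_true(all(diff(u$onset_ms) > 0) || nrow(u) <= 1)
  }
})

test_that("raising the pause threshold never increases the utterance count", {
  withr::local_seed(22)
  for (rep in 1:150) {
    tok <- rand_marker_stream(sample(2:40, 1))
    counts <- vapply(c(1000, 2000, 2600, 4000), function(thr) {
      max(segment_utterances(tok, segmentation_config(thr))$utterance)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0), info = sprintf("stream %d", rep))
  }
})

test_that("segmentation is idempotent and total on edge inputs", {
  withr::local_seed(23)
  tok <- rand_marker_stream(30)
  seg <- segment_utterances(tok)
  again <- segment_utterances(seg[, setdiff(names(seg), "utterance")])
  expect_equal(again$utterance, seg$utterance)

  empty <- segment_utterances(make_tokens(character(0)))
  expect_equal(nrow(empty), 0)

  tok$pause_after_ms[3] <- NA_integer_
  expect_error(segment_utterances(tok), "timing",
               class = "prespeech_validation_error")
})

test_that("generated transcripts reproduce their stored boundaries", {
  co <- suppressWarnings(
    generate_cohort(cohort_config(n_younger = 2, n_older = 2, rng_seed = 5)))
  for (tr in co$trials) {
    expect_true(resegment_trial(tr)$identical)
  }
})
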