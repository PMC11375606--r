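square_region <- function(label, x0, y0, side = 100) {
  aoi_region(label, "active_agent",
             rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side),
                   c(x0, y0 + side)))
}

test_that("fixations are assigned to containing AOIs, with buffer and bounds", {
  cfg <- aoi_config("beach", list(square_region("a", 100, 100),
                                  square_region("b", 400, 400)))
  fx <- tibble::tibble(onset_ms = c(0, 100, 200, 300, 400),
                       offset_ms = c(50, 150, 250, 350, 450),
                       x_px = c(150, 450, 800, 150, -5),
                       y_px = c(150, 450, 800, 100, 500))
  out <- assign_fixations(fx, cfg)
  expect_equal(out$aoi_label, c("a", "b", NA, "a", NA))  # boundary is inside
  expect_equal(out$off_screen, c(FALSE, FALSE, FALSE, FALSE, TRUE))

  # a point 10 px outside region 'a' is captured by a 15 px buffer only
  out0 <- assign_fixations(tibble::tibble(onset_ms = 0, offset_ms = 10,
                                          x_px = 90, y_px = 150), cfg)
  expect_true(is.na(out0$aoi_label))
  out15 <- assign_fixations(tibble::tibble(onset_ms = 0, offset_ms = 10,
                                           x_px = 90, y_px = 150), cfg,
                            buffer_px = 15)
  expect_equal(out15$aoi_label, "a")
})

test_that("polygon membership agrees with a ray-casting oracle on random points", {
  withr::local_seed(41)
  cfgs <- default_aoi_configs()
  for (pic in names(cfgs)) {
    cfg <- cfgs[[pic]]
    x <- runif(5000, 0, 1680)
    y <- runif(5000, 0, 1050)
    for (region in cfg$regions) {
      got <- point_in_region(x, y, region)
      want <- vapply(seq_along(x), function(i)
        ray_pip(x[i], y[i], region$vertices), logical(1))
      expect_equal(got, want, info = paste(pic, region$label))
    }
  }
})

test_that("pre-speech windows run from the previous onset and tile the trial", {
  tr <- rand_trial(n_utt = 3)
  tr$utterances$onset_ms <- c(1000L, 4000L, 9000L)
  w <- prespeech_window(tr, 2)
  expect_equal(c(w$start_ms, w$end_ms), c(1000, 4000))
  w1 <- prespeech_window(tr, 1)
  expect_equal(c(w1$start_ms, w1$end_ms), c(0, 1000))
  expect_error(prespeech_window(tr, 4), class = "prespeech_domain_error")

  withr::local_seed(42)
  for (rep in 1:25) {
    tr <- rand_trial(n_utt = sample(2:10, 1))
    w <- prespeech_windows(tr)
    expect_equal(w$start_ms, c(0L, tr$utterances$onset_ms[-nrow(w)]))
    expect_equal(w$end_ms, tr$utterances$onset_ms)
    expect_true(all(w$start_ms[-1] == w$end_ms[-nrow(w)]))  # no gaps/overlap
  }
})

test_that("a hand-checkable construction yields count 2 and duration 1,000 ms", {
  tokens <- make_tokens("dog", pos = "common_noun",
                        sentence_ending_particle = TRUE,
                        onset_ms = 2000, offset_ms = 2400)
  tokens$utterance <- 1L
  tr <- trial_record(
    "P01", "younger", "beach", 4000,
    utterances = tibble::tibble(index = 1L, onset_ms = 2000L,
                                offset_ms = 2400L, aoi_label = "dog"),
    tokens = tokens,
    fixations = tibble::tibble(
      onset_ms = c(500L, 1000L, 1200L), offset_ms = c(900L, 1100L, 1800L),
      x_px = 1, y_px = 1,
      aoi_label = c("dog", "cat", "dog")))
  res <- prespeech_metrics(tr)
  expect_equal(res$count_total, 2)
  expect_equal(res$dur_total, 1000)
  expect_equal(res$count_per_utt, 2)
  expect_equal(res$dur_per_utt, 1000)
})

test_that("trials with only non-AOI commentary report missing aggregates", {
  tr <- rand_trial(n_utt = 3, aoi_prob = 0)
  res <- prespeech_metrics(tr)
  expect_equal(res$n_aoi_utterances, 0)
  expect_true(is.na(res$count_per_utt))
  expect_true(is.na(res$dur_per_utt))
})

test_that("random trials match the quadratic oracle under both duration modes", {
  withr::local_seed(43)
  for (rep in 1:120) {
    tr <- rand_trial(n_utt = sample(2:8, 1), n_fix = sample(10:60, 1))
    for (mode in c("onset", "truncate")) {
      got <- prespeech_metrics(tr, duration_mode = mode)
      want <- pre_oracle(tr, mode)
      expect_equal(got$n_aoi_utterances, want$n_aoi)
      expect_equal(got$count_per_utt, want$count_per_utt)
      expect_equal(got$dur_per_utt, want$dur_per_utt)
      if (mode == "onset" && !is.na(got$count_per_utt) &&
          got$count_total > 0) {
        min_dur <- min(tr$fixations$offset_ms - tr$fixations$onset_ms)
        expect_gte(got$dur_per_utt, got$count_per_utt * min_dur)
      }
    }
  }
})

test_that("pre-speech statistics are invariant to time shifts and to
           fixations on unrelated AOIs", {
  withr::local_seed(44)
  base <- rand_trial(n_utt = 6, n_fix = 50)
  shifted <- withr::with_seed(101, rand_trial(n_utt = 6, n_fix = 50))
  ref <- withr::with_seed(101, rand_trial(n_utt = 6, n_fix = 50,
                                          shift_ms = 7000))
  a <- prespeech_metrics(shifted)
  b <- prespeech_metrics(ref)
  expect_equal(a$count_per_utt, b$count_per_utt)
  expect_equal(a$dur_per_utt, b$dur_per_utt)

  res <- prespeech_metrics(base)
  targets <- unique(stats::na.omit(base$utterances$aoi_label))
  keep <- !is.na(base$fixations$aoi_label) &
    base$fixations$aoi_label %in% targets
  pruned <- base
  pruned$fixations <- base$fixations[keep, ]
  res2 <- prespeech_metrics(pruned)
  expect_equal(res$count_per_utt, res2$count_per_utt)
  expect_equal(res$dur_per_utt, res2$dur_per_utt)
})
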