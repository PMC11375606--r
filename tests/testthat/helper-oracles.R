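# Independent reference implementations used as oracles. These are written
# against the rule statements directly and share no code with the package
# internals they check.

# --- segmentation: literal split-and-scan over the four rules ------------
seg_oracle <- function(tokens, pause_threshold_ms = 2000, suffix_limit = 2) {
  n <- nrow(tokens)
  if (n == 0) return(integer(0))
  ids <- integer(n)
  cur <- 1L
  start <- 1L
  while (start <= n) {
    end <- n
    nsuf <- 0L
    for (i in start:n) {
      if (tokens$conjunctive_suffix[i]) nsuf <- nsuf + 1L
      hit <-
        tokens$pause_after_ms[i] > pause_threshold_ms ||
        (tokens$sentence_ending_particle[i] &&
           !tokens$contextually_connected_to_next[i]) ||
        (nsuf >= 1L && tokens$intonation_shift_after[i]) ||
        (tokens$conjunctive_suffix[i] && nsuf >= suffix_limit) ||
        (i < n && tokens$conjunction[i + 1L])
      if (hit) {
        end <- i
        break
      }
    }
    ids[start:end] <- cur
    cur <- cur + 1L
    start <- end + 1L
  }
  ids
}

rand_marker_stream <- function(n) {
  make_tokens(
    surface = paste0("w", seq_len(n)),
    sentence_ending_particle = runif(n) < 0.25,
    conjunction = runif(n) < 0.15,
    conjunctive_suffix = runif(n) < 0.2,
    intonation_shift_after = runif(n) < 0.15,
    contextually_connected_to_next = runif(n) < 0.2,
    pause_after_ms = sample(c(0, 100, 500, 1500, 2000, 2500, 3200), n,
                            replace = TRUE))
}

# --- geometry: classic ray-casting point-in-polygon ----------------------
ray_pip <- function(px, py, v) {
  n <- nrow(v)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- v[i, 2]; yj <- v[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- (v[j, 1] - v[i, 1]) * (py - yi) / (yj - yi) + v[i, 1]
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# --- pre-speech: quadratic (utterance x fixation) double loop ------------
pre_oracle <- function(trial, mode = c("onset", "truncate")) {
  mode <- match.arg(mode)
  u <- trial$utterances
  fx <- trial$fixations
  counts <- numeric(0)
  durs <- numeric(0)
  for (i in seq_len(nrow(u))) {
    if (is.na(u$aoi_label[i])) next
    wstart <- if (i == 1) 0 else u$onset_ms[i - 1]
    wend <- u$onset_ms[i]
    cnt <- 0
    dur <- 0
    for (j in seq_len(nrow(fx))) {
      if (is.na(fx$aoi_label[j])) next
      if (fx$aoi_label[j] != u$aoi_label[i]) next
      if (fx$onset_ms[j] < wstart || fx$onset_ms[j] >= wend) next
      cnt <- cnt + 1
      dur <- dur + (if (mode == "onset") fx$offset_ms[j] - fx$onset_ms[j]
                    else min(fx$offset_ms[j], wend) - fx$onset_ms[j])
    }
    counts <- c(counts, cnt)
    durs <- c(durs, dur)
  }
  if (length(counts) == 0) {
    list(n_aoi = 0, count_per_utt = NA_real_, dur_per_utt = NA_real_)
  } else {
    list(n_aoi = length(counts),
         count_per_utt = sum(counts) / length(counts),
         dur_per_utt = sum(durs) / length(counts))
  }
}

# random hand-built trial; fixation AOI labels are set directly so gaze
# tests are independent of the geometry code
rand_trial <- function(n_utt = 6, n_fix = 40,
                       labels = c("dog", "family", "yacht"),
                       aoi_prob = 0.7, shift_ms = 0) {
  # all random draws happen in relative time; shift_ms is added at the end
  # so that two calls with the same seed differ by a pure time translation
  onsets <- sort(sample(seq(1000, 40000, by = 7), n_utt))
  durs <- sample(500:2500, n_utt, replace = TRUE)
  offsets <- pmin(onsets + durs, c(onsets[-1], onsets[n_utt] + durs[n_utt]))
  aoi <- ifelse(runif(n_utt) < aoi_prob,
                sample(labels, n_utt, replace = TRUE), NA_character_)
  task_end <- max(offsets) + 2000
  fon <- sort(sample(seq_len(task_end - 400), n_fix)) - 1
  fdur <- sample(80:600, n_fix, replace = TRUE)
  onsets <- onsets + shift_ms
  offsets <- offsets + shift_ms
  fon <- fon + shift_ms
  task_end <- task_end + shift_ms
  tokens <- make_tokens(paste0("t", seq_len(n_utt)),
                        sentence_ending_particle = TRUE,
                        onset_ms = onsets, offset_ms = offsets)
  tokens$utterance <- seq_len(n_utt)
  fixations <- tibble::tibble(
    onset_ms = fon, offset_ms = pmin(fon + fdur, task_end),
    x_px = runif(n_fix, 0, 1680), y_px = runif(n_fix, 0, 1050),
    aoi_label = ifelse(runif(n_fix) < 0.8,
                       sample(labels, n_fix, replace = TRUE), NA_character_))
  trial_record("P01", "younger", "beach", task_end,
               utterances = tibble::tibble(index = seq_len(n_utt),
                                           onset_ms = onsets,
                                           offset_ms = offsets,
                                           aoi_label = aoi),
               tokens = tokens, fixations = fixations)
}

# --- split-plot ANOVA: closed-form balanced cell-means decomposition -----
# df: columns subject, group, w, y; balanced (equal subjects per group,
# both w levels per subject)
split_plot_oracle <- function(df) {
  grand <- mean(df$y)
  groups <- sort(unique(df$group))
  ws <- sort(unique(df$w))
  subjects <- unique(df$subject)
  n_per_g <- length(subjects) / length(groups)
  b <- length(ws)
  m_s <- tapply(df$y, df$subject, mean)
  g_of_s <- tapply(df$group, df$subject, function(g) g[1])
  m_g <- tapply(df$y, df$group, mean)
  m_w <- tapply(df$y, df$w, mean)
  m_gw <- tapply(df$y, list(df$group, df$w), mean)
  ss_group <- n_per_g * b * sum((m_g - grand)^2)
  ss_subj <- b * sum((m_s - m_g[g_of_s[names(m_s)]])^2)
  ss_w <- length(subjects) * sum((m_w - grand)^2)
  ss_gw <- n_per_g * sum((outer(m_g - grand, m_w - grand, `+`) + grand -
                            m_gw)^2)
  ss_total <- sum((df$y - grand)^2)
  ss_err <- ss_total - ss_group - ss_subj - ss_w - ss_gw
  df_subj <- length(subjects) - length(groups)
  list(SS_group = ss_group, SS_subj = ss_subj, SS_w = ss_w, SS_gw = ss_gw,
       SS_err = ss_err, df_subj = df_subj, df_err = df_subj,
       F_group = (ss_group / (length(groups) - 1)) / (ss_subj / df_subj),
       F_w = (ss_w / (b - 1)) / (ss_err / df_subj),
       F_gw = (ss_gw / (b - 1)) / (ss_err / df_subj))
}

rand_metrics_2x2 <- function(n1 = 24, n2 = 22, group_shift = 0) {
  subjects <- c(sprintf("A%02d", 1:n1), sprintf("B%02d", 1:n2))
  groups <- rep(c("younger", "older"), c(n1, n2))
  intercept <- rnorm(n1 + n2)
  rows <- lapply(seq_along(subjects), function(s) {
    tibble::tibble(participant_id = subjects[s], group = groups[s],
                   picture_id = c("han_river", "beach"),
                   y = intercept[s] + rnorm(2) +
                     ifelse(groups[s] == "older", group_shift, 0))
  })
  dplyr::bind_rows(rows)
}
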