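#' Synthetic cohort configuration
#'
#' Parameters of the synthetic two-group, two-picture cohort generator. The
#' generator emulates the statistical structure the analysis assumes —
#' utterance streams with coder-style token annotation, AOI-targeted
#' utterances, and fixation streams coupled to speech through the eye-voice
#' span (the roughly one-second lag between fixating an element and naming
#' it) — so the full pipeline can be exercised end to end.
#'
#' Group and picture effects are switchable. Defaults follow the direction
#' pattern reported for ageing cohorts (older adults: lower CIU probability,
#' lower noun/verb emission rates, longer eye-voice span; extra pre-speech
#' fixations for older adults on the Han River picture only), with
#' magnitudes chosen to yield standardized group differences of roughly one
#' between-subject SD. Magnitudes are free parameters, not estimates of any
#' real dataset.
#'
#' @param n_younger,n_older Participants per group (default 24 and 22,
#'   each >= 2).
#' @param pictures Picture identifiers (fixed two-level factor).
#' @param n_utt_mean Named per-picture mean utterance counts.
#' @param n_utt_sd SD of the utterance count.
#' @param utt_dur_meanlog,utt_dur_sdlog Lognormal utterance duration (ms).
#' @param gap_mean_ms Mean exponential inter-utterance pause (ms).
#' @param first_onset_mean_ms,first_onset_sd_ms Normal first-utterance
#'   onset (ms after picture onset).
#' @param token_pause_max_ms Maximum within-utterance inter-token pause (ms,
#'   uniform from 40; always below the 2,000 ms segmentation threshold).
#' @param noun_rate,verb_rate,other_rate Poisson token-count means per
#'   utterance and class.
#' @param intelligible_prob Intelligibility probability of content tokens.
#' @param filler_prob Probability that an `other` token is a non-word
#'   filler (fillers are never intelligible).
#' @param ciu_prob CIU probability per intelligible word (younger baseline).
#' @param aoi_utterance_prob Probability that an utterance describes an AOI.
#' @param eye_voice_span_ms,eye_voice_span_sd Eye-voice span (ms): the
#'   primary pre-speech fixation starts about this long before the
#'   utterance onset.
#' @param span_end_gap_ms,span_end_gap_sd Gap between the end of the primary
#'   pre-speech fixation and the utterance onset (ms).
#' @param extra_fix_rate Poisson mean of additional pre-speech fixations
#'   per AOI-related utterance.
#' @param extra_fix_dur_mean,extra_fix_dur_sd Additional pre-speech fixation
#'   duration (ms).
#' @param background_fix_rate Background fixations per second.
#' @param background_fix_dur_mean,background_fix_dur_sd Background fixation
#'   duration (ms).
#' @param fixation_pos_jitter_px SD of gaze position jitter around the AOI
#'   centroid (px).
#' @param subject_ciu_sd,subject_rate_sd,subject_span_sd Between-subject
#'   SDs: CIU logit shift, log token-rate multiplier, span shift (ms).
#' @param group_effects,picture_effects,count_interaction Effect switches.
#' @param effect_ciu_prob_older,effect_noun_rate_older,effect_verb_rate_older,effect_span_older_ms
#'   Older-group shifts (applied when `group_effects` is on).
#' @param effect_ciu_prob_han,effect_noun_rate_han,effect_verb_rate_han,effect_extra_fix_han
#'   Han-River shifts (applied when `picture_effects` is on).
#' @param effect_extra_fix_older_han Extra pre-speech fixation rate for
#'   older participants on the Han River picture only (the count
#'   interaction; applied when `count_interaction` is on).
#' @param rng_seed Integer seed making generation deterministic.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_younger = 24, n_older = 22,
                          pictures = PRESPEECH_PICTURES,
                          n_utt_mean = c(han_river = 16, beach = 12),
                          n_utt_sd = 2,
                          utt_dur_meanlog = log(3000), utt_dur_sdlog = 0.35,
                          gap_mean_ms = 800,
                          first_onset_mean_ms = 2000, first_onset_sd_ms = 300,
                          token_pause_max_ms = 300,
                          noun_rate = 2.2, verb_rate = 1.4, other_rate = 1.5,
                          intelligible_prob = 0.95, filler_prob = 0.5,
                          ciu_prob = 0.76,
                          aoi_utterance_prob = 0.85,
                          eye_voice_span_ms = 1000, eye_voice_span_sd = 150,
                          span_end_gap_ms = 150, span_end_gap_sd = 40,
                          extra_fix_rate = 0.5,
                          extra_fix_dur_mean = 250, extra_fix_dur_sd = 60,
                          background_fix_rate = 0.8,
                          background_fix_dur_mean = 220,
                          background_fix_dur_sd = 60,
                          fixation_pos_jitter_px = 25,
                          subject_ciu_sd = 0.3, subject_rate_sd = 0.15,
                          subject_span_sd = 100,
                          group_effects = TRUE, picture_effects = TRUE,
                          count_interaction = TRUE,
                          effect_ciu_prob_older = -0.12,
                          effect_noun_rate_older = -0.5,
                          effect_verb_rate_older = -0.4,
                          effect_span_older_ms = 300,
                          effect_ciu_prob_han = 0.04,
                          effect_noun_rate_han = 0.3,
                          effect_verb_rate_han = 0.4,
                          effect_extra_fix_han = 0.25,
                          effect_extra_fix_older_han = 0.7,
                          rng_seed = NULL) {
  cfg <- as.list(environment())
  if (cfg$n_younger < 2 || cfg$n_older < 2) {
    abort_config("at least two participants per group are required")
  }
  sds <- c(cfg$n_utt_sd, cfg$utt_dur_sdlog, cfg$first_onset_sd_ms,
           cfg$eye_voice_span_sd, cfg$span_end_gap_sd, cfg$extra_fix_dur_sd,
           cfg$background_fix_dur_sd, cfg$fixation_pos_jitter_px,
           cfg$subject_ciu_sd, cfg$subject_rate_sd, cfg$subject_span_sd)
  if (any(sds < 0)) abort_config("all SDs must be non-negative")
  probs <- c(cfg$intelligible_prob, cfg$filler_prob, cfg$ciu_prob,
             cfg$aoi_utterance_prob)
  if (any(probs < 0 | probs > 1)) {
    abort_config("probabilities must lie in [0, 1]")
  }
  structure(cfg, class = "cohort_config")
}

# Per-cell parameter resolution: applies the switched group/picture effects.
resolve_trial_params <- function(config, group, picture) {
  older <- group == "older"
  han <- picture == "han_river"
  ge <- config$group_effects
  pe <- config$picture_effects
  ci <- config$count_interaction
  clamp01 <- function(p) min(0.99, max(0.01, p))
  list(
    ciu_prob = clamp01(config$ciu_prob +
                         (if (ge && older) config$effect_ciu_prob_older else 0) +
                         (if (pe && han) config$effect_ciu_prob_han else 0)),
    noun_rate = max(0.05, config$noun_rate +
                      (if (ge && older) config$effect_noun_rate_older else 0) +
                      (if (pe && han) config$effect_noun_rate_han else 0)),
    verb_rate = max(0.05, config$verb_rate +
                      (if (ge && older) config$effect_verb_rate_older else 0) +
                      (if (pe && han) config$effect_verb_rate_han else 0)),
    other_rate = config$other_rate,
    span_ms = config$eye_voice_span_ms +
      (if (ge && older) config$effect_span_older_ms else 0),
    extra_fix_rate = max(0, config$extra_fix_rate +
                           (if (pe && han) config$effect_extra_fix_han else 0) +
                           (if (ci && older && han)
                             config$effect_extra_fix_older_han else 0)),
    n_utt_mean = config$n_utt_mean[[picture]])
}

sample_gap <- function(mean_ms) {
  if (mean_ms <= 0) return(0L)
  as.integer(round(rexp(1, 1 / mean_ms)))
}

# scalar crossing-number test; generator-internal fast path (the analysis
# path uses point_in_region, which also handles boundaries and buffers)
point_in_poly_fast <- function(px, py, v, nxt) {
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- v[nxt, 1]; y2 <- v[nxt, 2]
  crossing <- ((y1 > py) != (y2 > py)) &
    (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
  sum(crossing) %% 2 == 1
}

sample_point_in_region <- function(region, jitter_px) {
  ctr <- polygon_centroid(region$vertices)
  if (jitter_px <= 0) return(round(ctr, 1))
  v <- region$vertices
  nxt <- c(2:nrow(v), 1)
  for (k in 1:10) {
    pt <- ctr + rnorm(2, 0, jitter_px)
    if (point_in_poly_fast(pt[1], pt[2], v, nxt)) return(round(pt, 1))
  }
  round(ctr, 1)
}

generate_trial <- function(participant_id, group, picture, config, subj,
                           aoi_cfg, counter) {
  p <- resolve_trial_params(config, group, picture)
  ciu_p <- plogis(qlogis(p$ciu_prob) + subj$ciu_logit)
  rate_mult <- exp(subj$rate_log)
  noun_rate <- p$noun_rate * rate_mult
  verb_rate <- p$verb_rate * rate_mult
  span_mean <- max(200, p$span_ms + subj$span)
  labels <- aoi_labels(aoi_cfg)
  region_by_label <- stats::setNames(aoi_cfg$regions, labels)

  n_utt <- max(1L, as.integer(round(rnorm(1, p$n_utt_mean, config$n_utt_sd))))
  durs <- pmax(600L, as.integer(round(rlnorm(n_utt, config$utt_dur_meanlog,
                                             config$utt_dur_sdlog))))
  gaps <- vapply(seq_len(n_utt), function(i) sample_gap(config$gap_mean_ms),
                 integer(1))
  onset1 <- max(200L, as.integer(round(rnorm(1, config$first_onset_mean_ms,
                                             config$first_onset_sd_ms))))
  onsets <- onset1 + c(0L, cumsum(durs[-n_utt] + pmax(gaps[-n_utt], 1L)))
  offsets <- onsets + durs
  aoi_related <- runif(n_utt) < config$aoi_utterance_prob
  utt_labels <- ifelse(aoi_related, sample(labels, n_utt, replace = TRUE),
                       NA_character_)

  tok_acc <- list(utterance = vector("list", n_utt),
                  lemma = vector("list", n_utt),
                  pos = vector("list", n_utt),
                  intelligible = vector("list", n_utt),
                  ciu = vector("list", n_utt),
                  se = vector("list", n_utt),
                  pause = vector("list", n_utt),
                  on = vector("list", n_utt),
                  off = vector("list", n_utt))
  for (i in seq_len(n_utt)) {
    n_n <- rpois(1, noun_rate); n_v <- rpois(1, verb_rate)
    n_o <- rpois(1, p$other_rate)
    if (n_n + n_v + n_o == 0) n_o <- 1L
    base <- if (!is.na(utt_labels[i])) utt_labels[i] else "gen"
    pos <- c(sample(NOUN_POS, n_n, replace = TRUE, prob = c(0.7, 0.1, 0.2)),
             sample(VERB_POS, n_v, replace = TRUE, prob = c(0.75, 0.25)),
             rep("other", n_o))
    lemma <- c(paste0(base, "_n", sample.int(6, n_n, replace = TRUE)),
               paste0(base, "_v", sample.int(5, n_v, replace = TRUE)),
               rep(NA_character_, n_o))
    intelligible <- c(runif(n_n + n_v) < config$intelligible_prob,
                      rep(NA, n_o))
    for (j in seq_len(n_o)) {
      k <- n_n + n_v + j
      if (runif(1) < config$filler_prob) {
        lemma[k] <- sample(c("um", "eo", "geu"), 1)
        intelligible[k] <- FALSE
      } else {
        lemma[k] <- paste0("gen_o", sample.int(6, 1))
        intelligible[k] <- runif(1) < config$intelligible_prob
      }
    }
    ord <- sample.int(length(pos))
    pos <- pos[ord]; lemma <- lemma[ord]; intelligible <- intelligible[ord]
    ciu <- intelligible & (runif(length(pos)) < ciu_p)
    n_tok <- length(pos)
    bounds <- onsets[i] + as.integer(round((0:n_tok) * durs[i] / n_tok))
    pauses <- pmin(as.integer(round(runif(n_tok, 40, config$token_pause_max_ms))),
                   as.integer(floor(durs[i] / n_tok * 0.4)))
    t_on <- bounds[seq_len(n_tok)]
    t_off <- bounds[-1] - pauses
    t_off[n_tok] <- offsets[i]
    pause_after <- c(t_on[-1], NA_integer_) - t_off
    pause_after[n_tok] <- if (i < n_utt) onsets[i + 1] - offsets[i] else 0L
    tok_acc$utterance[[i]] <- rep.int(i, n_tok)
    tok_acc$lemma[[i]] <- lemma
    tok_acc$pos[[i]] <- pos
    tok_acc$intelligible[[i]] <- intelligible
    tok_acc$ciu[[i]] <- ciu
    tok_acc$se[[i]] <- seq_len(n_tok) == n_tok
    tok_acc$pause[[i]] <- as.integer(pause_after)
    tok_acc$on[[i]] <- t_on
    tok_acc$off[[i]] <- t_off
  }
  lemma_all <- unlist(tok_acc$lemma)
  n_tok_all <- length(lemma_all)
  tokens <- tibble(
    utterance = unlist(tok_acc$utterance),
    surface = lemma_all, lemma = lemma_all,
    pos = unlist(tok_acc$pos),
    intelligible = unlist(tok_acc$intelligible),
    ciu = unlist(tok_acc$ciu),
    sentence_ending_particle = unlist(tok_acc$se),
    conjunction = rep.int(FALSE, n_tok_all),
    conjunctive_suffix = rep.int(FALSE, n_tok_all),
    intonation_shift_after = rep.int(FALSE, n_tok_all),
    contextually_connected_to_next = rep.int(FALSE, n_tok_all),
    pause_after_ms = unlist(tok_acc$pause),
    onset_ms = unlist(tok_acc$on), offset_ms = unlist(tok_acc$off))

  # fixation stream: eye-voice-span-coupled pre-speech fixations on the
  # target AOI, then background fixations over the whole task
  f_on <- integer(0); f_off <- integer(0); f_x <- numeric(0); f_y <- numeric(0)
  for (i in seq_len(n_utt)) {
    if (is.na(utt_labels[i])) next
    wstart <- if (i == 1L) 0L else onsets[i - 1L]
    span <- rnorm(1, span_mean, config$eye_voice_span_sd)
    tries <- 0
    while (onsets[i] - span < wstart && tries < 3) {
      span <- rnorm(1, span_mean, config$eye_voice_span_sd)
      tries <- tries + 1
    }
    if (onsets[i] - span < wstart) {
      span <- onsets[i] - wstart  # window narrower than the span
      counter$clamped <- counter$clamped + 1L
    }
    span <- max(span, 100)
    fstart <- as.integer(round(onsets[i] - span))
    fend <- as.integer(round(onsets[i] -
                               max(20, rnorm(1, config$span_end_gap_ms,
                                             config$span_end_gap_sd))))
    fend <- max(fend, fstart + 50L)
    pt <- sample_point_in_region(region_by_label[[utt_labels[i]]],
                                 config$fixation_pos_jitter_px)
    f_on <- c(f_on, fstart); f_off <- c(f_off, fend)
    f_x <- c(f_x, pt[1]); f_y <- c(f_y, pt[2])
    cursor <- fstart
    for (k in seq_len(rpois(1, p$extra_fix_rate))) {
      fdur <- max(80, round(rnorm(1, config$extra_fix_dur_mean,
                                  config$extra_fix_dur_sd)))
      fe <- cursor - as.integer(round(runif(1, 40, 150)))
      fs <- as.integer(fe - fdur)
      if (fs < wstart) break
      pt2 <- sample_point_in_region(region_by_label[[utt_labels[i]]],
                                    config$fixation_pos_jitter_px)
      f_on <- c(f_on, fs); f_off <- c(f_off, fe)
      f_x <- c(f_x, pt2[1]); f_y <- c(f_y, pt2[2])
      cursor <- fs
    }
  }
  task_end <- offsets[n_utt] + 500L + sample_gap(config$gap_mean_ms)
  n_bg <- rpois(1, config$background_fix_rate * task_end / 1000)
  if (n_bg > 0) {
    bg_on <- as.integer(round(runif(n_bg, 0, max(0, task_end - 400))))
    bg_dur <- pmax(80, round(rnorm(n_bg, config$background_fix_dur_mean,
                                   config$background_fix_dur_sd)))
    bg_off <- pmin(as.integer(bg_on + bg_dur), task_end)
    keep <- bg_off > bg_on
    f_on <- c(f_on, bg_on[keep]); f_off <- c(f_off, bg_off[keep])
    f_x <- c(f_x, round(runif(sum(keep), 0, aoi_cfg$screen[["width_px"]]), 1))
    f_y <- c(f_y, round(runif(sum(keep), 0, aoi_cfg$screen[["height_px"]]), 1))
  }
  ord <- order(f_on)
  fixations <- tibble(onset_ms = f_on[ord], offset_ms = f_off[ord],
                      x_px = f_x[ord], y_px = f_y[ord])

  utterances <- tibble(index = seq_len(n_utt), onset_ms = onsets,
                       offset_ms = offsets, aoi_label = utt_labels)
  trial_record(participant_id, group, picture, task_end,
               utterances, tokens, fixations, validate = TRUE)
}

#' Generate a synthetic cohort
#'
#' Produces one [trial_record()] per participant x picture (two trials per
#' participant). Generated trials always satisfy the container invariants;
#' the rule engine reproduces the generated utterance boundaries (the
#' generator marks each utterance-final token with a sentence-ending
#' particle and keeps within-utterance pauses below threshold); each
#' AOI-related utterance is preceded by at least one fixation inside its
#' target AOI starting roughly one eye-voice span before the utterance
#' onset. Generation is deterministic given `rng_seed`.
#'
#' @param config A [cohort_config()].
#' @return Object of class `prespeech_cohort`: list with `trials` (list of
#'   trial records), `config`, `truth` (tibble of configured effect
#'   directions) and `clamp_warnings` (number of pre-speech fixations whose
#'   eye-voice span had to be clamped to a narrow window).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  gen <- function() {
    aoi_cfgs <- default_aoi_configs()
    ids <- c(sprintf("Y%02d", seq_len(config$n_younger)),
             sprintf("O%02d", seq_len(config$n_older)))
    groups <- rep(c("younger", "older"),
                  c(config$n_younger, config$n_older))
    counter <- new.env()
    counter$clamped <- 0L
    trials <- list()
    for (s in seq_along(ids)) {
      subj <- list(ciu_logit = rnorm(1, 0, config$subject_ciu_sd),
                   rate_log = rnorm(1, 0, config$subject_rate_sd),
                   span = rnorm(1, 0, config$subject_span_sd))
      for (pic in config$pictures) {
        trials[[length(trials) + 1]] <-
          generate_trial(ids[s], groups[s], pic, config, subj,
                         aoi_cfgs[[pic]], counter)
      }
    }
    if (counter$clamped > 0) {
      rlang::warn(sprintf(
        "%d pre-speech fixation(s) clamped to windows narrower than the eye-voice span",
        counter$clamped))
    }
    structure(list(trials = trials, config = config,
                   truth = cohort_truth(config),
                   clamp_warnings = counter$clamped),
              class = "prespeech_cohort")
  }
  if (!is.null(config$rng_seed)) {
    withr::with_seed(config$rng_seed, gen())
  } else {
    gen()
  }
}

cohort_truth <- function(config) {
  ge <- config$group_effects
  ci <- config$count_interaction
  pe <- config$picture_effects
  tibble(
    measure = c("cius_per_min", "nv_tokens_per_utt", "nv_types_per_utt",
                "prespeech_dur_per_utt", "prespeech_count_per_utt",
                "prespeech_count_per_utt"),
    effect = c("group", "group", "group", "group", "group:picture_id",
               "picture_id"),
    # sign convention: group rows are younger minus older; the interaction
    # row is (older Han - older Beach) - (younger Han - younger Beach);
    # the picture row is Han minus Beach
    configured_sign = c(if (ge) 1 else 0, if (ge) 1 else 0,
                        if (ge) 1 else 0, if (ge) -1 else 0,
                        if (ci) 1 else 0, if (pe) 1 else 0))
}

#' @export
print.prespeech_cohort <- function(x, ...) {
  cat(sprintf("<prespeech_cohort> %d trials (%d younger + %d older x %d pictures)\n",
              length(x$trials), x$config$n_younger, x$config$n_older,
              length(x$config$pictures)))
  invisible(x)
}

# subject-wise group difference (younger minus older) of subject means
group_difference <- function(metrics, col) {
  sm <- aggregate(metrics[[col]],
                  list(participant_id = metrics$participant_id,
                       group = metrics$group), mean)
  mean(sm$x[sm$group == "younger"]) - mean(sm$x[sm$group == "older"])
}

picture_difference <- function(metrics, col) {
  mean(metrics[[col]][metrics$picture_id == "han_river"]) -
    mean(metrics[[col]][metrics$picture_id == "beach"])
}

interaction_difference <- function(metrics, col) {
  pd <- function(g) picture_difference(metrics[metrics$group == g, ], col)
  pd("older") - pd("younger")
}

drop_incomplete_subjects <- function(metrics, cols) {
  bad <- unique(metrics$participant_id[
    rowSums(is.na(metrics[, cols, drop = FALSE])) > 0])
  if (length(bad) > 0) {
    rlang::warn(sprintf(
      "dropping %d subject(s) with undefined pre-speech aggregates", length(bad)))
    metrics <- metrics[!metrics$participant_id %in% bad, ]
  }
  metrics
}

nv_long <- function(metrics, kind = c("token", "type")) {
  kind <- match.arg(kind)
  ncol_ <- paste0("nouns_", kind, "_per_utt")
  vcol <- paste0("verbs_", kind, "_per_utt")
  bind_rows(
    tibble(participant_id = metrics$participant_id, group = metrics$group,
           picture_id = metrics$picture_id, pos = "noun",
           dv = metrics[[ncol_]]),
    tibble(participant_id = metrics$participant_id, group = metrics$group,
           picture_id = metrics$picture_id, pos = "verb",
           dv = metrics[[vcol]]))
}

anova_p <- function(anova, effect) {
  anova$p[match(effect, anova$effect)]
}

#' Pipeline parameter-recovery experiment
#'
#' Repeatedly generates a cohort, runs the full metric pipeline and the
#' study's ANOVAs, and summarises how often each configured effect is
#' detected (rejection rate at `alpha`) and whether the sign of the
#' recovered effect matches the configured direction. With all effect
#' switches off this estimates the pipeline-level type-I error; with
#' effects on it estimates power.
#'
#' @param config A [cohort_config()]; `rng_seed` (default 1) seeds
#'   replicate `r` with `rng_seed + r`.
#' @param n_reps Number of replicates (>= 1).
#' @param alpha Nominal significance level (default 0.05).
#' @return Tibble with one row per tracked effect: `measure`, `effect`,
#'   `configured_sign`, `rejection_rate`, `mean_estimate`, `sign_match`.
#' @export
recovery_experiment <- function(config = cohort_config(), n_reps = 30,
                                alpha = 0.05) {
  if (n_reps < 1) abort_domain("n_reps must be >= 1")
  base_seed <- config$rng_seed %||% 1L
  truth <- cohort_truth(config)
  pmat <- matrix(NA_real_, n_reps, nrow(truth))
  emat <- matrix(NA_real_, n_reps, nrow(truth))
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$rng_seed <- base_seed + r
    m <- suppressWarnings(
      cohort_metrics(generate_cohort(cfg)$trials))
    m2 <- suppressWarnings(drop_incomplete_subjects(
      m, c("prespeech_count_per_utt", "prespeech_dur_per_utt")))
    a_ciu <- mixed_anova(m, "cius_per_min", within = "picture_id")
    a_tok <- mixed_anova(nv_long(m, "token"), "dv",
                         within = c("picture_id", "pos"))
    a_typ <- mixed_anova(nv_long(m, "type"), "dv",
                         within = c("picture_id", "pos"))
    a_dur <- mixed_anova(m2, "prespeech_dur_per_utt", within = "picture_id")
    a_cnt <- mixed_anova(m2, "prespeech_count_per_utt", within = "picture_id")
    pmat[r, ] <- c(anova_p(a_ciu, "group"), anova_p(a_tok, "group"),
                   anova_p(a_typ, "group"), anova_p(a_dur, "group"),
                   anova_p(a_cnt, "group:picture_id"),
                   anova_p(a_cnt, "picture_id"))
    emat[r, ] <- c(group_difference(m, "cius_per_min"),
                   group_difference(m, "nouns_token_per_utt") +
                     group_difference(m, "verbs_token_per_utt"),
                   group_difference(m, "nouns_type_per_utt") +
                     group_difference(m, "verbs_type_per_utt"),
                   group_difference(m2, "prespeech_dur_per_utt"),
                   interaction_difference(m2, "prespeech_count_per_utt"),
                   picture_difference(m2, "prespeech_count_per_utt"))
  }
  est <- colMeans(emat)
  tibble(measure = truth$measure, effect = truth$effect,
         configured_sign = truth$configured_sign,
         rejection_rate = colMeans(pmat < alpha),
         mean_estimate = est,
         sign_match = ifelse(truth$configured_sign == 0, NA,
                             sign(est) == truth$configured_sign))
}
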