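#' Write a synthetic input tree
#'
#' Materialises a generated cohort as the package's external formats: one
#' YAML transcript per trial under `transcripts/`, a combined tab-separated
#' fixation report `fixations.tsv` (trials keyed as
#' `participant__picture`), the AOI configurations under `aoi/`, and a
#' `manifest.json` recording the generator configuration and the configured
#' effect directions.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of the written paths plus the cohort.
#' @export
simulate_inputs <- function(config = cohort_config(), dir) {
  cohort <- generate_cohort(config)
  tdir <- file.path(dir, "transcripts")
  adir <- file.path(dir, "aoi")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(adir, recursive = TRUE, showWarnings = FALSE)
  fix_rows <- list()
  for (tr in cohort$trials) {
    label <- make_trial_label(tr$participant_id, tr$picture_id)
    write_transcript(tr, file.path(tdir, paste0(label, ".yaml")))
    fx <- tr$fixations
    if (nrow(fx) > 0) {
      fix_rows[[length(fix_rows) + 1]] <- tibble(trial_label = label, fx)
    }
  }
  fix_path <- file.path(dir, "fixations.tsv")
  write_fixation_report(bind_rows(fix_rows), fix_path)
  for (pic in config$pictures) {
    write_aoi_config(default_aoi_config(pic),
                     file.path(adir, paste0("aoi_", pic, ".yaml")))
  }
  manifest <- list(
    kind = "synthetic_inputs",
    package_version = as.character(utils::packageVersion("prespeech")),
    config = config[!vapply(config, is.null, logical(1))],
    truth = as.data.frame(cohort$truth),
    clamp_warnings = cohort$clamp_warnings)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = dir, transcripts_dir = tdir,
                 fixation_report = fix_path, aoi_dir = adir,
                 cohort = cohort))
}

#' Pipeline run configuration
#'
#' @param transcripts_dir Directory of YAML transcripts (one per trial).
#' @param fixation_report Path to the combined fixation TSV.
#' @param out_dir Output directory.
#' @param aoi_dir Directory containing `aoi_<picture>.yaml` files, or
#'   `NULL` for the packaged defaults.
#' @param buffer_px Outward AOI buffer in pixels.
#' @param duration_mode Fixation duration crediting
#'   (see [prespeech_metrics()]).
#' @param pause_threshold_ms Segmentation pause threshold for the
#'   re-segmentation check.
#' @param resegment_check Verify transcript utterance boundaries against
#'   the rule engine and write a diff report (default `TRUE`).
#' @param seed Optional integer recorded in the manifest (the analysis
#'   itself is deterministic).
#' @return List of class `run_config`.
#' @export
run_config <- function(transcripts_dir, fixation_report, out_dir,
                       aoi_dir = NULL, buffer_px = 0,
                       duration_mode = c("onset", "truncate"),
                       pause_threshold_ms = 2000,
                       resegment_check = TRUE, seed = NULL) {
  duration_mode <- match.arg(duration_mode)
  structure(list(transcripts_dir = transcripts_dir,
                 fixation_report = fixation_report,
                 out_dir = out_dir, aoi_dir = aoi_dir,
                 buffer_px = buffer_px, duration_mode = duration_mode,
                 pause_threshold_ms = pause_threshold_ms,
                 resegment_check = resegment_check, seed = seed),
            class = "run_config")
}

#' Study-level inferential analyses of a metrics table
#'
#' Runs the analyses of the study design on a metrics table: a 2x2 mixed
#' ANOVA (group x picture) for CIUs per minute and for each pre-speech
#' measure, 2x2x2 mixed ANOVAs (group x picture x part of speech) for the
#' noun/verb token and type counts per utterance, and pooled two-sample
#' t-tests on words per minute within each picture. Subjects with undefined
#' pre-speech aggregates (no AOI-related utterances) are dropped from the
#' gaze ANOVAs with a warning.
#'
#' @param metrics Tibble from [cohort_metrics()].
#' @return List with `anovas` (named list of `anova_table`s), `wpm_tests`
#'   (tibble with one row per picture) and `report` (character lines).
#' @export
run_study_anovas <- function(metrics) {
  anovas <- list(
    cius_per_min = mixed_anova(metrics, "cius_per_min",
                               within = "picture_id"),
    nv_tokens = mixed_anova(nv_long(metrics, "token"), "dv",
                            within = c("picture_id", "pos")),
    nv_types = mixed_anova(nv_long(metrics, "type"), "dv",
                           within = c("picture_id", "pos")))
  gaze_cols <- c("prespeech_count_per_utt", "prespeech_dur_per_utt")
  m2 <- drop_incomplete_subjects(metrics, gaze_cols)
  anovas$prespeech_count <- mixed_anova(m2, "prespeech_count_per_utt",
                                        within = "picture_id")
  anovas$prespeech_dur <- mixed_anova(m2, "prespeech_dur_per_utt",
                                      within = "picture_id")
  wpm_rows <- lapply(unique(metrics$picture_id), function(pic) {
    mm <- metrics[metrics$picture_id == pic, ]
    tt <- two_sample_t(mm$wpm[mm$group == "younger"],
                       mm$wpm[mm$group == "older"], pooled = TRUE)
    tibble(picture_id = pic, tt)
  })
  wpm_tests <- bind_rows(wpm_rows)
  report <- c(
    unlist(lapply(names(anovas), function(nm) {
      format_anova_report(anovas[[nm]], label = nm)
    })),
    sprintf("wpm (%s) - younger vs older: t(%g) = %.3f, p = %.3f",
            wpm_tests$picture_id, wpm_tests$df, wpm_tests$t, wpm_tests$p))
  list(anovas = anovas, wpm_tests = wpm_tests, report = report)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: read the AOI configurations, transcripts and fixation
#' report; attach each trial's fixations (aborting if a trial has no
#' fixation data); optionally verify the transcript utterance boundaries
#' against the segmentation rule engine; compute the per-trial dependent
#' measures; run the study ANOVAs and t-tests; and write `metrics.csv`,
#' `anova_tables.csv`, `report.txt`, `segmentation_report.csv` and
#' `manifest.json` into the output directory. Identical configuration and
#' inputs produce identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `metrics`, `stats`, `segmentation` and
#'   `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$transcripts_dir, config$fixation_report)) {
    if (!file.exists(p)) {
      abort_validation(sprintf("input path does not exist: %s", p))
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  aoi_cfgs <- if (is.null(config$aoi_dir)) {
    default_aoi_configs()
  } else {
    cfgs <- lapply(PRESPEECH_PICTURES, function(pic) {
      read_aoi_config(file.path(config$aoi_dir,
                                paste0("aoi_", pic, ".yaml")))
    })
    stats::setNames(cfgs, PRESPEECH_PICTURES)
  }

  paths <- sort(list.files(config$transcripts_dir, pattern = "\\.ya?ml$",
                           full.names = TRUE))
  if (length(paths) == 0) {
    abort_validation(sprintf("no transcripts found in %s",
                             config$transcripts_dir))
  }
  trials <- lapply(paths, read_transcript)
  fixations <- read_fixation_report(config$fixation_report)
  fix_split <- split(fixations[, setdiff(names(fixations), "trial_label")],
                     fixations$trial_label)

  trials <- lapply(trials, function(tr) {
    label <- make_trial_label(tr$participant_id, tr$picture_id)
    fx <- fix_split[[label]]
    if (is.null(fx) || nrow(fx) == 0) {
      abort_validation(sprintf("fixation data missing for trial '%s'", label))
    }
    tr$fixations <- as_tibble(fx)
    validate_trial(tr, aoi_cfgs[[tr$picture_id]])
  })

  seg_tbl <- NULL
  if (config$resegment_check) {
    seg_cfg <- segmentation_config(pause_threshold_ms = config$pause_threshold_ms)
    seg_rows <- lapply(trials, function(tr) {
      res <- resegment_trial(tr, seg_cfg)
      tibble(trial_label = make_trial_label(tr$participant_id, tr$picture_id),
             identical = res$identical, n_stored = res$n_stored,
             n_recomputed = res$n_recomputed,
             n_diff = nrow(res$diff))
    })
    seg_tbl <- bind_rows(seg_rows)
    write.csv(as.data.frame(seg_tbl),
              file.path(config$out_dir, "segmentation_report.csv"),
              row.names = FALSE)
  }

  metrics <- cohort_metrics(trials, aoi_configs = aoi_cfgs,
                            buffer_px = config$buffer_px,
                            duration_mode = config$duration_mode)
  write_metrics(metrics, file.path(config$out_dir, "metrics.csv"))

  stats_out <- run_study_anovas(metrics)
  anova_tbl <- bind_rows(lapply(names(stats_out$anovas), function(nm) {
    tibble(measure = nm, as_tibble(stats_out$anovas[[nm]]))
  }))
  write.csv(as.data.frame(anova_tbl),
            file.path(config$out_dir, "anova_tables.csv"), row.names = FALSE)
  writeLines(stats_out$report, file.path(config$out_dir, "report.txt"))

  manifest <- list(
    kind = "pipeline_run",
    package_version = as.character(utils::packageVersion("prespeech")),
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    config_hash = rlang::hash(unclass(config)),
    n_trials = length(trials),
    seed = config$seed)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(metrics = metrics, stats = stats_out,
                 segmentation = seg_tbl,
                 paths = list(out_dir = config$out_dir)))
}
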