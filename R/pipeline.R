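#' Run the full analysis pipeline
#'
#' Executes, in order: per-sample cleaning (validity flagging, gaze and
#' pupil smoothing, blink rejection), trial segmentation, participant-level
#' vertical gaze correction, per-trial drift correction, trial and
#' participant quality control, sample repair, pupil baseline correction,
#' fixation detection, AOI dwell-time extraction, and the
#' information-theoretic mixed-model analysis. All intermediate tables can
#' be written to `outdir`; rerunning with the same inputs is bit-identical.
#'
#' @param study A study list as returned by [simulate_study()] or
#'   [read_study()] (design, participants, aois, streams, events, ratings).
#' @param covariate Covariate(s) to model: subset of
#'   `c("anxiety", "age")`.
#' @param geometry A [geometry_config()].
#' @param cleaning A [cleaning_config()].
#' @param fixation A [fixation_params()].
#' @param outdir Optional output directory; when given, QC reports,
#'   fixation lists, trial metrics, model tables, results and a run
#'   manifest are written there.
#' @param min_valid_per_condition Participant retention threshold.
#' @return List with `qc_trials`, `qc_participants`, `fixations`,
#'   `metrics`, `records` (per covariate), `results` (per covariate) and
#'   `manifest`.
#' @export
run_pipeline <- function(study,
                         covariate = "anxiety",
                         geometry = geometry_config(),
                         cleaning = cleaning_config(),
                         fixation = fixation_params(),
                         outdir = NULL,
                         min_valid_per_condition = 30) {
  stopifnot(all(covariate %in% c("anxiety", "age")))
  t_start <- Sys.time()
  cross <- geometry$screen_px / 2

  qc_rows <- list()
  fix_rows <- list()
  metric_rows <- list()
  part_rows <- list()

  for (pid in names(study$streams)) {
    stream <- study$streams[[pid]]
    validity <- flag_validity(stream, geometry, cleaning)
    stream <- smooth_gaze(stream, cleaning)
    stream <- smooth_pupil(stream, cleaning)
    blinks <- detect_blinks(stream, cleaning)
    mask <- apply_blink_mask(validity, blinks)

    ev <- study$events[study$events$participant_id == pid, c("trial_id", "event", "t_ms")]
    seg <- segment_trials(stream, ev)
    if (nrow(seg$windows) == 0) next

    trials <- lapply(seq_len(nrow(seg$windows)), function(i) {
      w <- seg$windows[i, ]
      slice <- seg$slices[[as.character(w$trial_id)]]
      sel <- stream$t_ms >= min(slice$t_ms) & stream$t_ms <= max(slice$t_ms)
      list(
        window = w, stream = slice, mask = mask[sel],
        cross_position_px = cross,
        fixation_window = c(w$fixation_onset_ms, w$scene_onset_ms)
      )
    })

    ycorr <- participant_y_correction(trials, geometry, cleaning)
    trials <- ycorr$trials

    for (tr in trials) {
      w <- tr$window
      dc <- drift_correct_trial(
        tr$stream, tr$cross_position_px, tr$fixation_window,
        geometry, cleaning,
        mask = tr$mask
      )
      slice <- dc$stream
      qc <- qc_trial(w, slice, tr$mask)
      if (!is.na(dc$reason) && dc$reason == "no_valid_cross_samples") {
        qc$valid <- FALSE
        qc$reasons <- paste(
          c(if (nzchar(qc$reasons)) qc$reasons, "drift_uncorrectable"),
          collapse = ","
        )
      }
      qc$participant_id <- pid
      qc$drift_applied <- dc$applied
      qc$drift_offset_x_px <- dc$offset_px[1]
      qc$drift_offset_y_px <- dc$offset_px[2]
      qc_rows[[length(qc_rows) + 1]] <- qc
      if (!qc$valid) next

      slice <- repair_invalid(slice, tr$mask)
      slice <- baseline_correct_pupil(slice, w$scene_onset_ms, cleaning)
      fx <- detect_fixations(slice, fixation, geometry, eye = cleaning$analysis_eye)
      scene_id <- study$design$scene_id[study$design$trial_id == w$trial_id][1]
      met <- aoi_fixation_time(
        fx, study$aois, scene_id,
        scene_window = c(w$scene_onset_ms, w$scene_offset_ms),
        geometry = geometry
      )
      if (nrow(fx) > 0) {
        fx$trial_id <- w$trial_id
        fx$participant_id <- pid
        fix_rows[[length(fix_rows) + 1]] <- fx
      }
      metric_rows[[length(metric_rows) + 1]] <- tibble::tibble(
        participant_id = pid,
        trial_id = w$trial_id,
        scene_id = scene_id,
        total_aoi_fixation_ms = met$total_aoi_fixation_ms,
        n_fixations = met$n_fixations
      )
    }
  }

  qc_trials <- dplyr::bind_rows(qc_rows)
  metrics <- dplyr::bind_rows(metric_rows)
  fixations <- dplyr::bind_rows(fix_rows)

  # participant retention
  for (pid in unique(qc_trials$participant_id)) {
    dec <- qc_trials[qc_trials$participant_id == pid, ]
    des <- study$design[study$design$participant_id == pid, ]
    pq <- qc_participant(dec, des, min_valid_per_condition)
    part_rows[[length(part_rows) + 1]] <- tibble::tibble(
      participant_id = pid,
      keep = pq$keep,
      n_valid_self = pq$counts$n_valid[pq$counts$perspective == "self"],
      n_valid_other = pq$counts$n_valid[pq$counts$perspective == "other"]
    )
  }
  qc_participants <- dplyr::bind_rows(part_rows)
  kept <- qc_participants$participant_id[qc_participants$keep]

  metrics <- metrics[metrics$participant_id %in% kept, ]
  metrics <- dplyr::inner_join(
    metrics,
    study$design[, c("participant_id", "trial_id", "perspective", "statement_valence")],
    by = c("participant_id", "trial_id")
  )

  records <- list()
  results <- list()
  for (cv in covariate) {
    rec <- build_model_table(metrics, study$ratings, study$participants, which = cv)
    records[[cv]] <- rec
    results[[cv]] <- run_analysis(rec, which = cv)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("peergaze")),
    config_hash = rlang::hash(list(
      geometry = unclass(geometry), cleaning = unclass(cleaning),
      fixation = unclass(fixation),
      min_valid_per_condition = min_valid_per_condition
    )),
    n_participants_in = length(study$streams),
    n_trials_in = nrow(qc_trials),
    n_trials_valid = sum(qc_trials$valid),
    n_participants_kept = length(kept),
    n_trials_modelled = nrow(metrics),
    wall_time_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )

  out <- list(
    qc_trials = qc_trials,
    qc_participants = qc_participants,
    fixations = fixations,
    metrics = metrics,
    records = records,
    results = results,
    manifest = manifest
  )
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_csv_precise(as.data.frame(qc_trials), file.path(outdir, "qc_trials.csv"))
    write_csv_precise(as.data.frame(qc_participants), file.path(outdir, "qc_participants.csv"))
    write_csv_precise(as.data.frame(fixations), file.path(outdir, "fixations.csv"))
    write_csv_precise(as.data.frame(metrics), file.path(outdir, "metrics.csv"))
    for (cv in covariate) {
      write_results(results[[cv]], outdir, covariate = cv)
    }
    jsonlite::write_json(
      manifest[names(manifest) != "wall_time_s"],
      file.path(outdir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  out
}
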