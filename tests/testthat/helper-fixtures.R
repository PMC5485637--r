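# Shared fixture builders. Everything is generated in code; no files.

# a hand-buildable stream: stationary gaze at `pos`, pupils at `pupil`
make_stream <- function(n, pos = c(960, 540), pupil = 3.5, rate_hz = 300,
                        t0 = 0) {
  period <- 1000 / rate_hz
  gaze_stream(tibble::tibble(
    t_ms = t0 + (seq_len(n) - 1) * period,
    lx_px = rep(pos[1], n),
    ly_px = rep(pos[2], n),
    rx_px = rep(pos[1], n),
    ry_px = rep(pos[2], n),
    lpupil_mm = rep(pupil, n),
    rpupil_mm = rep(pupil, n),
    valid_flag = rep(TRUE, n)
  ))
}

# standard cleaning chain up to the analysis mask, as used by the pipeline
clean_stream <- function(stream, geometry = geometry_config(),
                         cleaning = cleaning_config()) {
  validity <- flag_validity(stream, geometry, cleaning)
  stream <- smooth_gaze(stream, cleaning)
  stream <- smooth_pupil(stream, cleaning)
  blinks <- detect_blinks(stream, cleaning)
  mask <- apply_blink_mask(validity, blinks)
  list(stream = stream, mask = mask, blinks = blinks)
}

# minimal modelling table built straight from a design (no gaze stage)
make_records <- function(n_participants, seed, truth = default_truth_model(),
                         which = "anxiety") {
  design <- generate_design(n_participants, seed)
  fixt <- withr::with_seed(seed + 1, stats::rgamma(nrow(design), 4, scale = 300))
  parts <- simulate_participants(n_participants, seed + 2)$participants
  cov_by_pid <- stats::setNames(
    if (which == "anxiety") parts$sasa_total else parts$age,
    parts$participant_id
  )
  ratings <- simulate_ratings(
    design, fixt, cov_by_pid[design$participant_id], truth, seed + 3
  )
  metrics <- tibble::tibble(
    participant_id = design$participant_id,
    trial_id = design$trial_id,
    scene_id = design$scene_id,
    total_aoi_fixation_ms = fixt,
    perspective = design$perspective,
    statement_valence = design$statement_valence
  )
  list(
    records = build_model_table(metrics, ratings, parts, which),
    design = design, metrics = metrics, ratings = ratings,
    participants = parts, fixation_time = fixt
  )
}

# single-trial simulation spec used across detector tests
basic_trial_spec <- function(...) {
  utils::modifyList(
    list(
      scene_id = 1,
      cross_position_px = c(960, 540),
      fix_duration_ms = 1500,
      rating_duration_ms = 1000
    ),
    list(...)
  )
}
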