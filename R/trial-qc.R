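#' Segment a session stream into trials
#'
#' Cuts a continuous per-participant gaze stream into per-trial slices using
#' the event log. A trial needs all five markers (`fixation_onset`,
#' `scene_onset`, `scene_offset`, `statement_offset`, `rating`); trials with
#' missing markers are dropped and reported in the `dropped` element.
#' Each slice spans fixation onset to the rating event.
#'
#' @param stream A [gaze_stream()] for one participant.
#' @param events Tibble with columns `trial_id`, `event`, `t_ms`.
#' @return List with `windows` (one row per trial: the five marker times),
#'   `slices` (named list of stream slices), and `dropped` (tibble of
#'   trial_id and reason).
#' @export
segment_trials <- function(stream, events) {
  markers <- c(
    "fixation_onset", "scene_onset", "scene_offset",
    "statement_offset", "rating"
  )
  events <- events[order(events$t_ms), ]
  ids <- unique(events$trial_id)
  rows <- list()
  slices <- list()
  dropped <- list()
  for (id in ids) {
    ev <- events[events$trial_id == id, ]
    t <- stats::setNames(
      vapply(markers, function(m) {
        hit <- ev$t_ms[ev$event == m]
        if (length(hit) == 1) hit else NA_real_
      }, numeric(1)),
      markers
    )
    if (anyNA(t)) {
      dropped[[length(dropped) + 1]] <- tibble::tibble(
        trial_id = id,
        reason = paste0("missing_", paste(markers[is.na(t)], collapse = "+"))
      )
      next
    }
    if (is.unsorted(t, strictly = TRUE)) {
      dropped[[length(dropped) + 1]] <- tibble::tibble(
        trial_id = id, reason = "markers_out_of_order"
      )
      next
    }
    keep <- stream$t_ms >= t["fixation_onset"] & stream$t_ms <= t["rating"]
    rows[[length(rows) + 1]] <- tibble::tibble(
      trial_id = id,
      fixation_onset_ms = t[["fixation_onset"]],
      scene_onset_ms = t[["scene_onset"]],
      scene_offset_ms = t[["scene_offset"]],
      statement_offset_ms = t[["statement_offset"]],
      rating_ms = t[["rating"]]
    )
    slices[[as.character(id)]] <- stream[keep, ]
  }
  list(
    windows = dplyr::bind_rows(rows),
    slices = slices,
    dropped = dplyr::bind_rows(dropped)
  )
}

#' Longest consecutive invalid run within a window, in ms
#'
#' @param mask Logical validity mask (TRUE = valid).
#' @param t_ms Sample timestamps aligned with `mask`.
#' @param window `c(start_ms, end_ms)`, inclusive.
#' @return Duration in ms of the longest contiguous invalid run inside the
#'   window (run length times the sample period); 0 if none.
#' @export
longest_invalid_run <- function(mask, t_ms, window = range(t_ms)) {
  sel <- t_ms >= window[1] & t_ms <= window[2]
  if (!any(sel)) stop("empty window in longest_invalid_run")
  m <- mask[sel]
  period <- if (sum(sel) >= 2) stats::median(diff(t_ms[sel])) else NA_real_
  runs <- rle(!m)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  if (longest == 0L) 0 else longest * period
}

#' Trial-level quality control
#'
#' A trial is excluded if any of the following holds, computed on the
#' pre-repair validity mask with strict inequalities:
#' (i) more than `max_run_ms` consecutive invalid samples anywhere between
#' fixation onset and the end of the trial (`run_after_fix_onset`);
#' (ii) more than `max_run_ms` consecutive invalid samples between fixation
#' onset and scene offset (`run_before_scene_offset`);
#' (iii) more than `max_invalid_fraction` invalid samples between fixation
#' onset and scene offset (`pct_invalid`).
#'
#' @param window One row of `segment_trials()$windows`.
#' @param slice The matching stream slice.
#' @param mask Pre-repair validity mask aligned with `slice`.
#' @param max_run_ms Longest tolerated invalid run (default 1000 ms).
#' @param max_invalid_fraction Largest tolerated invalid fraction between
#'   fixation onset and scene offset (default 0.4).
#' @return One-row tibble: `trial_id`, `valid`, `reasons` (comma-separated
#'   codes, empty when valid), `invalid_fraction`, `longest_run_trial_ms`,
#'   `longest_run_to_offset_ms`.
#' @export
qc_trial <- function(window, slice, mask,
                     max_run_ms = 1000, max_invalid_fraction = 0.4) {
  stopifnot(length(mask) == nrow(slice))
  full_win <- c(window$fixation_onset_ms, max(slice$t_ms))
  pre_off_win <- c(window$fixation_onset_ms, window$scene_offset_ms)
  run_full <- longest_invalid_run(mask, slice$t_ms, full_win)
  run_pre <- longest_invalid_run(mask, slice$t_ms, pre_off_win)
  sel <- slice$t_ms >= pre_off_win[1] & slice$t_ms <= pre_off_win[2]
  frac <- mean(!mask[sel])
  # strict "more than" comparisons, with a small numerical guard so that a
  # run of exactly max_run_ms is retained despite floating-point timestamps
  eps <- 1e-6
  reasons <- c(
    if (run_full > max_run_ms + eps) "run_after_fix_onset",
    if (run_pre > max_run_ms + eps) "run_before_scene_offset",
    if (frac > max_invalid_fraction + eps) "pct_invalid"
  )
  tibble::tibble(
    trial_id = window$trial_id,
    valid = length(reasons) == 0,
    reasons = paste(reasons, collapse = ","),
    invalid_fraction = frac,
    longest_run_trial_ms = run_full,
    longest_run_to_offset_ms = run_pre
  )
}

#' Participant-level retention rule
#'
#' A participant is retained only with at least `min_valid_per_condition`
#' QC-valid trials in each perspective condition (self, other) - the strict
#' reading of "less than 30 valid trials per condition".
#'
#' @param decisions Tibble of [qc_trial()] rows for one participant.
#' @param design Design rows for the same participant with `trial_id` and
#'   `perspective`.
#' @param min_valid_per_condition Minimum valid trials per condition.
#' @return List with `keep` (logical) and `counts` (tibble of valid trials
#'   per perspective level).
#' @export
qc_participant <- function(decisions, design, min_valid_per_condition = 30) {
  merged <- dplyr::inner_join(
    decisions[, c("trial_id", "valid")],
    design[, c("trial_id", "perspective")],
    by = "trial_id"
  )
  counts <- tibble::tibble(
    perspective = c("self", "other"),
    n_valid = vapply(
      c("self", "other"),
      function(p) sum(merged$valid[merged$perspective == p]),
      integer(1)
    )
  )
  list(keep = all(counts$n_valid >= min_valid_per_condition), counts = counts)
}

#' Standard 9-point calibration target layout
#'
#' Targets at 20%, 50% and 80% of the horizontal and vertical screen span.
#'
#' @param geometry A [geometry_config()].
#' @return Tibble with `point_id`, `x_px`, `y_px` (9 rows).
#' @export
calibration_targets <- function(geometry) {
  fr <- c(0.2, 0.5, 0.8)
  grid <- expand.grid(fx = fr, fy = fr)
  tibble::tibble(
    point_id = seq_len(nrow(grid)),
    x_px = grid$fx * geometry$screen_px[1],
    y_px = grid$fy * geometry$screen_px[2]
  )
}

#' Calibration quality check
#'
#' Calibration passes if at least `min_samples` gaze samples fall within
#' one degree of visual angle of every calibration point.
#'
#' @param samples Tibble with `point_id`, `x_px`, `y_px`: gaze samples
#'   collected while each target was shown.
#' @param targets 9-row tibble from [calibration_targets()] (or equivalent).
#' @param geometry A [geometry_config()].
#' @param min_samples Minimum on-target samples per point (default 12).
#' @param radius_deg On-target radius in degrees (default 1).
#' @return List with `per_point` (tibble of point_id and n_within) and
#'   `pass` (logical).
#' @export
calibration_qc <- function(samples, targets, geometry,
                           min_samples = 12, radius_deg = 1) {
  if (nrow(targets) != 9) stop("calibration requires exactly 9 targets")
  radius_px <- deg_to_px(radius_deg, geometry)
  per_point <- tibble::tibble(
    point_id = targets$point_id,
    n_within = vapply(seq_len(nrow(targets)), function(i) {
      s <- samples[samples$point_id == targets$point_id[i], ]
      if (nrow(s) == 0) return(0L)
      d <- sqrt((s$x_px - targets$x_px[i])^2 + (s$y_px - targets$y_px[i])^2)
      sum(d <= radius_px)
    }, integer(1))
  )
  list(per_point = per_point, pass = all(per_point$n_within >= min_samples))
}
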