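#' Signal-cleaning configuration
#'
#' Parameters of the per-sample cleaning stage. Defaults follow common
#' practice for 300 Hz remote tracking: a second-order Savitzky-Golay gaze
#' filter of 7 samples, a 3-sample running-median pupil filter, a 200 ms
#' pre-stimulus pupil baseline, blink flagging at an instantaneous pupil
#' rate of change above 0.1 mm per sample in both eyes, a physiological
#' pupil range of 1.5-9 mm, and analysis of the left eye.
#'
#' @param sg_order,sg_window_samples Savitzky-Golay polynomial order and
#'   (odd) window length in samples for gaze smoothing.
#' @param pupil_median_window_samples Running-median window for the pupil.
#' @param baseline_window_ms Pupil baseline window before scene onset.
#' @param blink_rate_threshold_mm Per-sample absolute pupil diameter change
#'   above which (in both eyes simultaneously) samples belong to a blink.
#' @param pupil_range_mm Physiological pupil diameter range `c(lo, hi)` mm.
#' @param drift_max_offset_px Largest drift offset (Euclidean, pixels) that
#'   is still corrected; larger estimates leave the trial unchanged.
#' @param y_correction_threshold_px Participant-level median vertical offset
#'   (pixels) above which a global y correction is applied.
#' @param analysis_eye Eye used for velocity, drift and fixation analysis.
#'
#' @return A list of class `cleaning_config`.
#' @export
cleaning_config <- function(sg_order = 2,
                            sg_window_samples = 7,
                            pupil_median_window_samples = 3,
                            baseline_window_ms = 200,
                            blink_rate_threshold_mm = 0.1,
                            pupil_range_mm = c(1.5, 9.0),
                            drift_max_offset_px = 150,
                            y_correction_threshold_px = 30,
                            analysis_eye = "left") {
  stopifnot(
    sg_window_samples %% 2 == 1, sg_window_samples > sg_order,
    pupil_median_window_samples %% 2 == 1,
    baseline_window_ms > 0, blink_rate_threshold_mm > 0,
    length(pupil_range_mm) == 2, pupil_range_mm[1] > 0,
    pupil_range_mm[2] > pupil_range_mm[1],
    drift_max_offset_px > 0
  )
  structure(
    list(
      sg_order = sg_order,
      sg_window_samples = sg_window_samples,
      pupil_median_window_samples = pupil_median_window_samples,
      baseline_window_ms = baseline_window_ms,
      blink_rate_threshold_mm = blink_rate_threshold_mm,
      pupil_range_mm = pupil_range_mm,
      drift_max_offset_px = drift_max_offset_px,
      y_correction_threshold_px = y_correction_threshold_px,
      analysis_eye = match.arg(analysis_eye, c("left", "right"))
    ),
    class = "cleaning_config"
  )
}

#' Per-sample validity mask
#'
#' A sample is valid iff, for both eyes simultaneously: (i) the tracker
#' flagged both eyes as found, (ii) gaze lies within the screen area, and
#' (iii) pupil diameter is positive and within the physiological range.
#' The stream itself is not modified.
#'
#' @param stream A [gaze_stream()].
#' @param geometry A [geometry_config()].
#' @param config A [cleaning_config()].
#' @return Logical vector, one element per sample.
#' @export
flag_validity <- function(stream, geometry, config = cleaning_config()) {
  w <- geometry$screen_px[1]
  h <- geometry$screen_px[2]
  on_screen <- function(x, y) {
    !is.na(x) & !is.na(y) & x >= 0 & x <= w & y >= 0 & y <= h
  }
  pupil_ok <- function(p) {
    !is.na(p) & p > 0 & p >= config$pupil_range_mm[1] & p <= config$pupil_range_mm[2]
  }
  flag <- stream$valid_flag
  flag[is.na(flag)] <- FALSE
  flag &
    on_screen(stream$lx_px, stream$ly_px) &
    on_screen(stream$rx_px, stream$ry_px) &
    pupil_ok(stream$lpupil_mm) &
    pupil_ok(stream$rpupil_mm)
}

sgolay_smooth <- function(x, order, window) {
  n <- length(x)
  if (n < window) stop("need at least ", window, " samples for Savitzky-Golay smoothing")
  nas <- is.na(x)
  if (all(nas)) return(x)
  if (any(nas)) {
    # fill gaps for filtering only; NA positions are restored afterwards
    x_fill <- stats::approx(which(!nas), x[!nas], xout = seq_len(n), rule = 2)$y
    out <- signal::sgolayfilt(x_fill, p = order, n = window)
    out[nas] <- NA_real_
    out
  } else {
    signal::sgolayfilt(x, p = order, n = window)
  }
}

#' Smooth gaze with a Savitzky-Golay filter
#'
#' Applies a polynomial least-squares (Savitzky-Golay) filter independently
#' to each gaze coordinate of each eye. Edge samples are smoothed by the
#' polynomial fit of the terminal window, so polynomials up to the filter
#' order are reproduced exactly everywhere. NA samples are excluded from
#' the fit and remain NA.
#'
#' @inheritParams flag_validity
#' @return The stream with smoothed gaze columns.
#' @export
smooth_gaze <- function(stream, config = cleaning_config()) {
  for (col in gaze_cols) {
    stream[[col]] <- sgolay_smooth(stream[[col]], config$sg_order, config$sg_window_samples)
  }
  stream
}

#' Smooth pupil diameter with a running median
#'
#' A short running median (default 3 samples) per eye removes single-sample
#' tracker spikes without smearing blink ramps. Edge samples pass through
#' unchanged.
#'
#' @inheritParams flag_validity
#' @return The stream with median-filtered pupil columns.
#' @export
smooth_pupil <- function(stream, config = cleaning_config()) {
  k <- config$pupil_median_window_samples
  if (nrow(stream) < k) stop("need at least ", k, " samples for the pupil median filter")
  for (col in pupil_cols) {
    x <- stream[[col]]
    nas <- is.na(x)
    if (all(nas)) next
    x_fill <- stats::approx(which(!nas), x[!nas], xout = seq_along(x), rule = 2)$y
    sm <- as.numeric(stats::runmed(x_fill, k = k, endrule = "keep"))
    sm[nas] <- NA_real_
    stream[[col]] <- sm
  }
  stream
}

#' Detect blink sections from pupil rate of change
#'
#' Blinks produce a rapid collapse and recovery of measured pupil diameter
#' in both eyes. Samples whose absolute first difference of (smoothed)
#' pupil diameter exceeds the threshold in both eyes simultaneously seed a
#' section; a section spans the contiguous run of such samples. NA pupil
#' samples are treated as supra-threshold (tracker loss).
#'
#' @inheritParams flag_validity
#' @return Tibble with columns `start`, `end` (sample indices, inclusive).
#' @export
detect_blinks <- function(stream, config = cleaning_config()) {
  thr <- config$blink_rate_threshold_mm
  rate <- function(p) {
    d <- c(0, abs(diff(p)))
    d[is.na(d)] <- Inf
    d
  }
  supra <- rate(stream$lpupil_mm) > thr & rate(stream$rpupil_mm) > thr
  runs <- rle(supra)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values
  tibble::tibble(start = starts[keep], end = ends[keep])
}

#' Combine validity and blink information into the analysis mask
#'
#' @param validity Logical vector from [flag_validity()].
#' @param blinks Blink sections from [detect_blinks()].
#' @return Logical vector: valid and not within a blink section.
#' @export
apply_blink_mask <- function(validity, blinks) {
  if (nrow(blinks) > 0) {
    for (i in seq_len(nrow(blinks))) {
      validity[blinks$start[i]:blinks$end[i]] <- FALSE
    }
  }
  validity
}

#' Repair invalid samples
#'
#' Invalid gaze samples are replaced with the last valid value
#' (zero-order hold; leading invalid samples take the first valid value).
#' Invalid pupil samples are linearly interpolated between flanking valid
#' samples (leading/trailing take the nearest valid value). The mask itself
#' is not modified, so QC statistics remain based on the pre-repair mask.
#'
#' @param stream A [gaze_stream()].
#' @param mask Logical validity mask (TRUE = valid).
#' @return The repaired stream, with the mask stored in column `valid`.
#' @export
repair_invalid <- function(stream, mask) {
  stopifnot(length(mask) == nrow(stream))
  if (!any(mask)) stop("cannot repair a stream with no valid samples")
  idx <- seq_len(nrow(stream))
  for (col in gaze_cols) {
    x <- stream[[col]]
    x[!mask] <- NA_real_
    x <- zoo::na.locf(x, na.rm = FALSE)
    x <- zoo::na.locf(x, fromLast = TRUE, na.rm = FALSE)
    stream[[col]] <- x
  }
  for (col in pupil_cols) {
    x <- stream[[col]]
    x[!mask] <- NA_real_
    ok <- !is.na(x)
    stream[[col]] <- stats::approx(idx[ok], x[ok], xout = idx, rule = 2)$y
  }
  stream$valid <- mask
  stream
}

#' Baseline-correct pupil diameter
#'
#' Subtracts, per eye, the mean pupil diameter over the window immediately
#' before scene onset (`[onset - baseline_window_ms, onset)`) from the whole
#' trace.
#'
#' @param stream A [gaze_stream()] covering one trial.
#' @param scene_onset_ms Scene onset time on the stream's clock.
#' @inheritParams flag_validity
#' @return The stream with baseline-corrected pupil columns.
#' @export
baseline_correct_pupil <- function(stream, scene_onset_ms, config = cleaning_config()) {
  win <- stream$t_ms >= scene_onset_ms - config$baseline_window_ms &
    stream$t_ms < scene_onset_ms
  if (stream$t_ms[1] > scene_onset_ms - config$baseline_window_ms || !any(win)) {
    stop("insufficient pre-onset data for pupil baseline correction")
  }
  for (col in pupil_cols) {
    stream[[col]] <- stream[[col]] - mean(stream[[col]][win], na.rm = TRUE)
  }
  stream
}

#' Per-trial drift correction against the fixation cross
#'
#' Estimates a constant gaze offset as the difference between the known
#' fixation-cross position and the median valid gaze of the analysis eye
#' during the cross window. The offset is applied to all gaze samples of
#' the trial (both eyes) only if its Euclidean magnitude is below
#' `drift_max_offset_px`; otherwise the trial is left unchanged.
#'
#' @param stream A [gaze_stream()] covering one trial.
#' @param cross_position_px Fixation-cross position `c(x, y)` in pixels.
#' @param fixation_window `c(start_ms, end_ms)` of the cross period.
#' @param geometry A [geometry_config()].
#' @param config A [cleaning_config()].
#' @param mask Optional validity mask; defaults to the `valid` column, or
#'   all-valid if absent.
#' @return List with elements `stream`, `applied` (logical), `offset_px`
#'   (length-2), and `reason` (`NA` or a reason code).
#' @export
drift_correct_trial <- function(stream, cross_position_px, fixation_window,
                                geometry, config = cleaning_config(),
                                mask = NULL) {
  if (is.null(mask)) mask <- stream[["valid"]] %||% rep(TRUE, nrow(stream))
  ec <- eye_cols(config$analysis_eye)
  in_win <- stream$t_ms >= fixation_window[1] & stream$t_ms <= fixation_window[2]
  use <- in_win & mask
  if (!any(use)) {
    return(list(
      stream = stream, applied = FALSE,
      offset_px = c(NA_real_, NA_real_), reason = "no_valid_cross_samples"
    ))
  }
  med <- c(
    stats::median(stream[[ec["x"]]][use]),
    stats::median(stream[[ec["y"]]][use])
  )
  offset <- cross_position_px - med
  if (sqrt(sum(offset^2)) >= config$drift_max_offset_px) {
    return(list(
      stream = stream, applied = FALSE,
      offset_px = offset, reason = "drift_uncorrectable"
    ))
  }
  stream$lx_px <- stream$lx_px + offset[1]
  stream$ly_px <- stream$ly_px + offset[2]
  stream$rx_px <- stream$rx_px + offset[1]
  stream$ry_px <- stream$ry_px + offset[2]
  list(stream = stream, applied = TRUE, offset_px = offset, reason = NA_character_)
}

#' Participant-level vertical gaze correction
#'
#' Some participants show a constant vertical calibration bias across the
#' whole session. The participant-level median vertical offset (cross y
#' minus median valid gaze y during the cross window, across trials) is
#' computed; if its magnitude exceeds the threshold it is added to every
#' vertical gaze sample of every trial before per-trial drift correction.
#'
#' @param trials List of per-trial lists, each with elements `stream`,
#'   `cross_position_px`, `fixation_window`, and optionally `mask`.
#' @param geometry A [geometry_config()].
#' @param config A [cleaning_config()]; `y_correction_threshold_px` is the
#'   trigger threshold.
#' @return List with `trials` (corrected) , `applied` (logical), and
#'   `shift_px` (the applied vertical shift, 0 when not applied).
#' @export
participant_y_correction <- function(trials, geometry, config = cleaning_config()) {
  ec <- eye_cols(config$analysis_eye)
  per_trial <- vapply(trials, function(tr) {
    s <- tr$stream
    mask <- tr$mask %||% s[["valid"]] %||% rep(TRUE, nrow(s))
    use <- s$t_ms >= tr$fixation_window[1] & s$t_ms <= tr$fixation_window[2] & mask
    if (!any(use)) return(NA_real_)
    tr$cross_position_px[2] - stats::median(s[[ec["y"]]][use])
  }, numeric(1))
  shift <- stats::median(per_trial, na.rm = TRUE)
  if (is.na(shift) || abs(shift) <= config$y_correction_threshold_px) {
    return(list(trials = trials, applied = FALSE, shift_px = 0))
  }
  trials <- lapply(trials, function(tr) {
    tr$stream$ly_px <- tr$stream$ly_px + shift
    tr$stream$ry_px <- tr$stream$ry_px + shift
    tr
  })
  list(trials = trials, applied = TRUE, shift_px = shift)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
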