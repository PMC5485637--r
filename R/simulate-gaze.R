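#' Gaze-simulation configuration
#'
#' Parameters of the synthetic binocular gaze generator. Fixational
#' scatter is an AR(1) (drift-like) process with the given marginal
#' standard deviation in degrees and lag-one correlation: at 300 Hz real
#' fixational drift and tracker noise are strongly autocorrelated, and a
#' white process of the same amplitude would exceed saccadic velocity
#' thresholds on most samples. Saccades are linear interpolations between
#' fixation centroids; blinks collapse the measured pupil in both eyes
#' with a supra-threshold rate of change on the ramps, tracker loss (NA)
#' in between, and an invalid tracker flag throughout.
#'
#' @param sampling_rate_hz Tracker sampling rate.
#' @param noise_sd_deg Marginal SD of fixational scatter, degrees.
#' @param noise_ar Lag-one autocorrelation of the scatter process.
#' @param saccade_duration_range_ms Range of simulated saccade durations.
#' @param fixation_duration_range_ms Range of scene-exploration fixation
#'   durations (sampled log-uniformly).
#' @param blink_prob Probability that any given trial contains a blink.
#' @param blink_duration_range_ms Range of blink durations.
#' @param drift_offset_sd_px SD of the constant per-trial gaze offset
#'   (calibration drift) in pixels.
#' @param pupil_baseline_mm Mean resting pupil diameter.
#' @param aoi_gaze_prob Probability that a scene-exploration fixation
#'   targets a face AOI (when AOIs are supplied).
#' @param fixation_jitter_ms,scene_duration_ms,statement_duration_ms,
#'   rating_duration_range_ms,iti_range_ms Trial timing: fixation-cross
#'   jitter 1-2 s, scene alone 5 s, scene+statement 3 s, self-paced rating
#'   bounds, inter-trial interval 5-6 s.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(sampling_rate_hz = 300,
                              noise_sd_deg = 0.3,
                              noise_ar = 0.95,
                              saccade_duration_range_ms = c(20, 60),
                              min_saccade_amplitude_deg = 2.5,
                              fixation_duration_range_ms = c(120, 800),
                              blink_prob = 0.25,
                              blink_duration_range_ms = c(100, 300),
                              drift_offset_sd_px = 10,
                              pupil_baseline_mm = 3.5,
                              aoi_gaze_prob = 0.45,
                              fixation_jitter_ms = c(1000, 2000),
                              scene_duration_ms = 5000,
                              statement_duration_ms = 3000,
                              rating_duration_range_ms = c(800, 2500),
                              iti_range_ms = c(5000, 6000)) {
  stopifnot(
    sampling_rate_hz > 0, noise_sd_deg >= 0,
    noise_ar >= 0, noise_ar < 1,
    all(saccade_duration_range_ms > 0), all(fixation_duration_range_ms > 0),
    blink_prob >= 0, blink_prob <= 1, all(blink_duration_range_ms > 0),
    drift_offset_sd_px >= 0, scene_duration_ms > 0, statement_duration_ms > 0
  )
  structure(as.list(environment()), class = "simulation_config")
}

# AR(1) series with marginal sd `sd` and lag-1 correlation `phi`
ar1_noise <- function(n, sd, phi) {
  if (sd == 0 || n == 0) return(numeric(n))
  x <- numeric(n)
  innov_sd <- sd * sqrt(1 - phi^2)
  x[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    e <- stats::rnorm(n - 1, 0, innov_sd)
    for (i in 2:n) x[i] <- phi * x[i - 1] + e[i - 1]
  }
  x
}

#' Simulate one trial of binocular gaze with known ground truth
#'
#' Builds the trial timeline (fixation cross, 5 s scene alone, 3 s scene
#' with statement, rating period), plans a sequence of ground-truth
#' fixation/saccade events covering it, renders the left-eye gaze trace
#' (fixations at their centroids plus AR(1) scatter, saccades as linear
#' interpolation), derives the right eye with a small constant disparity,
#' adds a constant per-trial drift offset, and injects blinks.
#'
#' @param trial_spec List with `scene_id`, `cross_position_px` (c(x, y)),
#'   `fix_duration_ms`, `rating_duration_ms`, optionally `aoi_rects` (scene
#'   coordinates) and `t0_ms` (session-clock start, default 0).
#' @param config A [simulation_config()].
#' @param geometry A [geometry_config()].
#' @param seed Integer seed.
#' @return List with `stream` (a [gaze_stream()]), `truth` (tibble of
#'   ground-truth events: `kind`, `onset_ms`, `offset_ms`, `x_px`, `y_px`),
#'   `events` (the five trial markers as a tibble), and `drift_offset_px`.
#' @export
simulate_gaze_trial <- function(trial_spec, config = simulation_config(),
                                geometry = geometry_config(), seed = 1) {
  withr::with_seed(seed, {
    period <- 1000 / config$sampling_rate_hz
    t0 <- trial_spec$t0_ms %||% 0
    fix_dur <- trial_spec$fix_duration_ms
    scene_on <- fix_dur
    scene_off <- scene_on + config$scene_duration_ms
    statement_off <- scene_off + config$statement_duration_ms
    rating_t <- statement_off + trial_spec$rating_duration_ms
    n <- floor(rating_t / period) + 1
    t_rel <- (seq_len(n) - 1) * period

    sr <- scene_rect_px(geometry)
    rand_scene_point <- function() {
      margin <- 60
      c(
        stats::runif(1, sr["x"] + margin, sr["x"] + sr["w"] - margin),
        stats::runif(1, sr["y"] + margin, sr["y"] + sr["h"] - margin)
      )
    }
    rand_aoi_point <- function() {
      rects <- trial_spec$aoi_rects
      if (is.null(rects) || nrow(rects) == 0) return(rand_scene_point())
      r <- rects[sample.int(nrow(rects), 1), ]
      sc <- aoi_to_screen(r, geometry)
      c(
        stats::runif(1, sc$x + 0.15 * sc$w, sc$x + 0.85 * sc$w),
        stats::runif(1, sc$y + 0.15 * sc$h, sc$y + 0.85 * sc$h)
      )
    }

    # ground-truth event plan: cross fixation, then alternating
    # saccade/fixation until the rating event
    events <- list()
    add_event <- function(kind, onset, offset, pos = c(NA_real_, NA_real_)) {
      events[[length(events) + 1]] <<- tibble::tibble(
        kind = kind, onset_ms = onset, offset_ms = offset,
        x_px = pos[1], y_px = pos[2]
      )
    }
    lu <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
    if (!is.null(trial_spec$plan)) {
      # explicit ground-truth plan supplied by the caller (oracle tests)
      for (i in seq_len(nrow(trial_spec$plan))) {
        add_event(
          trial_spec$plan$kind[i], trial_spec$plan$onset_ms[i],
          trial_spec$plan$offset_ms[i],
          c(trial_spec$plan$x_px[i], trial_spec$plan$y_px[i])
        )
      }
    }
    add_plan <- is.null(trial_spec$plan)
    if (add_plan) add_event("fixation", 0, fix_dur, trial_spec$cross_position_px)
    cur_t <- fix_dur
    cur_pos <- trial_spec$cross_position_px
    while (add_plan && cur_t < rating_t) {
      # targets at least min_saccade_amplitude away from the current
      # position, and saccade durations capped by a main-sequence-like
      # bound (21 ms + 2.2 ms/deg), keep every simulated saccade separable
      # from fixation under velocity/dispersion thresholds
      min_amp_px <- deg_to_px(config$min_saccade_amplitude_deg, geometry)
      for (try in 1:25) {
        target <- if (stats::runif(1) < config$aoi_gaze_prob && cur_t < scene_off) {
          rand_aoi_point()
        } else {
          rand_scene_point()
        }
        if (sqrt(sum((target - cur_pos)^2)) >= min_amp_px) break
      }
      amp_deg <- px_to_deg(sqrt(sum((target - cur_pos)^2)), geometry)
      hi <- min(config$saccade_duration_range_ms[2], 21 + 2.2 * amp_deg)
      lo <- min(config$saccade_duration_range_ms[1], hi)
      sacc_dur <- stats::runif(1, lo, hi)
      add_event("saccade", cur_t, cur_t + sacc_dur)
      cur_t <- cur_t + sacc_dur
      fdur <- lu(
        config$fixation_duration_range_ms[1], config$fixation_duration_range_ms[2]
      )
      fdur <- min(fdur, rating_t - cur_t)
      if (fdur <= 0) break
      add_event("fixation", cur_t, cur_t + fdur, target)
      cur_t <- cur_t + fdur
      cur_pos <- target
    }
    truth <- dplyr::bind_rows(events)

    # render the noiseless left-eye trace from the event plan
    x <- numeric(n)
    y <- numeric(n)
    prev_pos <- trial_spec$cross_position_px
    for (i in seq_len(nrow(truth))) {
      sel <- t_rel >= truth$onset_ms[i] & t_rel < truth$offset_ms[i]
      if (!any(sel)) next
      if (truth$kind[i] == "fixation") {
        x[sel] <- truth$x_px[i]
        y[sel] <- truth$y_px[i]
        prev_pos <- c(truth$x_px[i], truth$y_px[i])
      } else {
        nxt <- if (i < nrow(truth)) c(truth$x_px[i + 1], truth$y_px[i + 1]) else prev_pos
        frac <- (t_rel[sel] - truth$onset_ms[i]) / (truth$offset_ms[i] - truth$onset_ms[i])
        x[sel] <- prev_pos[1] + frac * (nxt[1] - prev_pos[1])
        y[sel] <- prev_pos[2] + frac * (nxt[2] - prev_pos[2])
      }
    }
    tail_sel <- t_rel >= max(truth$offset_ms)
    if (any(tail_sel)) {
      x[tail_sel] <- prev_pos[1]
      y[tail_sel] <- prev_pos[2]
    }

    # fixational scatter and per-trial calibration drift
    px_per_deg <- 1 / deg_per_px(geometry)
    x <- x + ar1_noise(n, config$noise_sd_deg, config$noise_ar) * px_per_deg
    y <- y + ar1_noise(n, config$noise_sd_deg, config$noise_ar) * px_per_deg
    drift <- stats::rnorm(2, 0, config$drift_offset_sd_px)
    x <- x + drift[1]
    y <- y + drift[2]
    disparity <- stats::rnorm(2, 0, 1.5)
    rx <- x + disparity[1]
    ry <- y + disparity[2]

    # pupil: per-eye baseline with tiny slow variation
    base_l <- config$pupil_baseline_mm + stats::rnorm(1, 0, 0.2)
    base_r <- base_l + stats::rnorm(1, 0, 0.1)
    lp <- base_l + ar1_noise(n, 0.02, 0.99)
    rp <- base_r + ar1_noise(n, 0.02, 0.99)
    flag <- rep(TRUE, n)

    # blinks: supra-threshold collapse ramps, tracker loss in between
    if (stats::runif(1) < config$blink_prob) {
      bdur <- stats::runif(
        1, config$blink_duration_range_ms[1], config$blink_duration_range_ms[2]
      )
      bstart <- stats::runif(1, scene_on, scene_off - bdur)
      i0 <- which(t_rel >= bstart)[1]
      i1 <- max(which(t_rel < bstart + bdur))
      if (!is.na(i0) && i1 - i0 + 1 >= 10) {
        ramp <- 4
        down <- seq(lp[i0], 0.4, length.out = ramp + 1)[-1]
        lp[i0:(i0 + ramp - 1)] <- down
        rp[i0:(i0 + ramp - 1)] <- down + (base_r - base_l)
        up <- seq(0.4, lp[min(i1 + 1, n)], length.out = ramp + 1)[-(ramp + 1)]
        lp[(i1 - ramp + 1):i1] <- up
        rp[(i1 - ramp + 1):i1] <- up + (base_r - base_l)
        mid <- (i0 + ramp):(i1 - ramp)
        lp[mid] <- NA_real_
        rp[mid] <- NA_real_
        x[i0:i1] <- NA_real_
        y[i0:i1] <- NA_real_
        rx[i0:i1] <- NA_real_
        ry[i0:i1] <- NA_real_
        flag[i0:i1] <- FALSE
        add_event("blink", t_rel[i0], t_rel[i1] + period)
        truth <- dplyr::bind_rows(events)
      }
    }

    stream <- gaze_stream(tibble::tibble(
      t_ms = t0 + t_rel,
      lx_px = x, ly_px = y, rx_px = rx, ry_px = ry,
      lpupil_mm = lp, rpupil_mm = rp,
      valid_flag = flag
    ))
    markers <- tibble::tibble(
      event = c(
        "fixation_onset", "scene_onset", "scene_offset",
        "statement_offset", "rating"
      ),
      t_ms = t0 + c(0, scene_on, scene_off, statement_off, rating_t)
    )
    truth$onset_ms <- truth$onset_ms + t0
    truth$offset_ms <- truth$offset_ms + t0
    list(
      stream = stream, truth = truth, events = markers,
      drift_offset_px = drift
    )
  })
}

#' Generate face AOI rectangles for each scene
#'
#' One to three face rectangles per scene, in scene pixel coordinates,
#' placed in the upper half of the scene where heads plausibly appear.
#'
#' @param seed Integer seed.
#' @param n_scenes Number of scenes.
#' @param geometry A [geometry_config()].
#' @return Named list: scene id (character) -> tibble of `x, y, w, h`.
#' @export
generate_scene_aois <- function(seed, n_scenes = 72, geometry = geometry_config()) {
  withr::with_seed(seed, {
    sw <- geometry$scene_px[1]
    sh <- geometry$scene_px[2]
    out <- lapply(seq_len(n_scenes), function(s) {
      k <- sample(1:3, 1)
      tibble::tibble(
        x = stats::runif(k, 0.05 * sw, 0.95 * sw - 110),
        y = stats::runif(k, 0.05 * sh, 0.45 * sh),
        w = rep(110, k),
        h = rep(130, k)
      )
    })
    names(out) <- as.character(seq_len(n_scenes))
    out
  })
}

#' Simulate a full study
#'
#' Generates the counterbalanced design, participant questionnaire data,
#' scene AOIs, a continuous per-participant gaze stream with trial event
#' markers and ground-truth gaze events, and interpretation ratings drawn
#' from a known mixed-effects truth model in which the fixation-time
#' predictor is each trial's ground-truth AOI dwell time.
#'
#' @param n_participants Number of participants.
#' @param seed Integer master seed; all stages derive from it.
#' @param config A [simulation_config()].
#' @param geometry A [geometry_config()].
#' @param truth A [truth_model()]; the covariate coefficient applies to
#'   the participant's social anxiety score (`covariate = "anxiety"`) or
#'   age (`covariate = "age"`).
#' @param covariate Which participant measure drives the ratings.
#' @return List with elements `design`, `participants` (plus item-level
#'   `sasa_items`, `pds_items`), `aois`, `streams` (named list, one stream
#'   per participant), `events` (tibble with `participant_id`, `trial_id`,
#'   `event`, `t_ms`), `truth_events`, `true_aoi_time`, `ratings`,
#'   `config`, `geometry`, `truth`.
#' @export
simulate_study <- function(n_participants, seed,
                           config = simulation_config(),
                           geometry = geometry_config(),
                           truth = default_truth_model(),
                           covariate = c("anxiety", "age")) {
  covariate <- match.arg(covariate)
  design <- generate_design(n_participants, seed)
  pdata <- simulate_participants(n_participants, seed + 1)
  aois <- generate_scene_aois(seed + 2, geometry = geometry)
  cross <- geometry$screen_px / 2

  streams <- list()
  all_events <- list()
  all_truth <- list()
  true_aoi <- numeric(nrow(design))
  pids <- unique(design$participant_id)
  for (pi in seq_along(pids)) {
    pid <- pids[pi]
    rows <- which(design$participant_id == pid)
    t0 <- 0
    parts <- list()
    timing_seed <- (seed + 7919L * pi) %% 2147483647L
    timings <- withr::with_seed(timing_seed, tibble::tibble(
      fix = stats::runif(length(rows), config$fixation_jitter_ms[1], config$fixation_jitter_ms[2]),
      rate = stats::runif(
        length(rows), config$rating_duration_range_ms[1], config$rating_duration_range_ms[2]
      ),
      iti = stats::runif(length(rows), config$iti_range_ms[1], config$iti_range_ms[2])
    ))
    for (k in seq_along(rows)) {
      row <- rows[k]
      spec <- list(
        scene_id = design$scene_id[row],
        cross_position_px = cross,
        fix_duration_ms = timings$fix[k],
        rating_duration_ms = timings$rate[k],
        aoi_rects = aois[[as.character(design$scene_id[row])]],
        t0_ms = t0
      )
      trial_seed <- (seed + 7919L * pi + 131L * k) %% 2147483647L
      sim <- simulate_gaze_trial(spec, config, geometry, seed = trial_seed)
      parts[[k]] <- sim
      scene_win <- sim$events$t_ms[sim$events$event %in% c("scene_onset", "scene_offset")]
      fx <- sim$truth[sim$truth$kind == "fixation", ]
      if (nrow(fx) > 0) {
        ov <- pmax(
          0,
          pmin(fx$offset_ms, scene_win[2]) - pmax(fx$onset_ms, scene_win[1])
        )
        rects <- aoi_to_screen(as.data.frame(spec$aoi_rects), geometry)
        hit <- point_in_rects(fx$x_px, fx$y_px, rects)
        true_aoi[row] <- sum(ov[hit])
      }
      t0 <- max(sim$stream$t_ms) + timings$iti[k]
    }
    streams[[pid]] <- gaze_stream(dplyr::bind_rows(lapply(parts, `[[`, "stream")))
    ev <- dplyr::bind_rows(lapply(seq_along(parts), function(k) {
      out <- parts[[k]]$events
      out$trial_id <- design$trial_id[rows[k]]
      out
    }))
    ev$participant_id <- pid
    all_events[[pid]] <- ev
    tr <- dplyr::bind_rows(lapply(seq_along(parts), function(k) {
      out <- parts[[k]]$truth
      out$trial_id <- design$trial_id[rows[k]]
      out
    }))
    tr$participant_id <- pid
    all_truth[[pid]] <- tr
  }

  cov_vals <- if (covariate == "anxiety") {
    pdata$participants$sasa_total
  } else {
    pdata$participants$age
  }
  names(cov_vals) <- pdata$participants$participant_id
  ratings <- simulate_ratings(
    design, true_aoi, cov_vals[design$participant_id], truth, seed + 3
  )

  list(
    design = design,
    participants = pdata$participants,
    sasa_items = pdata$sasa_items,
    pds_items = pdata$pds_items,
    aois = aois,
    streams = streams,
    events = dplyr::bind_rows(all_events),
    truth_events = dplyr::bind_rows(all_truth),
    true_aoi_time = true_aoi,
    ratings = ratings,
    config = config,
    geometry = geometry,
    truth = truth,
    covariate = covariate,
    seed = seed
  )
}
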