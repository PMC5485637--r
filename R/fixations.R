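#' Fixation detection parameters
#'
#' Velocity-dispersion-duration hybrid thresholds: a sample can belong to a
#' fixation only while gaze velocity stays below `velocity_threshold_dps`;
#' candidate runs are split so that no member sample lies farther than
#' `dispersion_threshold_deg` from the fixation centroid; groups shorter
#' than `min_duration_ms` are discarded.
#'
#' @param velocity_threshold_dps Maximum gaze velocity, degrees/second.
#' @param dispersion_threshold_deg Maximum radial distance of member
#'   samples from the fixation centroid, degrees.
#' @param min_duration_ms Minimum fixation duration, ms.
#' @return A list of class `fixation_params`.
#' @export
fixation_params <- function(velocity_threshold_dps = 75,
                            dispersion_threshold_deg = 2,
                            min_duration_ms = 75) {
  stopifnot(
    velocity_threshold_dps > 0, dispersion_threshold_deg > 0,
    min_duration_ms > 0
  )
  structure(
    list(
      velocity_threshold_dps = velocity_threshold_dps,
      dispersion_threshold_deg = dispersion_threshold_deg,
      min_duration_ms = min_duration_ms
    ),
    class = "fixation_params"
  )
}

#' Per-sample gaze velocity in degrees per second
#'
#' Central-difference displacement over two samples, converted to degrees
#' and divided by twice the sample period; one-sided differences at the
#' endpoints.
#'
#' @param x_px,y_px Gaze coordinates (pixels) of the analysis eye.
#' @param t_ms Sample timestamps (ms).
#' @param geometry A [geometry_config()].
#' @return Numeric vector of velocities, one per sample.
#' @export
compute_velocity <- function(x_px, y_px, t_ms, geometry) {
  n <- length(x_px)
  if (n < 3) stop("need at least 3 samples to compute velocity")
  dpp <- deg_per_px(geometry)
  v <- numeric(n)
  i <- 2:(n - 1)
  disp <- sqrt((x_px[i + 1] - x_px[i - 1])^2 + (y_px[i + 1] - y_px[i - 1])^2)
  v[i] <- disp * dpp / ((t_ms[i + 1] - t_ms[i - 1]) / 1000)
  v[1] <- sqrt((x_px[2] - x_px[1])^2 + (y_px[2] - y_px[1])^2) * dpp /
    ((t_ms[2] - t_ms[1]) / 1000)
  v[n] <- sqrt((x_px[n] - x_px[n - 1])^2 + (y_px[n] - y_px[n - 1])^2) * dpp /
    ((t_ms[n] - t_ms[n - 1]) / 1000)
  v
}

# Greedy dispersion grouping of one below-velocity candidate run.
# Returns a list of index ranges (start, end) relative to the run.
split_by_dispersion <- function(x_deg, y_deg, threshold_deg) {
  n <- length(x_deg)
  groups <- list()
  start <- 1
  sx <- x_deg[1]
  sy <- y_deg[1]
  m <- 1
  for (i in seq_len(n)[-1]) {
    # centroid updated as if the incoming sample were accepted
    cx <- (sx + x_deg[i]) / (m + 1)
    cy <- (sy + y_deg[i]) / (m + 1)
    if (sqrt((x_deg[i] - cx)^2 + (y_deg[i] - cy)^2) > threshold_deg) {
      groups[[length(groups) + 1]] <- c(start, i - 1)
      start <- i
      sx <- x_deg[i]
      sy <- y_deg[i]
      m <- 1
    } else {
      sx <- sx + x_deg[i]
      sy <- sy + y_deg[i]
      m <- m + 1
    }
  }
  groups[[length(groups) + 1]] <- c(start, n)
  groups
}

# Enforce the dispersion invariant exactly: if any member lies farther than
# the threshold from the final centroid (possible in rare drift cases under
# greedy grouping), split the group at its farthest sample and recurse.
enforce_dispersion <- function(x_deg, y_deg, range, threshold_deg) {
  idx <- range[1]:range[2]
  d <- sqrt((x_deg[idx] - mean(x_deg[idx]))^2 + (y_deg[idx] - mean(y_deg[idx]))^2)
  if (all(d <= threshold_deg)) return(list(range))
  cut <- idx[which.max(d)]
  out <- list()
  if (cut > range[1]) {
    out <- c(out, enforce_dispersion(x_deg, y_deg, c(range[1], cut - 1), threshold_deg))
  }
  if (cut < range[2]) {
    out <- c(out, enforce_dispersion(x_deg, y_deg, c(cut + 1, range[2]), threshold_deg))
  }
  out
}

#' Detect fixations in a gaze slice
#'
#' Velocity-dispersion-duration classification: (1) samples with velocity
#' below the threshold are fixation candidates; (2) each contiguous
#' candidate run is scanned left to right with a running centroid, closing
#' the current group whenever the incoming sample would lie farther than
#' the dispersion threshold from the updated centroid; (3) groups shorter
#' than the minimum duration are discarded. Every returned fixation is
#' re-checked against its own invariants (duration, and all member samples
#' within the dispersion threshold of the final centroid).
#'
#' A fixation's duration is its dwell time, `n_samples` times the sample
#' period, so a run of k samples covers k sample intervals.
#'
#' @param slice A [gaze_stream()] slice (smoothed, repaired).
#' @param params A [fixation_params()].
#' @param geometry A [geometry_config()].
#' @param eye Analysis eye, `"left"` (default) or `"right"`.
#' @return Tibble with one row per fixation: `onset_ms`, `offset_ms`,
#'   `duration_ms`, `x_px`, `y_px`, `n_samples`, `dispersion_deg`.
#' @export
detect_fixations <- function(slice, params = fixation_params(),
                             geometry = geometry_config(), eye = "left") {
  ec <- eye_cols(eye)
  x <- slice[[ec["x"]]]
  y <- slice[[ec["y"]]]
  t <- slice$t_ms
  n <- length(x)
  empty <- tibble::tibble(
    onset_ms = numeric(), offset_ms = numeric(), duration_ms = numeric(),
    x_px = numeric(), y_px = numeric(), n_samples = integer(),
    dispersion_deg = numeric()
  )
  if (n < 3) return(empty)
  period <- sample_period_ms(slice)
  v <- compute_velocity(x, y, t, geometry)
  cand <- v < params$velocity_threshold_dps & !is.na(x) & !is.na(y)

  dpp <- deg_per_px(geometry)
  x_deg <- x * dpp
  y_deg <- y * dpp

  runs <- rle(cand)
  run_ends <- cumsum(runs$lengths)
  run_starts <- run_ends - runs$lengths + 1

  rows <- list()
  for (r in which(runs$values)) {
    a <- run_starts[r]
    b <- run_ends[r]
    groups <- split_by_dispersion(
      x_deg[a:b], y_deg[a:b], params$dispersion_threshold_deg
    )
    for (g in groups) {
      checked <- enforce_dispersion(
        x_deg[a:b], y_deg[a:b], g, params$dispersion_threshold_deg
      )
      for (cg in checked) {
        i0 <- a + cg[1] - 1
        i1 <- a + cg[2] - 1
        dur <- (i1 - i0 + 1) * period
        if (dur < params$min_duration_ms) next
        idx <- i0:i1
        cx <- mean(x[idx])
        cy <- mean(y[idx])
        disp <- max(sqrt((x_deg[idx] - mean(x_deg[idx]))^2 +
                           (y_deg[idx] - mean(y_deg[idx]))^2))
        rows[[length(rows) + 1]] <- tibble::tibble(
          onset_ms = t[i0], offset_ms = t[i1], duration_ms = dur,
          x_px = cx, y_px = cy, n_samples = length(idx),
          dispersion_deg = disp
        )
      }
    }
  }
  if (length(rows) == 0) return(empty)
  dplyr::arrange(dplyr::bind_rows(rows), .data$onset_ms)
}

# convert AOI rectangles from scene to screen coordinates
aoi_to_screen <- function(rects, geometry) {
  sr <- scene_rect_px(geometry)
  rects$x <- rects$x + sr["x"]
  rects$y <- rects$y + sr["y"]
  rects
}

point_in_rects <- function(x, y, rects) {
  hit <- rep(FALSE, length(x))
  for (i in seq_len(nrow(rects))) {
    hit <- hit | (x >= rects$x[i] & x <= rects$x[i] + rects$w[i] &
                    y >= rects$y[i] & y <= rects$y[i] + rects$h[i])
  }
  hit
}

#' Total AOI fixation time for one trial
#'
#' Sums the durations of fixations whose centroid falls inside any face
#' AOI rectangle of the scene, restricted to the free-viewing scene window.
#' Fixations straddling a window boundary contribute only their in-window
#' portion. AOI rectangles are defined in scene pixel coordinates and
#' mapped to the screen through the geometry.
#'
#' @param fixations Output of [detect_fixations()].
#' @param aoi_set Named list: `scene_id` -> data frame of `x, y, w, h`
#'   rectangles (scene pixels).
#' @param scene_id Scene identifier (coerced to character for lookup).
#' @param scene_window `c(onset_ms, offset_ms)` of the scene-alone period.
#' @param geometry A [geometry_config()].
#' @return One-row tibble: `total_aoi_fixation_ms`, `n_fixations` (count of
#'   in-window fixations on AOIs).
#' @export
aoi_fixation_time <- function(fixations, aoi_set, scene_id, scene_window,
                              geometry = geometry_config()) {
  key <- as.character(scene_id)
  if (!key %in% names(aoi_set)) stop("unknown scene_id: ", key)
  rects <- aoi_to_screen(as.data.frame(aoi_set[[key]]), geometry)
  if (nrow(fixations) == 0) {
    return(tibble::tibble(total_aoi_fixation_ms = 0, n_fixations = 0L))
  }
  # in-window overlap of each fixation
  ov_start <- pmax(fixations$onset_ms, scene_window[1])
  ov_end <- pmin(fixations$onset_ms + fixations$duration_ms, scene_window[2])
  overlap <- pmax(0, ov_end - ov_start)
  on_aoi <- point_in_rects(fixations$x_px, fixations$y_px, rects)
  keep <- overlap > 0 & on_aoi
  tibble::tibble(
    total_aoi_fixation_ms = sum(overlap[keep]),
    n_fixations = sum(keep)
  )
}

#' Per-participant, per-condition mean AOI fixation times
#'
#' @param metrics Tibble with `participant_id`, `trial_id`,
#'   `total_aoi_fixation_ms`.
#' @param design Design tibble with `participant_id`, `trial_id`,
#'   `perspective`, `statement_valence`.
#' @return Tibble of participant x perspective x valence cell means.
#' @export
condition_summary <- function(metrics, design) {
  merged <- dplyr::inner_join(
    metrics, design,
    by = c("participant_id", "trial_id")
  )
  dplyr::summarise(
    dplyr::group_by(
      merged, .data$participant_id, .data$perspective, .data$statement_valence
    ),
    mean_aoi_fixation_ms = mean(.data$total_aoi_fixation_ms),
    n_trials = dplyr::n(),
    .groups = "drop"
  )
}
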