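g <- geometry_config()
fp <- fixation_params()
period <- 1000 / 300

test_that("velocity is zero for stationary gaze and matches the closed form for drift", {
  s <- make_stream(100)
  v <- compute_velocity(s$lx_px, s$ly_px, s$t_ms, g)
  expect_true(all(v == 0))
  # 1 px/sample at 300 Hz: deg/px * 300 deg/s
  s2 <- make_stream(100)
  s2$lx_px <- 960 + seq_len(100)
  v2 <- compute_velocity(s2$lx_px, s2$ly_px, s2$t_ms, g)
  expect_equal(unique(round(v2, 6)), round(deg_per_px(g) * 300, 6))
  expect_equal(v2[50], 8.148, tolerance = 1e-3)
  # translation invariance
  s3 <- s2
  s3$lx_px <- s3$lx_px + 123
  s3$ly_px <- s3$ly_px - 77
  expect_equal(
    compute_velocity(s3$lx_px, s3$ly_px, s3$t_ms, g), v2,
    tolerance = 1e-12
  )
  expect_error(compute_velocity(1:2, 1:2, c(0, period), g), "3 samples")
})

test_that("a stationary episode must last 75 ms to count as a fixation", {
  mk_episode <- function(dur_ms) {
    # saccade-fixation-saccade: fast moves flanking a stationary episode
    n_fix <- round(dur_ms / period)
    n_move <- 30
    x <- c(
      seq(200, 800, length.out = n_move), # ~73 px/sample: far above threshold
      rep(800, n_fix),
      seq(800, 1400, length.out = n_move)
    )
    n <- length(x)
    s <- make_stream(n)
    s$lx_px <- x
    s$ly_px <- rep(400, n)
    s
  }
  fx300 <- detect_fixations(mk_episode(300), fp, g)
  expect_equal(nrow(fx300), 1)
  expect_equal(fx300$duration_ms, 300, tolerance = 0.025) # +- ~7 ms
  expect_equal(fx300$x_px, 800, tolerance = 0.5)
  fx60 <- detect_fixations(mk_episode(60), fp, g)
  expect_equal(nrow(fx60), 0)
})

test_that("slow drift between two stationary episodes is split by dispersion", {
  # two 200 ms episodes 5 deg apart, joined by drift below the velocity threshold
  sep_px <- deg_to_px(5, g)
  n_fix <- round(200 / period)
  n_drift <- 40 # 5 deg over 40 samples: ~37.5 deg/s, below 75
  x <- c(
    rep(500, n_fix),
    seq(500, 500 + sep_px, length.out = n_drift),
    rep(500 + sep_px, n_fix)
  )
  s <- make_stream(length(x))
  s$lx_px <- x
  s$ly_px <- rep(400, length(x))
  fx <- detect_fixations(s, fp, g)
  expect_equal(nrow(fx), 2)
  expect_equal(fx$x_px[1], 500, tolerance = deg_to_px(0.75, g))
  expect_equal(fx$x_px[2], 500 + sep_px, tolerance = deg_to_px(0.75, g))
  expect_true(all(fx$dispersion_deg <= 2))
})

test_that("every emitted fixation satisfies its own invariants on noisy input", {
  cl <- cleaning_config()
  for (s in 1:10) {
    sim <- simulate_gaze_trial(basic_trial_spec(), seed = 400 + s)
    cs <- clean_stream(sim$stream)
    st <- repair_invalid(cs$stream, cs$mask)
    fx <- detect_fixations(st, fp, g)
    expect_true(all(fx$duration_ms >= 75))
    expect_true(all(fx$dispersion_deg <= 2 + 1e-9))
    expect_true(all(diff(fx$onset_ms) > 0))
    expect_true(all(fx$onset_ms + fx$duration_ms - period <= max(st$t_ms) + 1e-9))
  }
})

test_that("AOI dwell time sums in-window fixation durations with centroid membership", {
  aois <- list("1" = tibble::tibble(x = 100, y = 100, w = 110, h = 130))
  sr <- scene_rect_px(g)
  inside <- c(sr[["x"]] + 155, sr[["y"]] + 165) # centre of the AOI on screen
  fx <- tibble::tibble(
    onset_ms = 2000, offset_ms = 2996.7, duration_ms = 1000,
    x_px = inside[1], y_px = inside[2], n_samples = 300, dispersion_deg = 0.2
  )
  m <- aoi_fixation_time(fx, aois, 1, c(1500, 6500), g)
  expect_equal(m$total_aoi_fixation_ms, 1000)
  # fixation outside all AOIs contributes nothing
  fx_out <- fx
  fx_out$x_px <- sr[["x"]] + 600
  expect_equal(aoi_fixation_time(fx_out, aois, 1, c(1500, 6500), g)$total_aoi_fixation_ms, 0)
  # straddling the window boundary: only the in-window part counts
  fx_straddle <- fx
  fx_straddle$onset_ms <- 1000 # 500 ms before scene onset
  m2 <- aoi_fixation_time(fx_straddle, aois, 1, c(1500, 6500), g)
  expect_equal(m2$total_aoi_fixation_ms, 500)
  expect_error(aoi_fixation_time(fx, aois, 99, c(1500, 6500), g), "unknown scene_id")
})

test_that("AOI membership agrees with a brute-force point-in-rectangle oracle", {
  for (i in 1:100) {
    layout <- withr::with_seed(i, tibble::tibble(
      x = runif(3, 0, 1000), y = runif(3, 0, 600),
      w = runif(3, 50, 200), h = runif(3, 50, 200)
    ))
    pts <- withr::with_seed(i + 500, tibble::tibble(
      x = runif(40, -100, 1400), y = runif(40, -100, 900)
    ))
    sr <- scene_rect_px(g)
    screen_rects <- layout
    screen_rects$x <- screen_rects$x + sr[["x"]]
    screen_rects$y <- screen_rects$y + sr[["y"]]
    px <- pts$x + sr[["x"]]
    py <- pts$y + sr[["y"]]
    oracle <- vapply(seq_len(40), function(j) {
      any(px[j] >= screen_rects$x & px[j] <= screen_rects$x + screen_rects$w &
            py[j] >= screen_rects$y & py[j] <= screen_rects$y + screen_rects$h)
    }, logical(1))
    fx <- tibble::tibble(
      onset_ms = 2000, offset_ms = 2100, duration_ms = 100,
      x_px = px, y_px = py, n_samples = 30, dispersion_deg = 0.1
    )
    m <- aoi_fixation_time(fx, list("7" = layout), 7, c(1500, 6500), g)
    expect_equal(m$total_aoi_fixation_ms, 100 * sum(oracle))
    expect_equal(m$n_fixations, sum(oracle))
  }
})

test_that("AOI dwell never exceeds the 5 s scene window on random trials", {
  aois <- generate_scene_aois(3, n_scenes = 5)
  for (i in 1:200) {
    fx <- withr::with_seed(i, {
      k <- sample(1:12, 1)
      on <- sort(runif(k, 0, 9000))
      dur <- pmin(runif(k, 80, 1500), c(diff(on), 9500 - on[k]))
      tibble::tibble(
        onset_ms = on, offset_ms = on + dur, duration_ms = dur,
        x_px = runif(k, 0, 1920), y_px = runif(k, 0, 1080),
        n_samples = 30, dispersion_deg = 0.5
      )
    })
    m <- aoi_fixation_time(fx, aois, sample(1:5, 1), c(1500, 6500), g)
    expect_lte(m$total_aoi_fixation_ms, 5000)
    expect_gte(m$total_aoi_fixation_ms, 0)
  }
})

test_that("condition summary averages per participant-by-condition cell", {
  design <- generate_design(2, 9)
  metrics <- tibble::tibble(
    participant_id = design$participant_id,
    trial_id = design$trial_id,
    total_aoi_fixation_ms = ifelse(design$perspective == "self", 1200, 800)
  )
  cs <- condition_summary(metrics, design)
  expect_equal(nrow(cs), 8) # 2 participants x 2 x 2
  expect_true(all(cs$mean_aoi_fixation_ms[cs$perspective == "self"] == 1200))
  expect_true(all(cs$mean_aoi_fixation_ms[cs$perspective == "other"] == 800))
  expect_true(all(cs$n_trials == 18))
  # grand mean equals the trial-weighted mean of the cells
  expect_equal(
    sum(cs$mean_aoi_fixation_ms * cs$n_trials) / sum(cs$n_trials),
    mean(metrics$total_aoi_fixation_ms)
  )
})
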