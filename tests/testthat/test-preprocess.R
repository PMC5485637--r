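g <- geometry_config()
cl <- cleaning_config()

test_that("validity requires on-screen gaze and physiological pupil in both eyes", {
  s <- make_stream(10)
  expect_true(all(flag_validity(s, g, cl)))
  s2 <- s
  s2$lx_px[3] <- -5 # off screen
  s2$rpupil_mm[5] <- 0 # non-positive pupil
  s2$lpupil_mm[6] <- 12 # outside physiological range
  s2$valid_flag[7] <- FALSE # tracker lost an eye
  v <- flag_validity(s2, g, cl)
  expect_equal(which(!v), c(3L, 5L, 6L, 7L))
})

test_that("Savitzky-Golay smoothing reproduces polynomials up to its order", {
  n <- 100
  t <- seq_len(n)
  s <- make_stream(n)
  s$lx_px <- 300 + 2 * t # linear
  s$ly_px <- 200 + 0.5 * t - 0.01 * t^2 # quadratic
  out <- smooth_gaze(s, cl)
  expect_lt(max(abs(out$lx_px - s$lx_px)), 1e-9)
  expect_lt(max(abs(out$ly_px[4:(n - 3)] - s$ly_px[4:(n - 3)])), 1e-9)
  # constant input is untouched
  expect_equal(out$rx_px, s$rx_px, tolerance = 1e-12)
})

test_that("Savitzky-Golay smoothing attenuates white noise", {
  n <- 10000
  s <- make_stream(n)
  s$lx_px <- withr::with_seed(1, 960 + rnorm(n, 0, 10))
  out <- smooth_gaze(s, cl)
  expect_lt(var(out$lx_px), var(s$lx_px))
  # theoretical noise gain of the order-2, 7-sample kernel is 1/3
  expect_equal(var(out$lx_px - 960) / var(s$lx_px - 960), 1 / 3, tolerance = 0.1)
})

test_that("median-3 pupil filter removes singleton spikes and keeps monotone runs", {
  s <- make_stream(20)
  s$lpupil_mm <- rep(3, 20)
  s$lpupil_mm[10] <- 5 # singleton spike
  s$rpupil_mm <- seq(3, 4.9, by = 0.1) # monotone
  out <- smooth_pupil(s, cl)
  expect_equal(out$lpupil_mm, rep(3, 20))
  expect_equal(out$rpupil_mm[2:19], s$rpupil_mm[2:19])
  # constant stays constant
  s2 <- make_stream(10)
  expect_equal(smooth_pupil(s2, cl)$lpupil_mm, rep(3.5, 10))
})

test_that("blink detection needs supra-threshold pupil change in both eyes", {
  s <- make_stream(60)
  ramp <- seq(3.5, 0.7, length.out = 8) # 0.4 mm/sample collapse
  recovery <- seq(0.7, 3.5, length.out = 8)[-1]
  s$lpupil_mm[20:34] <- c(ramp, recovery)
  s$rpupil_mm[20:34] <- c(ramp, recovery)
  sections <- detect_blinks(s, cl)
  expect_equal(nrow(sections), 1)
  expect_lte(sections$start, 21)
  expect_gte(sections$end, 34) # covers collapse and recovery ramps
  # same excursion in one eye only: no blink
  s1 <- make_stream(60)
  s1$lpupil_mm[20:27] <- ramp
  expect_equal(nrow(detect_blinks(s1, cl)), 0)
  expect_equal(nrow(detect_blinks(make_stream(30), cl)), 0)
})

test_that("repair holds gaze, interpolates pupil, and never touches valid samples", {
  s <- make_stream(10)
  s$lx_px <- c(100, 100, 7, 8, 9, 100, 100, 100, 100, 100)
  s$ly_px <- s$lx_px
  s$lpupil_mm <- c(3, 3, 9, 9, 3, 3, 4, 4, 4, 4)
  mask <- rep(TRUE, 10)
  mask[3:5] <- FALSE
  out <- repair_invalid(s, mask)
  expect_equal(out$lx_px[3:5], c(100, 100, 100)) # last valid value held
  # pupil linearly interpolated between 3 (sample 2) and 3 (sample 6)
  expect_equal(out$lpupil_mm[3:5], c(3, 3, 3))
  s2 <- make_stream(8)
  s2$lpupil_mm <- c(3, 3, 0, 0, 4, 4, 4, 4)
  m2 <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  out2 <- repair_invalid(s2, m2)
  expect_equal(out2$lpupil_mm[3:4], c(3 + 1 / 3, 3 + 2 / 3), tolerance = 0.01)
  # identity on fully valid input
  s3 <- make_stream(10)
  out3 <- repair_invalid(s3, rep(TRUE, 10))
  expect_equal(out3$lx_px, s3$lx_px)
  expect_error(repair_invalid(s3, rep(FALSE, 10)), "no valid samples")
})

test_that("repair preserves valid samples under random masks", {
  for (i in 1:20) {
    s <- make_stream(50)
    s$lx_px <- withr::with_seed(i, rnorm(50, 960, 40))
    s$lpupil_mm <- withr::with_seed(i + 100, runif(50, 3, 4))
    mask <- withr::with_seed(i + 200, runif(50) > 0.3)
    if (!any(mask)) next
    out <- repair_invalid(s, mask)
    expect_equal(out$lx_px[mask], s$lx_px[mask])
    expect_equal(out$lpupil_mm[mask], s$lpupil_mm[mask])
  }
})

test_that("pupil baseline correction zero-means the pre-onset window", {
  s <- make_stream(400) # 0..1330 ms
  s$lpupil_mm <- seq(3, 4, length.out = 400)
  onset <- 700
  out <- baseline_correct_pupil(s, onset, cl)
  win <- s$t_ms >= onset - 200 & s$t_ms < onset
  expect_equal(mean(out$lpupil_mm[win]), 0, tolerance = 1e-12)
  # constant trace becomes all zeros
  s2 <- make_stream(400, pupil = 4)
  expect_true(all(abs(baseline_correct_pupil(s2, onset, cl)$lpupil_mm) < 1e-12))
  expect_error(baseline_correct_pupil(s2, 100, cl), "insufficient")
})

test_that("drift correction cancels small offsets and refuses large ones", {
  cross <- c(960, 540)
  s <- make_stream(900, pos = cross + c(50, 0)) # uniform 50 px rightward error
  s$valid <- rep(TRUE, 900)
  res <- drift_correct_trial(s, cross, c(0, 1000), g, cl)
  expect_true(res$applied)
  expect_equal(unname(res$offset_px), c(-50, 0))
  win <- res$stream$t_ms <= 1000
  expect_equal(median(res$stream$lx_px[win]), cross[1], tolerance = 1e-9)

  s2 <- make_stream(900, pos = cross + c(200, 0))
  res2 <- drift_correct_trial(s2, cross, c(0, 1000), g, cl)
  expect_false(res2$applied)
  expect_equal(res2$reason, "drift_uncorrectable")
  expect_equal(res2$stream$lx_px, s2$lx_px)

  res3 <- drift_correct_trial(make_stream(900, pos = cross), cross, c(0, 1000), g, cl)
  expect_true(res3$applied)
  expect_equal(unname(res3$offset_px), c(0, 0))

  s4 <- make_stream(900)
  res4 <- drift_correct_trial(s4, cross, c(0, 1000), g, cl, mask = rep(FALSE, 900))
  expect_false(res4$applied)
  expect_equal(res4$reason, "no_valid_cross_samples")
})

test_that("drift correction composed with its inverse is the identity", {
  cross <- c(960, 540)
  s <- make_stream(600, pos = cross + c(-30, 20))
  res <- drift_correct_trial(s, cross, c(0, 1000), g, cl)
  back <- res$stream
  back$lx_px <- back$lx_px - res$offset_px[1]
  back$ly_px <- back$ly_px - res$offset_px[2]
  expect_lt(max(abs(back$lx_px - s$lx_px)), 1e-9)
  expect_lt(max(abs(back$ly_px - s$ly_px)), 1e-9)
})

test_that("participant-level y correction fixes a global vertical bias idempotently", {
  cross <- c(960, 540)
  mk_trial <- function(bias) {
    list(
      stream = make_stream(600, pos = cross + c(0, bias)),
      cross_position_px = cross,
      fixation_window = c(0, 1000)
    )
  }
  biased <- replicate(5, mk_trial(60), simplify = FALSE)
  res <- participant_y_correction(biased, g, cl)
  expect_true(res$applied)
  expect_equal(res$shift_px, -60, tolerance = 1e-9)
  resid <- vapply(res$trials, function(tr) {
    cross[2] - median(tr$stream$ly_px[tr$stream$t_ms <= 1000])
  }, numeric(1))
  expect_true(all(abs(resid) < 1e-9))
  # second pass applies nothing
  res2 <- participant_y_correction(res$trials, g, cl)
  expect_false(res2$applied)
  # unbiased data: no correction
  clean <- replicate(5, mk_trial(0), simplify = FALSE)
  expect_false(participant_y_correction(clean, g, cl)$applied)
})
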