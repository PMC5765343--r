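test_that("extract_series averages the window and keeps full precision", {
  st <- frame_stack(array(37L, c(10, 10, 5)))
  s <- extract_series(st, measurement_point(5, 5, 1))
  expect_equal(s$values, rep(37, 5))
  # radius 0 returns the raw single-pixel trace
  st2 <- random_stack(6, 6, 10)
  s2 <- extract_series(st2, measurement_point(3, 4, 0))
  expect_equal(s2$values, as.numeric(st2$frames[3, 4, ]))
  expect_error(extract_series(st, measurement_point(1, 5, 1)), "window")
})

test_that("the intensity series' dominant spectral peak sits at the beat frequency", {
  cfg <- small_config(n_frames = 300)
  m <- small_model(beat_frequency_hz = 15)
  sim <- generate_video(m, cfg)
  pts <- default_measurement_points(m, cfg)
  v <- extract_series(sim$stack, pts[3, ])$values
  v <- v - mean(v)
  spec <- Mod(stats::fft(v))[2:(length(v) %/% 2)]
  peak_hz <- which.max(spec) * cfg$fps / length(v)
  expect_lt(abs(peak_hz - 15), cfg$fps / length(v) + 1e-9)
})

test_that("zero-crossing frequency handles constants, sines and plateaus", {
  expect_equal(beat_frequency(list(values = rep(3, 100), fps = 300)), 0)
  tt <- (0:999) / 300
  sine <- list(values = sin(2 * pi * 10 * tt), fps = 300)
  expect_lt(abs(beat_frequency(sine) - 10), 0.15)
  expect_lt(abs(beat_frequency(sine, method = "count") - 10), 0.15)
  # zero samples inherit the previous sign: one crossing per sign flip only
  v <- c(1, 0, -1, 0, 1, 0, -1, 0)
  # signs become + + - - + + - -: three crossings over 8 samples
  expect_equal(beat_frequency(list(values = v, fps = 8), smoothing_window = 1,
                              method = "count"), 3 / (2 * 1))
  expect_error(beat_frequency(sine, smoothing_window = 2), "odd")
})

test_that("kymographs are time-invariant for static scenes and reduce to series", {
  cfg <- small_config(n_frames = 12)
  m <- small_model(amplitude_um = 0)
  st <- generate_video(m, cfg)$stack
  km <- kymograph(st, measurement_point(32, 40), 21, 90)
  expect_true(all(km == km[, 1]))
  # probe of length 1 degenerates to the radius-0 intensity series
  km1 <- kymograph(st, measurement_point(32, 40), 1, 90)
  expect_equal(as.numeric(km1),
               extract_series(st, measurement_point(32, 40, 0))$values)
  expect_error(kymograph(st, measurement_point(2, 40), 21, 90), "probe")
})

test_that("the kymograph peak traces the analytic midline oscillation", {
  cfg <- small_config(n_frames = 120)
  m <- small_model(beat_frequency_hz = 12)
  sim <- generate_video(m, cfg)
  col <- 40
  km <- kymograph(sim$stack, measurement_point(32, col), 41, 90)
  peaks <- apply(km, 2, which.max) - 21   # offset from centreline row
  frac <- (col - m$head_position_px[2]) / (m$length_um * 2.8)
  truth <- ground_truth_displacement(sim$ground_truth, frac,
                                     (seq_len(120) - 1) / cfg$fps, units = "px")
  expect_gt(stats::cor(peaks, truth), 0.99)
  expect_lt(max(abs(peaks - truth)), 1)
})

test_that("beat speed recovers 4Af on sinusoids and scales with calibration", {
  cfg <- small_config(n_frames = 300)
  m <- small_model(beat_frequency_hz = 10, amplitude_um = 3)
  st <- generate_video(m, cfg)$stack
  km <- kymograph(st, measurement_point(32, 40), 41, 90)
  v <- beat_speed(km)
  expect_lt(abs(v - 4 * 3 * 10) / (4 * 3 * 10), 0.05)
  # halving px_per_10um doubles the reported speed for the same pixel track
  expect_equal(beat_speed(km, fps = 300, px_per_10um = 14), 2 * v)
  # a static flagellum has zero speed
  st0 <- generate_video(small_model(amplitude_um = 0), small_config(n_frames = 20))$stack
  expect_equal(beat_speed(kymograph(st0, measurement_point(32, 40), 21, 90)), 0)
  # pure background is untrackable
  flat <- frame_stack(array(20L, c(30, 30, 20)))
  expect_error(beat_speed(kymograph(flat, measurement_point(15, 15), 11, 90)),
               "untrackable")
})

test_that("intensity index matches its formula, bounds and oracle", {
  # identical frames score zero
  expect_equal(intensity_index(frame_stack(array(7L, c(4, 4, 6)))), 0)
  # full-field 0/255 flicker at d = 1 attains the 8-bit maximum 255/256
  flick <- frame_stack(array(rep(c(0L, 255L), each = 16), c(4, 4, 10)))
  expect_equal(intensity_index(flick, d = 1), 100 * 255 / 256)
  # vectorised result equals the literal triple-loop transcription, exactly
  set.seed(41)
  for (rep in 1:5) {
    st <- frame_stack(array(sample(0:255, 2 * 2 * 4, TRUE), c(2, 2, 4)))
    for (d in 1:3)
      expect_identical(intensity_index(st, d = d), intensity_index_loop(st, d))
  }
  # linearity in the pixel differences (pre-clipping construction)
  a <- array(rep(c(0L, 10L), each = 16), c(4, 4, 8))
  b <- array(rep(c(0L, 20L), each = 16), c(4, 4, 8))
  expect_equal(2 * intensity_index(frame_stack(a)), intensity_index(frame_stack(b)))
  # additive noise strictly increases the index of a static scene
  m0 <- small_model(amplitude_um = 0, noise_sd = 0)
  mn <- small_model(amplitude_um = 0, noise_sd = 4)
  cfg <- small_config(n_frames = 30)
  expect_gt(intensity_index(generate_video(mn, cfg)$stack),
            intensity_index(generate_video(m0, cfg)$stack))
  expect_error(intensity_index(frame_stack(array(0L, c(2, 2, 3))), d = 3), "lag")
})

test_that("motion reports have one row per point plus a summary row", {
  cfg <- small_config(n_frames = 150)
  m <- small_model(beat_frequency_hz = 12)
  sim <- generate_video(m, cfg)
  pts <- default_measurement_points(m, cfg)
  rep <- motion_report(sim$stack, pts, probe_length_px = 41)
  expect_identical(nrow(rep), nrow(pts) + 1L)
  expect_identical(rep$point_id[nrow(rep)], "mean")
  expect_lt(abs(rep$beat_frequency_hz[nrow(rep)] - 12), 0.3)
  expect_true(is.finite(attr(rep, "intensity_index")))
  # static scene: all-zero motion
  st0 <- generate_video(small_model(amplitude_um = 0), small_config(n_frames = 30))$stack
  pts0 <- data.frame(row = c(30, 34), col = c(30, 50), window_radius = 1)
  rep0 <- motion_report(st0, pts0, probe_length_px = 15)
  expect_equal(rep0$beat_frequency_hz, rep(0, 3))
  expect_equal(rep0$beat_speed_um_s, rep(0, 3))
  # CSV export carries the footer rows
  f <- withr::local_tempfile(fileext = ".csv")
  write_motion_report(rep, f)
  out <- utils::read.csv(f)
  expect_identical(out$point_id, c(paste0("p", 1:5), "mean", "se", "intensity_index"))
})
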