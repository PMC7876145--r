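test_that("a quiet noiseless movie is uniform at the background level", {
  cfg <- tirf_sim_config(frame_count = 3, image_size = 32, arrival_rate = 0,
                         n_diffuse = 0, shot_noise = FALSE, read_noise_sd = 0)
  mv <- generate_tirf_movie(cfg)
  for (f in mv$stack$frames)
    expect_true(all(f == cfg$background_level))
})

test_that("a scripted event appears in the per-frame truth count exactly", {
  cfg <- tirf_sim_config(frame_count = 40, image_size = 32, arrival_rate = 0,
                         n_diffuse = 0, shot_noise = FALSE, read_noise_sd = 0)
  ev <- data.frame(x = 15.3, y = 12.7, start_frame = 10, end_frame = 29)
  mv <- generate_tirf_movie(cfg, events = ev)
  expected <- as.integer(seq_len(40) - 1 >= 10 & seq_len(40) - 1 <= 29)
  expect_equal(mv$truth$per_frame_docked_count, expected)
})

test_that("event durations follow the configured mean residence", {
  sim <- simulate_track_set(2000, 0.5, 900, frame_period = 40, seed = 21)
  ev <- sim$truth$event_log
  # drop clipped events so the mean is not biased by the movie end
  ok <- ev$end_frame < 1999
  dur_ms <- (ev$end_frame[ok] - ev$start_frame[ok] + 1) * 40
  expect_lt(abs(mean(dur_ms) - 900) / 900, 0.05)
})

test_that("steady-state occupancy converges to arrival_rate x residence frames", {
  lam <- 0.8; m_frames <- 15
  sim <- simulate_track_set(4000, lam, m_frames * 40, seed = 31)
  occ <- sim$truth$per_frame_docked_count[1000:4000]
  target <- lam * m_frames
  se <- sd(occ) / sqrt(length(occ) / (2 * m_frames))
  expect_lt(abs(mean(occ) - target), 3 * se)
})

test_that("seeded movie generation is bit-reproducible", {
  cfg <- tirf_sim_config(frame_count = 6, image_size = 48, seed = 8,
                         arrival_rate = 1, mean_residence = 300)
  a <- generate_tirf_movie(cfg)
  b <- generate_tirf_movie(cfg)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth$event_log, b$truth$event_log)
})

test_that("track-set truth counts are consistent with the event log", {
  sim <- simulate_track_set(300, 0.3, 500, dropout_prob = 0.2, seed = 13)
  ev <- sim$truth$event_log
  cnt <- vapply(0:299, function(f)
    sum(ev$start_frame <= f & ev$end_frame >= f), 0L)
  expect_equal(sim$truth$per_frame_docked_count, cnt)
  expect_true(all(ev$end_frame >= ev$start_frame))
})

test_that("undersized fields are rejected", {
  expect_error(tirf_sim_config(image_size = 8), "image_size")
})
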