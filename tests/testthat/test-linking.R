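test_that("a stationary particle yields one full-length track", {
  det <- data.frame(frame = 0:9, x = 5, y = 5)
  tr <- link_particles(det, frame_count = 10)
  expect_identical(length(unique(tr$points$track_id)), 1L)
  expect_identical(nrow(tr$points), 10L)
})

test_that("well-separated particles never swap", {
  det <- rbind(data.frame(frame = 0:9, x = 5, y = 5),
               data.frame(frame = 0:9, x = 25, y = 5))
  tr <- link_particles(det, max_displacement = 3, frame_count = 10)
  expect_identical(length(unique(tr$points$track_id)), 2L)
  for (id in unique(tr$points$track_id)) {
    p <- tr$points[tr$points$track_id == id, ]
    expect_true(all(p$x == p$x[1]))
  }
})

test_that("gap closing bridges a single dropout and max_gap 0 splits it", {
  det <- data.frame(frame = c(0, 1, 2, 4, 5), x = 10, y = 10)
  tr1 <- link_particles(det, max_gap = 1, frame_count = 6)
  expect_identical(length(unique(tr1$points$track_id)), 1L)
  bridged <- tr1$points[tr1$points$frame == 3, ]
  expect_identical(nrow(bridged), 1L)
  expect_false(bridged$observed)
  tr0 <- link_particles(det, max_gap = 0, frame_count = 6)
  expect_identical(length(unique(tr0$points$track_id)), 2L)
})

test_that("every detection is assigned exactly once (conservation)", {
  set.seed(5)
  sim <- simulate_track_set(80, 0.4, 600, dropout_prob = 0, image_size = 64,
                            seed = 5)
  obs <- sim$tracks$points
  det <- data.frame(frame = obs$frame, x = obs$x, y = obs$y)
  tr <- link_particles(det, frame_count = 80)
  expect_identical(sum(tr$points$observed), nrow(det))
})

test_that("track count equals true event count on clean well-separated movies", {
  ev <- data.frame(x = c(10, 40, 20), y = c(12, 35, 50),
                   start_frame = c(2, 10, 20), end_frame = c(15, 30, 39))
  cfg <- tirf_sim_config(frame_count = 40, image_size = 64, arrival_rate = 0,
                         n_diffuse = 0, bleach_rate = 0, shot_noise = FALSE,
                         read_noise_sd = 0, seed = 3)
  mv <- generate_tirf_movie(cfg, events = ev)
  det <- detect_stack(mv$stack)
  tr <- link_particles(det, frame_count = 40)
  expect_identical(length(unique(tr$points$track_id)), 3L)
})
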