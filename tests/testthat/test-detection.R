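test_that("a blank frame yields no detections", {
  expect_identical(nrow(detect_spots(matrix(5, 32, 32))), 0L)
})

test_that("isolated Gaussian spots are found within 1 px of truth", {
  xs <- c(6.3, 24.7, 9.2, 25.5, 16.0)
  ys <- c(7.1, 5.9, 24.4, 22.8, 15.2)
  img <- gaussian_frame(32, xs, ys, amp = rep(150, 5), sigma = 1.7)
  set.seed(2)
  img <- img + rnorm(length(img), sd = 2)
  det <- detect_spots(img, diameter = 5, quality_threshold = 10)
  expect_identical(nrow(det), 5L)
  d <- sqrt(outer(xs, det$x, "-")^2 + outer(ys, det$y, "-")^2)
  expect_true(all(apply(d, 1, min) < 1))
})

test_that("two spots closer than the resolution limit merge into one", {
  img <- gaussian_frame(32, c(15.5, 16.5), c(16, 16), amp = c(120, 120),
                        sigma = 1.7)
  det <- detect_spots(img, diameter = 5, quality_threshold = 10)
  expect_identical(nrow(det), 1L)
})

test_that("detection benchmark on generator movies: recall, precision, RMSE", {
  cfg <- tirf_sim_config(frame_count = 45, image_size = 128,
                         arrival_rate = 26.8 / 22.5, mean_residence = 900,
                         seed = 9)
  mv <- generate_tirf_movie(cfg)
  frames <- 15:44   # past the fill-up transient
  det <- detect_stack(mv$stack, frames = frames)
  ev <- mv$truth$event_log
  tp_t <- n_t <- tp_d <- n_d <- 0; errs <- c()
  for (f in frames) {
    act <- ev[ev$start_frame <= f & ev$end_frame >= f, ]
    df <- det[det$frame == f, ]
    dm <- sqrt(outer(act$x, df$x, "-")^2 + outer(act$y, df$y, "-")^2)
    # recall scored on resolvable events: PSF inside the field and no other
    # active vesicle within one spot diameter (5 px)
    interior <- act$x >= 3 & act$x <= 124 & act$y >= 3 & act$y <= 124
    de <- sqrt(outer(act$x, act$x, "-")^2 + outer(act$y, act$y, "-")^2)
    diag(de) <- Inf
    resolvable <- interior & apply(de, 1, min) > 5
    hit <- apply(dm, 1, function(r) any(r <= 1))
    tp_t <- tp_t + sum(hit[resolvable]); n_t <- n_t + sum(resolvable)
    # a detection corresponds to a docked vesicle if one lies within half a
    # spot diameter (a merged pair detects at the midpoint)
    tp_d <- tp_d + sum(apply(dm, 2, function(r) any(r <= 2.5)))
    n_d <- n_d + nrow(df)
    errs <- c(errs, apply(dm, 1, min)[hit])
  }
  expect_gte(tp_t / n_t, 0.95)                 # recall
  expect_gte(tp_d / n_d, 0.90)                 # precision (diffuse removed)
  expect_lte(sqrt(mean(errs^2)), 0.5)          # localisation RMSE
})
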