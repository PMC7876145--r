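test_that("offset averaging is the arithmetic mean of the +/- pair", {
  pr <- cest_profile_set(1:2, c(-1.5, 1.5),
                         rbind(c(0.8, 0.6), c(0.5, 0.5)))
  avg <- average_cest_offsets(pr, 1.5)
  expect_equal(unname(avg), c(0.7, 0.5))
  expect_error(average_cest_offsets(pr, 3), "\\+3")
  # symmetric noiseless profile: average equals either side
  cfg <- cest_sim_config(per_residue_bound_fraction = rep(0.3, 4), noise_sd = 0)
  prs <- generate_cest_profiles(cfg)$profiles
  i <- which(prs$offsets == 1.5)
  expect_equal(unname(average_cest_offsets(prs, 1.5)),
               unname(prs$ratios[, i]), tolerance = 1e-12)
})

test_that("offset averaging round-trips the generator formula", {
  pb <- 0.4; w <- 10; d <- 0.35
  cfg <- cest_sim_config(per_residue_bound_fraction = rep(pb, 3),
                         transfer_width = w, direct_sat_width = d,
                         noise_sd = 0)
  pr <- generate_cest_profiles(cfg)$profiles
  Tx <- w^2 / (w^2 + 1.5^2); Dx <- d^2 / (d^2 + 1.5^2)
  expect_equal(unname(average_cest_offsets(pr, 1.5)),
               rep((1 - pb * Tx) * (1 - Dx), 3), tolerance = 1e-12)
})

test_that("detached-population estimator hits its fixed points", {
  # region identical to reference -> 1
  pr <- cest_profile_set(60:140, c(-1.5, 1.5),
                         matrix(0.9, 81, 2))
  est <- estimate_detached_population(pr, region_definition(65, 97))
  expect_equal(est$fraction_detached, 1)
  # fully saturated region -> 0
  ratios <- matrix(0.9, 81, 2)
  ratios[60:140 %in% 65:97, ] <- 0
  pr0 <- cest_profile_set(60:140, c(-1.5, 1.5), ratios)
  expect_equal(estimate_detached_population(pr0, region_definition(65, 97))$fraction_detached, 0)
  # saturated reference is an error
  rat2 <- matrix(0.05, 81, 2)
  pr2 <- cest_profile_set(60:140, c(-1.5, 1.5), rat2)
  expect_error(estimate_detached_population(pr2, region_definition(65, 97)),
               "reference")
})

test_that("estimator recovers the generated detached population within 5 points", {
  pb <- ifelse(seq_len(140) %in% 65:97, 0.05, 0)
  for (s in 1:5) {
    cfg <- cest_sim_config(offsets = c(-5, -3, -1.5, 1.5, 3, 5),
                           per_residue_bound_fraction = pb,
                           noise_sd = 0.02, seed = s)
    pr <- generate_cest_profiles(cfg)$profiles
    est <- estimate_detached_population(pr, region_definition(65, 97))
    expect_lt(abs(est$fraction_detached - 0.95), 0.05)
  }
})
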