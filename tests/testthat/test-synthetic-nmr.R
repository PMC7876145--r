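test_that("noiseless titration equals the isotherm exactly and is 1 at zero lipid", {
  cfg <- nmr_sim_config(noise_sd = 0, n_residues = 20,
                        lipid_concs = c(0, 100, 500, 2000, 14000))
  sim <- generate_titration(cfg)
  expect_true(all(sim$dataset$ratios[, 1] == 1))
  chi <- eval_binding_model(50, cfg$lipid_concs, 5.2, 14.3)
  for (j in seq_along(cfg$lipid_concs))
    expect_equal(sim$dataset$ratios[, j], rep(1 - chi[j], 20),
                 tolerance = 1e-12)
  # frozen spot check: chi at 1000 uM is ~0.84
  cfg2 <- nmr_sim_config(noise_sd = 0, n_residues = 3,
                         lipid_concs = c(0, 500, 900, 1000))
  r <- generate_titration(cfg2)$dataset$ratios[1, 4]
  expect_equal(r, 1 - 0.842458380712, tolerance = 1e-9)
})

test_that("titration generation is reproducible and respects region scaling", {
  regions <- list(list(region = region_definition(1, 10), scaling = 1),
                  list(region = region_definition(11, 20), scaling = 0.25))
  cfg <- nmr_sim_config(noise_sd = 0.02, n_residues = 20, regions = regions,
                        lipid_concs = c(0, 100, 500, 2000, 14000), seed = 7)
  a <- generate_titration(cfg)
  b <- generate_titration(cfg)
  expect_identical(a$dataset$ratios, b$dataset$ratios)
  expect_true(all(a$dataset$ratios >= 0 & a$dataset$ratios <= 1.05))
  # scaled region attenuates 4x less, noiselessly
  cfg0 <- nmr_sim_config(noise_sd = 0, n_residues = 20, regions = regions,
                         lipid_concs = c(0, 100, 500, 2000, 14000))
  r0 <- generate_titration(cfg0)$dataset$ratios
  expect_equal(1 - r0[15, 5], (1 - r0[5, 5]) * 0.25, tolerance = 1e-12)
})

test_that("unusable noise levels are rejected", {
  cfg <- nmr_sim_config(noise_sd = 0.5)
  expect_error(generate_titration(cfg), "clipping")
})

test_that("CEST generator matches its stated saturation model", {
  # p_b = 0: profile is the pure direct-saturation shape
  cfg <- cest_sim_config(per_residue_bound_fraction = rep(0, 5), noise_sd = 0)
  pr <- generate_cest_profiles(cfg)$profiles
  d2 <- cfg$direct_sat_width^2
  expect_equal(pr$ratios[1, ], 1 - d2 / (d2 + cfg$offsets^2), tolerance = 1e-12,
               ignore_attr = TRUE)
  # full saturation at zero offset
  cfg1 <- cest_sim_config(per_residue_bound_fraction = rep(1, 2), noise_sd = 0)
  pr1 <- generate_cest_profiles(cfg1)$profiles
  expect_equal(pr1$ratios[1, which(pr1$offsets == 0)], 0, tolerance = 1e-12)
  # p_b = 0.5, w = 3 kHz at offset 3 kHz with negligible direct saturation
  cfg2 <- cest_sim_config(offsets = c(-3, 3),
                          per_residue_bound_fraction = 0.5,
                          transfer_width = 3, direct_sat_width = 1e-4,
                          noise_sd = 0)
  pr2 <- generate_cest_profiles(cfg2)$profiles
  expect_equal(unname(pr2$ratios[1, 2]), 0.75, tolerance = 1e-6)
})

test_that("noiseless CEST profiles are even in the offset", {
  cfg <- cest_sim_config(per_residue_bound_fraction = runif(10), noise_sd = 0,
                         seed = 3)
  pr <- generate_cest_profiles(cfg)$profiles
  for (x in unique(abs(pr$offsets))) {
    ip <- which(pr$offsets == x); im <- which(pr$offsets == -x)
    expect_equal(pr$ratios[, ip[1]], pr$ratios[, im[1]], tolerance = 1e-12)
  }
})

test_that("relaxation generator hits exact values and is reproducible", {
  g <- generate_relaxation(80, c(0, 80, 160), noise_sd = 0)
  expect_equal(unname(g$series$intensities[1, ]), c(1, exp(-1), exp(-2)),
               tolerance = 1e-12)
  a <- generate_relaxation(50, seq(0, 200, by = 25), noise_sd = 0.01, seed = 5)
  b <- generate_relaxation(50, seq(0, 200, by = 25), noise_sd = 0.01, seed = 5)
  expect_identical(a$series$intensities, b$series$intensities)
})
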