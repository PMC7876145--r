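test_that("region averaging of attenuations is exact arithmetic", {
  ds <- titration_dataset(50, residues = 1:2, lipid_concs = c(0, 100),
                         ratios = rbind(c(1, 0.2), c(1, 0.4)))
  cur <- compute_bound_fraction(ds, region_definition(1, 2))
  expect_equal(unname(cur$chi_b_mean), c(0, 0.7))
  expect_equal(unname(cur$chi_b_sd[2]), stats::sd(c(0.8, 0.6)))
  # all-ones dataset gives zero everywhere
  ds1 <- titration_dataset(50, 1:3, c(0, 10, 100), matrix(1, 3, 3))
  expect_true(all(compute_bound_fraction(ds1, region_definition(1, 3))$chi_b_mean == 0))
  expect_error(compute_bound_fraction(ds, region_definition(50, 60)),
               "no residues")
})

test_that("round trip: noiseless generator curve equals the isotherm pointwise", {
  cfg <- nmr_sim_config(noise_sd = 0, n_residues = 30)
  sim <- generate_titration(cfg)
  cur <- compute_bound_fraction(sim$dataset, region_definition(1, 25, "N-term"))
  expect_equal(unname(cur$chi_b_mean),
               eval_binding_model(50, cfg$lipid_concs, 5.2, 14.3),
               tolerance = 1e-12)
})

test_that("noiseless fits recover every study parameter pair", {
  pairs <- list(c(5.2, 14.3), c(88.9, 10.3), c(5933, 5.7),
                c(424.5, 17.5), c(16.0, 34.5))
  for (p in pairs) {
    cfg <- nmr_sim_config(kd_true = p[1], l_true = p[2], noise_sd = 0,
                          n_residues = 25)
    cur <- compute_bound_fraction(generate_titration(cfg)$dataset,
                                  region_definition(1, 25))
    fit <- fit_binding_curve(cur)
    expect_true(fit$converged)
    expect_equal(fit$kd, p[1], tolerance = 1e-6)
    expect_equal(fit$l, p[2], tolerance = 1e-6)
  }
})

test_that("fit on a zero curve reports no convergence without erroring", {
  ds <- titration_dataset(50, 1:5, c(0, 10, 100, 1000), matrix(1, 5, 4))
  fit <- fit_binding_curve(compute_bound_fraction(ds, region_definition(1, 5)))
  expect_false(fit$converged)
})

test_that("noisy fits recover K_D to within ~10% (median over seeds)", {
  errs <- vapply(1:12, function(s) {
    cfg <- nmr_sim_config(noise_sd = 0.02, n_residues = 25, seed = s)
    cur <- compute_bound_fraction(generate_titration(cfg)$dataset,
                                  region_definition(1, 25))
    abs(fit_binding_curve(cur)$kd - 5.2) / 5.2
  }, 0)
  expect_lt(median(errs), 0.10)
})
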