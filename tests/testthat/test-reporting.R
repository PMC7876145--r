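test_that("Welch test hits the hand-computed fixture", {
  r <- welch_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t_statistic, -1.2247448714, tolerance = 1e-9)
  expect_equal(r$degrees_of_freedom, 4, tolerance = 1e-9)
  expect_equal(r$p_value, 0.2878641347, tolerance = 1e-9)
})

test_that("identical samples give t = 0, p = 1; zero-variance contrast flags", {
  r <- welch_ttest(c(5, 5, 6), c(5, 5, 6))
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)
  d <- welch_ttest(c(0, 0), c(1, 1))
  expect_true(d$degenerate)
  expect_equal(d$p_value, 0)
  expect_error(welch_ttest(1, c(1, 2)), "at least 2")
})

test_that("Welch test agrees with stats::t.test to 1e-10 on random inputs", {
  set.seed(99)
  for (k in 1:300) {
    a <- rnorm(sample(2:12, 1), sd = runif(1, 0.2, 3))
    b <- rnorm(sample(2:12, 1), mean = runif(1, -1, 1), sd = runif(1, 0.2, 3))
    r <- welch_ttest(a, b)
    ref <- stats::t.test(a, b)
    expect_equal(r$t_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$degrees_of_freedom, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("replicate aggregation uses the n-1 denominator", {
  expect_equal(aggregate_replicates(c(10, 10, 10)), c(mean = 10, sd = 0))
  expect_equal(aggregate_replicates(c(1, 2, 3)), c(mean = 2, sd = 1))
  expect_error(aggregate_replicates(5), "at least 2")
})

test_that("the pipeline produces a structured, deterministic report", {
  config <- list(
    seed = 3,
    conditions = list(
      no_protein = list(arrival_rate = 0.3, mean_residence = 440,
                        frame_count = 800, n_replicates = 2),
      with_protein = list(arrival_rate = 0.6, mean_residence = 900,
                          frame_count = 800, n_replicates = 2)),
    comparisons = list(list(a = "no_protein", b = "with_protein",
                            metric = "residence")))
  r1 <- run_pipeline(config)
  expect_named(r1$conditions, c("no_protein", "with_protein"))
  expect_length(r1$comparisons, 1)
  expect_true(r1$comparisons[[1]]$p_value >= 0 && r1$comparisons[[1]]$p_value <= 1)
  r2 <- run_pipeline(config)
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  write_report(r1, p1); write_report(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # zero arrival rate reports zero docked vesicles
  cfg0 <- list(seed = 1, conditions = list(
    empty = list(arrival_rate = 0, mean_residence = 400, frame_count = 300,
                 n_replicates = 2)))
  r0 <- run_pipeline(cfg0)
  expect_equal(r0$conditions$empty$mean_docked$mean, 0)
})
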