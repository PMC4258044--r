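test_that("the trivial [0,1] oracle method has coverage and width exactly 1", {
  sc <- scenario_spec(icc_design(8, 3), 0.7, 0.9)
  res <- run_coverage_study(sc, methods = "oracle", n_reps = 100, seed = 51)
  expect_equal(res$coverage, 1)
  expect_equal(res$mean_width, 1)
  expect_equal(res$sem_width, 0)
  expect_equal(res$n_failed, 0L)
})

test_that("coverage studies are seed-reproducible with sane summaries", {
  sc <- scenario_spec(icc_design(12, 3), 0.7, 0.9)
  r1 <- run_coverage_study(sc, methods = c("mls", "gci"), n_reps = 150,
                           gci_draws = 2000, seed = 52)
  r2 <- run_coverage_study(sc, methods = c("mls", "gci"), n_reps = 150,
                           gci_draws = 2000, seed = 52)
  expect_equal(r1$coverage, r2$coverage)
  expect_equal(r1$mean_width, r2$mean_width)
  expect_true(all(r1$coverage >= 0 & r1$coverage <= 1))
  expect_true(all(r1$sem_width > 0))
  expect_named(r1, c("method", "n_reps", "coverage", "mean_width",
                     "sem_width", "mean_point", "sd_point", "n_failed"))
  expect_error(run_coverage_study(sc, n_reps = 50), "at least 100")
})

test_that("residual p-values are approximately uniform under normality", {
  sc <- scenario_spec(icc_design(48, 3), 0.70, 0.99, family = "normal")
  res <- shapiro_residual_study(sc, n_reps = 600, seed = 53)
  # near-uniform; the projection correlation between residuals makes the
  # test slightly conservative (long-run mean p ~0.52, rejection ~3.5%)
  expect_gt(res$mean_p, 0.46)
  expect_lt(res$mean_p, 0.58)
  expect_gt(res$prop_above_05, 0.92)
  expect_error(
    shapiro_residual_study(scenario_spec(icc_design(6, 3, 2), 0.7, 0.9)),
    "r0 = 1")
})

test_that("method recommendation follows the 8-level simulation rule", {
  all3 <- recommend_method(icc_design(96, 8), normality_ok = TRUE)
  expect_setequal(all3$recommended, c("mls", "gci", "bayes"))
  expect_false(all3$caution)

  freq <- recommend_method(icc_design(48, 3), normality_ok = TRUE)
  expect_setequal(freq$recommended, c("mls", "gci"))

  none <- recommend_method(icc_design(48, 3), normality_ok = FALSE)
  expect_length(none$recommended, 0)
  expect_true(none$caution)
  expect_match(none$rationale, "None of the methods work well")
  # the cutoff and the weakness of normality tests are both flagged
  expect_match(all3$rationale, "estimate based on simulation")
  expect_match(all3$rationale, "weak")
})
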