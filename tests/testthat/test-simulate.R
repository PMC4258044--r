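test_that("variance components solve the ICC targets and round-trip", {
  vc <- solve_variance_components(0.70, 0.99)
  expect_equal(c(vc$sigma2_b, vc$sigma2_l, vc$sigma2_e),
               c(0.70, 0.29, 0.01))
  vc2 <- solve_variance_components(0.70, 0.70)
  expect_equal(c(vc2$sigma2_b, vc2$sigma2_l, vc2$sigma2_e),
               c(0.70, 0, 0.30))
  vc3 <- solve_variance_components(0.90, 0.94)
  expect_equal(c(vc3$sigma2_b, vc3$sigma2_l, vc3$sigma2_e),
               c(0.90, 0.04, 0.06))
  for (v in list(vc, vc2, vc3)) {
    expect_equal(icc_b(v), v$sigma2_b)  # total variance is 1
    expect_equal(icc_w(v), v$sigma2_b + v$sigma2_l)
  }
  expect_error(solve_variance_components(0.8, 0.7), "infeasible")
})

test_that("closed-form family moments are correct", {
  gm <- effect_moments(1, "gamma", alpha = 3)
  expect_equal(round(gm$skewness, 2), 1.15)
  expect_equal(gm$kurtosis, 5)
  gm10 <- effect_moments(1, "gamma", alpha = 10)
  expect_equal(round(gm10$skewness, 2), 0.63)
  expect_equal(gm10$kurtosis, 3.6)
  expect_equal(effect_moments(2, "uniform")$kurtosis, 1.8)
  expect_equal(effect_moments(2, "normal")$skewness, 0)
})

test_that("every family is moment matched to its target variance", {
  set.seed(41)
  n <- 2e5
  for (fam in c("normal", "uniform", "mixture", "gamma")) {
    s2 <- 2.5
    x <- draw_effect(n, s2, fam, alpha = 3)
    expect_lt(abs(mean(x)), 3 * sqrt(s2 / n))
    expect_equal(stats::var(x), s2, tolerance = 0.02)
    mom <- effect_moments(s2, fam, alpha = 3)
    expect_equal(sample_skewness(x), mom$skewness, tolerance = 0.05)
    expect_equal(sample_kurtosis(x), mom$kurtosis, tolerance = 0.1)
  }
})

test_that("uniform draws are bounded and mixture location solves mu^2*10/9", {
  set.seed(42)
  x <- draw_effect(1e4, 0.75, "uniform")
  expect_true(all(abs(x) <= sqrt(3 * 0.75) + 1e-12))
  # target variance 10/9 puts the mixture modes at +/- 1 with sd 1/3;
  # E|X| is then 1 up to a negligible overlap correction
  m <- draw_effect(2e5, 10 / 9, "mixture")
  expect_equal(mean(abs(m)), 1, tolerance = 0.01)
})

test_that("zero-variance components yield identically zero terms", {
  expect_identical(draw_effect(5, 0, "gamma"), numeric(5))
  sc <- scenario_spec(icc_design(6, 3), 0.7, 0.7) # sigma2_l = 0
  g1 <- generate_data(sc, seed = 43)
  g2 <- generate_data(sc, seed = 43)
  expect_identical(g1$values, g2$values)
})

test_that("generation is deterministic in the seed and respects the design", {
  sc <- scenario_spec(icc_design(10, 4, 2), 0.7, 0.9, family = "gamma",
                      alpha = 3, mu = 5)
  g1 <- generate_data(sc, seed = 44)
  g2 <- generate_data(sc, seed = 44)
  g3 <- generate_data(sc, seed = 45)
  expect_identical(g1$values, g2$values)
  expect_false(identical(g1$values, g3$values))
  expect_equal(dim(g1$values), c(10L, 4L, 2L))
  # replicates within a cell share subject and rater effects, so the
  # between-replicate spread inside a cell reflects only sigma2_e
  diffs <- g1$values[, , 1] - g1$values[, , 2]
  expect_lt(stats::var(as.vector(diffs)), 6 * 2 * (1 - 0.9))
})

test_that("simulated grids hit the target ICCs on average", {
  sc <- scenario_spec(icc_design(48, 3), 0.70, 0.99)
  set.seed(46)
  est <- replicate(200, icc_b(mean_squares(generate_data(sc))))
  # point estimates at this design have SD ~0.17 and a slight upward
  # bias: long-run mean ~0.74 at a true value of 0.70
  expect_equal(mean(est), 0.74, tolerance = 0.06)
})
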