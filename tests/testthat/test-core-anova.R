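test_that("mean squares match hand-computed and published tables", {
  ms <- mean_squares(tiny_grid())
  expect_equal(ms$ms_subject, 6.25)
  expect_equal(ms$ms_rater, 2.25)
  expect_equal(ms$ms_error, 0.25)

  const <- icc_data(matrix(5, nrow = 3, ncol = 2))
  msc <- mean_squares(const)
  expect_equal(c(msc$ms_subject, msc$ms_rater, msc$ms_error), c(0, 0, 0))

  # published ANOVA tables report SS and DF; MS must be their ratio
  expect_equal(39.73 / 9, 4.414, tolerance = 1e-3)
  s <- agreement_study_summary()
  expect_equal(s$ss_rater / s$df_rater, s$ms_rater)
})

test_that("mean squares agree with the aov decomposition on random grids", {
  for (case in list(c(6, 3, 1, 11), c(5, 4, 2, 12), c(9, 2, 3, 13))) {
    g <- random_grid(case[1], case[2], case[3], seed = case[4])
    ms <- mean_squares(g)
    df <- as.data.frame(g)
    fit <- stats::aov(value ~ factor(subject) + factor(rater), data = df)
    tab <- summary(fit)[[1]]
    expect_equal(ms$ms_subject, tab["factor(subject)", "Mean Sq"],
                 tolerance = 1e-10)
    expect_equal(ms$ms_rater, tab["factor(rater)", "Mean Sq"],
                 tolerance = 1e-10)
    expect_equal(ms$ms_error, tab["Residuals", "Mean Sq"],
                 tolerance = 1e-10)
    # the three lines reconcile with the total corrected SS
    expect_equal(ms$ss_subject + ms$ss_rater + ms$ss_error,
                 sum((g$values - mean(g$values))^2), tolerance = 1e-10)
  }
})

test_that("mean squares are location invariant and scale equivariant", {
  g <- random_grid(7, 4, seed = 21)
  ms <- mean_squares(g)
  shifted <- icc_data(g$values + 17.3, g$design)
  ms_s <- mean_squares(shifted)
  expect_equal(ms_s$ms_subject, ms$ms_subject)
  expect_equal(ms_s$ms_error, ms$ms_error)
  scaled <- icc_data(3 * g$values, g$design)
  ms_c <- mean_squares(scaled)
  expect_equal(ms_c$ms_subject, 9 * ms$ms_subject)
  expect_equal(ms_c$ms_rater, 9 * ms$ms_rater)
  expect_equal(ms_c$ms_error, 9 * ms$ms_error)
  # ICC point estimates are unchanged by rescaling
  expect_equal(icc_b(ms_c), icc_b(ms))
  expect_equal(icc_w(ms_c), icc_w(ms))
})

test_that("EMS inversion recovers variance components with truncation", {
  vc <- variance_components(agreement_study_summary())
  expect_equal(vc$sigma2_b, 9.4664, tolerance = 1e-6)
  expect_equal(vc$sigma2_l, 0.151167, tolerance = 1e-5)
  expect_equal(vc$sigma2_e, 0.786)

  eq <- variance_components(anova_summary(2, 2, 2, icc_design(4, 3)))
  expect_equal(c(eq$sigma2_b, eq$sigma2_l, eq$sigma2_e), c(0, 0, 2))

  tr <- variance_components(anova_summary(0.5, 3, 1, icc_design(4, 3)))
  expect_equal(tr$sigma2_b, 0)
  expect_lt(tr$raw["sigma2_b"], 0) # untruncated value retained
})

test_that("ICC point estimates match the published study and edge cases", {
  s <- agreement_study_summary()
  expect_equal(round(icc_b(s), 4), 0.9099)
  expect_equal(round(icc_w(s), 4), 0.9244)

  expect_equal(icc_b(var_comp(2.5, 0, 0)), 1)
  expect_equal(icc_b(var_comp(0, 1.2, 0.4)), 0)
  expect_equal(icc_w(var_comp(0.3, 0.7, 0)), 1)
  expect_equal(icc_w(var_comp(0.70, 0.29, 0.01)), 0.99)
  expect_error(icc_b(var_comp(0, 0, 0)), "undefined")
})

test_that("icc_w >= icc_b for every variance-component triple", {
  set.seed(99)
  for (i in 1:50) {
    vc <- var_comp(runif(1), runif(1), runif(1))
    expect_gte(icc_w(vc), icc_b(vc))
  }
})

test_that("invalid designs and unbalanced grids are rejected", {
  expect_error(icc_design(1, 3), "b0")
  expect_error(icc_design(3, 1), "l0")
  expect_error(icc_design(3, 3, 0), "r0")
  expect_error(icc_data(array(1, dim = c(2, 2, 1)),
                        icc_design(3, 2, 1)), "balance")
  bad <- matrix(1:4, 2, 2); bad[1, 1] <- NA
  expect_error(icc_data(bad), "balance")
})
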