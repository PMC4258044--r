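test_that("HPD equals the exhaustive shortest-window search", {
  x <- c(0.1, 0.2, 0.21, 0.22, 0.9)
  ci <- hpd_interval(x, level = 0.6, min_draws = 1)
  expect_equal(c(ci$lower, ci$upper), c(0.20, 0.22))

  set.seed(14)
  for (i in 1:20) {
    draws <- runif(40 + i)^2
    lv <- sample(c(0.5, 0.8, 0.95), 1)
    ci <- hpd_interval(draws, level = lv, min_draws = 1)
    expect_equal(c(ci$lower, ci$upper), hpd_brute_force(draws, lv))
  }

  deg <- hpd_interval(rep(0.6, 50), level = 0.95, min_draws = 1)
  expect_equal(c(deg$lower, deg$upper), c(0.6, 0.6))
  full <- hpd_interval(c(0.2, 0.5, 0.9), level = 1, min_draws = 1)
  expect_equal(c(full$lower, full$upper), c(0.2, 0.9))
  expect_error(hpd_interval(numeric(0)), "empty")
  expect_error(hpd_interval(runif(10)), "min_draws")
})

test_that("HPD interval is never wider than the equal-tailed interval", {
  sc <- scenario_spec(icc_design(24, 4), 0.6, 0.8)
  post <- fit_posterior(generate_data(sc, seed = 3), seed = 4)
  h <- hpd_interval(post)
  e <- equal_tail_interval(post)
  expect_lte(interval_width(h), interval_width(e) + 1e-12)
  set.seed(5)
  for (lv in c(0.5, 0.9)) {
    x <- rbeta(2000, 2, 5)
    expect_lte(interval_width(hpd_interval(x, lv)),
               interval_width(equal_tail_interval(x, lv)) + 1e-12)
  }
})

test_that("posterior recovers simulation parameters", {
  sc <- scenario_spec(icc_design(96, 6), 0.70, 0.80)
  g <- generate_data(sc, seed = 8)
  post <- fit_posterior(g, n_iter = 23000, burnin = 3000, thin = 20,
                        seed = 9)
  expect_equal(stats::median(post$draws$rho_b), 0.70, tolerance = 0.10)
  # location recovery: posterior mean of mu close to the grand mean
  mu_draws <- post$draws$mu
  expect_lt(abs(mean(mu_draws) - mean(g$values)), 2 * stats::sd(mu_draws))
  expect_true(all(post$draws$rho_b > 0 & post$draws$rho_b < 1))
  expect_true(all(post$draws$sigma2_e > 0))
})

test_that("chains are seed-reproducible and rho is scale invariant", {
  sc <- scenario_spec(icc_design(20, 4), 0.6, 0.8)
  g <- generate_data(sc, seed = 10)
  p1 <- fit_posterior(g, n_iter = 4000, burnin = 1000, thin = 3, seed = 11)
  p2 <- fit_posterior(g, n_iter = 4000, burnin = 1000, thin = 3, seed = 11)
  expect_identical(p1$draws$rho_b, p2$draws$rho_b)

  g10 <- icc_data(10 * g$values, g$design)
  p10 <- fit_posterior(g10, n_iter = 4000, burnin = 1000, thin = 3,
                       seed = 11)
  # the Gibbs chain is exactly scale equivariant, so the ICC draws match
  expect_equal(p10$draws$rho_b, p1$draws$rho_b, tolerance = 1e-9)
  expect_equal(p10$draws$sigma2_e, 100 * p1$draws$sigma2_e,
               tolerance = 1e-6)
})

test_that("a two-rater design triggers the propriety warning", {
  sc <- scenario_spec(icc_design(12, 2), 0.6, 0.8)
  g <- generate_data(sc, seed = 12)
  expect_warning(fit_posterior(g, n_iter = 2000, burnin = 500, thin = 1,
                               seed = 13), "propriety")
})

test_that("the Gibbs posterior matches an independent JAGS fit", {
  # moderately identified design so both samplers mix well
  sc <- scenario_spec(icc_design(16, 4), 0.5, 0.8)
  g <- generate_data(sc, seed = 15)
  post <- fit_posterior(g, n_iter = 43000, burnin = 3000, thin = 10,
                        seed = 16)

  library(rjags)
  model_str <- "model{
    for (b in 1:B) { for (l in 1:L) {
      y[b, l] ~ dnorm(mu + eb[b] + el[l], tau_e)
    }}
    for (b in 1:B) { eb[b] ~ dnorm(0, tau_b) }
    for (l in 1:L) { el[l] ~ dnorm(0, tau_l) }
    mu ~ dnorm(0, 1e-8)
    sb ~ dunif(0, 1e3); sl ~ dunif(0, 1e3); se ~ dunif(0, 1e3)
    tau_b <- 1/(sb*sb); tau_l <- 1/(sl*sl); tau_e <- 1/(se*se)
    rho <- sb*sb / (sb*sb + sl*sl + se*se)
  }"
  y <- g$values[, , 1]
  inits <- list(sb = sd(y), sl = sd(y) / 2, se = sd(y) / 2, mu = mean(y),
                .RNG.name = "base::Mersenne-Twister", .RNG.seed = 17)
  jm <- jags.model(textConnection(model_str),
                   data = list(y = y, B = nrow(y), L = ncol(y)),
                   inits = inits, n.chains = 1, quiet = TRUE)
  update(jm, 5000)
  samp <- coda.samples(jm, "rho", 40000, thin = 10)
  rho_jags <- as.numeric(samp[[1]])

  q_mine <- stats::quantile(post$draws$rho_b, c(0.1, 0.5, 0.9))
  q_jags <- stats::quantile(rho_jags, c(0.1, 0.5, 0.9))
  expect_equal(unname(q_mine), unname(q_jags), tolerance = 0.06)
})
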