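#' Prior specification for the Bayesian interval
#'
#' Only the uniform (improper, flat) prior on the three standard
#' deviations is supported; it is scale-invariant on the ICC and free of
#' user-chosen hyperparameters, which is why it is the package default.
#'
#' @param family Prior family tag; currently `"uniform_sd"`.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(family = "uniform_sd") {
  family <- match.arg(family, "uniform_sd")
  structure(list(family = family), class = "prior_spec")
}

#' Posterior sample for the two-way random-effects model
#'
#' Draws from the joint posterior of `(mu, sigma_b, sigma_l, sigma_e)`
#' under the additive two-way model and a flat prior on the standard
#' deviations, using a conjugate-block Gibbs sampler (normal full
#' conditionals for the mean and the effect blocks; inverse-gamma with
#' shape `(m - 1)/2` and rate `S/2` for each variance, `m` effects with
#' sum of squares `S`). The between-subject ICC `rho_b` is attached per
#' retained draw.
#'
#' With fewer than 3 rater levels the rater-variance conditional is
#' extremely heavy tailed and the posterior borders on impropriety; a
#' warning is emitted.
#'
#' @param data An [icc_data()] grid (raw data are required; mean squares
#'   alone do not determine the likelihood).
#' @param prior A [prior_spec()].
#' @param n_iter,burnin,thin Chain length, burn-in and thinning. Defaults
#'   13000/3000/10 (1000 retained draws), suitable for simulation
#'   campaigns; use e.g. 100000/10000/10 for a single-dataset analysis.
#' @param seed Optional integer seed.
#'
#' @return An `icc_posterior` object: data frame `draws` with columns
#'   `mu`, `sigma2_b`, `sigma2_l`, `sigma2_e`, `rho_b`, plus settings and
#'   diagnostics in `meta` (effective sample size of `rho_b`; a
#'   `convergence_warning` flag when it falls below 100).
#' @seealso [hpd_interval()], [bayes_interval()]
#' @export
fit_posterior <- function(data, prior = prior_spec(), n_iter = 13000,
                          burnin = 3000, thin = 10, seed = NULL) {
  if (!is_icc_data(data)) stop("'data' must be an icc_data grid",
                               call. = FALSE)
  if (!inherits(prior, "prior_spec")) stop("'prior' must be a prior_spec",
                                           call. = FALSE)
  n_iter <- as.integer(n_iter); burnin <- as.integer(burnin)
  thin <- as.integer(thin)
  if (n_iter <= burnin) stop("'n_iter' must exceed 'burnin'", call. = FALSE)
  if (thin < 1L) stop("'thin' must be >= 1", call. = FALSE)
  d <- data$design
  if (d$l0 < 3L)
    warning("posterior propriety is fragile with fewer than 3 rater ",
            "levels under the flat-on-sd prior; interpret with care")
  if (!is.null(seed)) set.seed(seed)

  cell_means <- apply(data$values, c(1L, 2L), mean)
  ss_within <- sum((data$values -
                      array(cell_means, dim(data$values)))^2)
  vc <- variance_components(mean_squares(data))
  tot <- vc$sigma2_b + vc$sigma2_l + vc$sigma2_e
  if (tot <= 0)
    stop("numerical error: data grid is constant; posterior is degenerate",
         call. = FALSE)
  floor_ <- 1e-8 * tot
  draws <- gibbs_vc(cell_means, ss_within, d$r0, n_iter, burnin, thin,
                    max(vc$sigma2_b, floor_), max(vc$sigma2_l, floor_),
                    max(vc$sigma2_e, floor_))
  if (nrow(draws) < 1L) stop("no retained draws", call. = FALSE)
  if (!all(is.finite(draws)))
    stop("numerical error: non-finite values in the chain", call. = FALSE)
  df <- data.frame(mu = draws[, 1L], sigma2_b = draws[, 2L],
                   sigma2_l = draws[, 3L], sigma2_e = draws[, 4L])
  df$rho_b <- df$sigma2_b / (df$sigma2_b + df$sigma2_l + df$sigma2_e)
  ess <- ess_acf(df$rho_b)
  structure(
    list(draws = df, n_iter = n_iter, burnin = burnin, thin = thin,
         seed = seed, design = d,
         meta = list(ess_rho = ess, convergence_warning = ess < 100)),
    class = "icc_posterior")
}

# initial-sequence effective sample size from the empirical acf
ess_acf <- function(x, max_lag = min(length(x) - 1L, 100L)) {
  n <- length(x)
  if (n < 10L || stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1L]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1L] - 1L)]
  n / (1 + 2 * sum(rho))
}

#' @export
print.icc_posterior <- function(x, ...) {
  cat(sprintf("Posterior sample: %d retained draws (iter %d, burnin %d, thin %d)\n",
              nrow(x$draws), x$n_iter, x$burnin, x$thin))
  cat(sprintf("rho_b posterior median %.4f, ESS %.0f\n",
              stats::median(x$draws$rho_b), x$meta$ess_rho))
  if (isTRUE(x$meta$convergence_warning))
    cat("warning: effective sample size below 100\n")
  invisible(x)
}

#' Highest posterior density interval
#'
#' Shortest window containing `ceiling(level * n)` of the sorted draws:
#' among credible intervals of the requested mass the HPD interval is the
#' narrowest.
#'
#' @param x An `icc_posterior` (its `rho_b` draws are used) or a numeric
#'   vector of posterior draws.
#' @param level Credible level in (0, 1]; level 1 returns the sample
#'   range.
#' @param min_draws Floor on the number of draws (default 1000; lower it
#'   explicitly for toy examples).
#'
#' @return An `icc_interval` with method tag `"bayes"`.
#' @export
hpd_interval <- function(x, level = 0.95, min_draws = 1000L) {
  if (!identical(level, 1) && !identical(level, 1L)) check_level(level)
  draws <- if (inherits(x, "icc_posterior")) x$draws$rho_b else as.numeric(x)
  if (!length(draws)) stop("empty posterior sample", call. = FALSE)
  if (length(draws) < min_draws)
    stop("fewer than ", min_draws, " draws; pass 'min_draws' explicitly ",
         "to override", call. = FALSE)
  s <- sort(draws)
  n <- length(s)
  k <- ceiling(level * n)
  if (k >= n) {
    lo <- s[1L]; up <- s[n]
  } else {
    i <- which.min(s[k:n] - s[1:(n - k + 1L)])
    lo <- s[i]; up <- s[i + k - 1L]
  }
  est <- stats::median(draws)
  meta <- list(n_draws = n)
  if (inherits(x, "icc_posterior"))
    meta <- c(meta, x$meta, list(n_iter = x$n_iter, burnin = x$burnin,
                                 thin = x$thin, seed = x$seed))
  new_icc_interval("bayes", level, lo, up, estimate = est, meta = meta)
}

#' Equal-tailed credible interval from posterior draws
#'
#' @inheritParams hpd_interval
#' @return An `icc_interval` with method tag `"bayes"`.
#' @export
equal_tail_interval <- function(x, level = 0.95, min_draws = 1000L) {
  check_level(level)
  draws <- if (inherits(x, "icc_posterior")) x$draws$rho_b else as.numeric(x)
  if (!length(draws)) stop("empty posterior sample", call. = FALSE)
  if (length(draws) < min_draws)
    stop("fewer than ", min_draws, " draws; pass 'min_draws' explicitly ",
         "to override", call. = FALSE)
  alpha <- 1 - level
  q <- stats::quantile(draws, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  new_icc_interval("bayes", level, q[1L], q[2L],
                   estimate = stats::median(draws),
                   meta = list(n_draws = length(draws), type = "equal_tail"))
}

#' Noninformative-Bayes credible interval for ICC_b
#'
#' Convenience wrapper: [fit_posterior()] followed by [hpd_interval()]
#' (the default; the HPD interval is the shortest credible interval) or
#' [equal_tail_interval()].
#'
#' @inheritParams fit_posterior
#' @param level Credible level in (0, 1).
#' @param type `"hpd"` (default) or `"equal"`.
#' @return An `icc_interval` with method tag `"bayes"`.
#' @export
bayes_interval <- function(data, level = 0.95, prior = prior_spec(),
                           n_iter = 13000, burnin = 3000, thin = 10,
                           seed = NULL, type = c("hpd", "equal")) {
  type <- match.arg(type)
  post <- fit_posterior(data, prior = prior, n_iter = n_iter,
                        burnin = burnin, thin = thin, seed = seed)
  if (type == "hpd") hpd_interval(post, level, min_draws = 1L)
  else equal_tail_interval(post, level, min_draws = 1L)
}
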