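#' Monte Carlo draws of the generalized pivotal quantity for ICC_b
#'
#' The between-subject ICC admits no ordinary pivot, but conditional on the
#' observed mean squares the quantities `SS_i / sigma2(EMS_i)` are
#' independent chi-squared variables. Substituting independent
#' `W_1 ~ chi2(df_subject)`, `W_2 ~ chi2(df_rater)`,
#' `W_3 ~ chi2(df_error)` into the expected-mean-square inversion gives
#' generalized pivots for the three variance components,
#' \deqn{G_b = (df_1 MS_1/W_1 - df_3 MS_3/W_3) / (l_0 r_0),}
#' \deqn{G_l = (df_2 MS_2/W_2 - df_3 MS_3/W_3) / (b_0 r_0),}
#' \deqn{G_e = df_3 MS_3/W_3,}
#' and the ICC pivot `G = G_b / (G_b + G_l + G_e)`. Component pivots that
#' go negative are clamped at zero before the ratio is formed, so every
#' draw lies in `[0, 1]` (the error pivot is strictly positive, so the
#' denominator never vanishes).
#'
#' @param summary An `icc_anova` object ([mean_squares()] or
#'   [anova_summary()]).
#' @param n_draws Number of Monte Carlo triples (default 100000; at least
#'   1000).
#' @param seed Optional integer seed giving a reproducible stream; when
#'   `NULL` the ambient RNG stream is used.
#'
#' @return An `icc_pivot_draws` object with the numeric vector `g`, the
#'   draw count and the seed.
#' @seealso [gci_interval()]
#' @export
draw_pivot <- function(summary, n_draws = 1e5, seed = NULL) {
  if (!is_icc_anova(summary)) stop("'summary' must be an icc_anova",
                                   call. = FALSE)
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 1000L)
    stop("'n_draws' must be at least 1000", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  w1 <- stats::rchisq(n_draws, summary$df_subject)
  w2 <- stats::rchisq(n_draws, summary$df_rater)
  w3 <- stats::rchisq(n_draws, summary$df_error)
  g <- pivot_transform(summary, w1, w2, w3)
  structure(list(g = g, n_draws = n_draws, seed = seed,
                 design = summary$design),
            class = "icc_pivot_draws")
}

# Deterministic map from chi-squared triples to ICC pivot values; separated
# from the RNG so the W/df concentration limit can be checked directly.
pivot_transform <- function(summary, w1, w2, w3) {
  d <- summary$design
  g_e <- summary$df_error * summary$ms_error / w3
  g_b <- (summary$df_subject * summary$ms_subject / w1 - g_e) / (d$l0 * d$r0)
  g_l <- (summary$df_rater * summary$ms_rater / w2 - g_e) / (d$b0 * d$r0)
  g_b <- pmax(g_b, 0)
  g_l <- pmax(g_l, 0)
  g_b / (g_b + g_l + g_e)
}

#' @export
print.icc_pivot_draws <- function(x, ...) {
  cat(sprintf("Generalized pivot sample for ICC_b: %d draws\n", x$n_draws))
  print(summary(x$g))
  invisible(x)
}

#' Generalized confidence interval for ICC_b
#'
#' Equal-tailed interval whose endpoints are the `alpha/2` and
#' `1 - alpha/2` empirical quantiles (order statistics with linear
#' interpolation) of the generalized pivot sample drawn by
#' [draw_pivot()]. The interval depends on the data only through the three
#' observed mean squares, and is invariant to rescaling them.
#'
#' @inheritParams draw_pivot
#' @param level Nominal confidence level in (0, 1); default 0.95.
#'
#' @return An `icc_interval` with method tag `"gci"`.
#' @examples
#' s <- anova_summary(95.450, 4.414, 0.786, icc_design(24, 10))
#' gci_interval(s, n_draws = 20000, seed = 1)
#' @export
gci_interval <- function(summary, level = 0.95, n_draws = 1e5, seed = NULL) {
  check_level(level)
  piv <- draw_pivot(summary, n_draws = n_draws, seed = seed)
  alpha <- 1 - level
  q <- stats::quantile(piv$g, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                       type = 7)
  new_icc_interval("gci", level, q[1L], q[2L],
                   estimate = icc_b(summary),
                   meta = list(n_draws = piv$n_draws, seed = seed))
}
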