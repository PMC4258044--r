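#' Variance components matching target ICC values
#'
#' Inverts the ICC definitions at a given total variance:
#' `sigma2_b = icc_b * T`, `sigma2_l = (icc_w - icc_b) * T`,
#' `sigma2_e = (1 - icc_w) * T`. Because both ICCs are scale invariant the
#' default total of 1 loses no generality for coverage studies.
#'
#' @param icc_b Target between-subject ICC, in (0, 1].
#' @param icc_w Target within-rater ICC, with `icc_b <= icc_w < 1`.
#' @param total_variance Total variance `T > 0` (default 1).
#' @return An `icc_varcomp`.
#' @examples
#' solve_variance_components(0.70, 0.99) # (0.70, 0.29, 0.01)
#' @export
solve_variance_components <- function(icc_b, icc_w, total_variance = 1) {
  if (!is.numeric(icc_b) || icc_b <= 0 || icc_b > 1)
    stop("'icc_b' must be in (0, 1]", call. = FALSE)
  if (!is.numeric(icc_w) || icc_w >= 1)
    stop("'icc_w' must be < 1", call. = FALSE)
  if (icc_w < icc_b)
    stop("infeasible target: icc_w < icc_b", call. = FALSE)
  if (total_variance <= 0) stop("'total_variance' must be > 0",
                                call. = FALSE)
  var_comp(icc_b * total_variance,
           (icc_w - icc_b) * total_variance,
           (1 - icc_w) * total_variance)
}

#' Simulation scenario for the balanced two-way model
#'
#' Bundles a design, target ICC values and an effect/error distribution
#' family. All four families are centred and moment matched: each random
#' term has mean 0 and exactly the variance implied by the targets, so the
#' true ICCs are identical across families and only the distribution shape
#' changes.
#'
#' @param design An [icc_design()].
#' @param icc_b,icc_w Target ICCs (see [solve_variance_components()]).
#' @param family `"normal"`, `"uniform"`, `"mixture"` (bimodal two-point
#'   normal mixture) or `"gamma"` (mean-shifted gamma).
#' @param alpha Gamma shape (gamma family only); 3 gives skewness
#'   `2/sqrt(3) = 1.15` and kurtosis 5, 10 gives 0.63 and 3.6.
#' @param mu Overall mean (default 0).
#' @param total_variance Total variance (default 1).
#' @return An `icc_scenario` object (includes the solved `components`).
#' @export
scenario_spec <- function(design, icc_b, icc_w,
                          family = c("normal", "uniform", "mixture",
                                     "gamma"),
                          alpha = 3, mu = 0, total_variance = 1) {
  if (!is_icc_design(design)) stop("'design' must be an icc_design",
                                   call. = FALSE)
  family <- match.arg(family)
  if (family == "gamma" && (!is.numeric(alpha) || alpha <= 0))
    stop("gamma 'alpha' must be positive", call. = FALSE)
  comps <- solve_variance_components(icc_b, icc_w, total_variance)
  structure(list(design = design, icc_b = icc_b, icc_w = icc_w,
                 family = family, alpha = alpha, mu = mu,
                 total_variance = total_variance, components = comps),
            class = "icc_scenario")
}

#' @export
print.icc_scenario <- function(x, ...) {
  cat(sprintf(
    "Scenario: %s family, b0=%d l0=%d r0=%d, ICC_b=%.2f ICC_w=%.2f\n",
    x$family, x$design$b0, x$design$l0, x$design$r0, x$icc_b, x$icc_w))
  if (x$family == "gamma") cat(sprintf("gamma shape alpha = %g\n", x$alpha))
  invisible(x)
}

#' Draw one centred random term
#'
#' Workhorse behind [generate_data()], exposed for moment checking. Every
#' family is centred at 0 with variance `sigma2`:
#' uniform on `[-A, A]` with `A = sqrt(3 sigma2)`; two-point normal
#' mixture with means `+/- m`, sd `m/3`, weights 1/2 and
#' `m = 3 sqrt(sigma2/10)`; mean-shifted gamma
#' `w = G - alpha * theta` with `G ~ Gamma(alpha, scale theta)` and
#' `theta = sqrt(sigma2/alpha)`.
#'
#' @param n Number of draws.
#' @param sigma2 Target variance (0 gives exact zeros).
#' @param family Distribution family tag.
#' @param alpha Gamma shape.
#' @return Numeric vector of length `n`.
#' @export
draw_effect <- function(n, sigma2, family = "normal", alpha = 3) {
  if (sigma2 < 0) stop("'sigma2' must be >= 0", call. = FALSE)
  if (sigma2 == 0) return(numeric(n))
  switch(family,
    normal = stats::rnorm(n, 0, sqrt(sigma2)),
    uniform = {
      A <- sqrt(3 * sigma2)
      stats::runif(n, -A, A)
    },
    mixture = {
      m <- 3 * sqrt(sigma2 / 10)
      sgn <- ifelse(stats::runif(n) < 0.5, -1, 1)
      stats::rnorm(n, sgn * m, m / 3)
    },
    gamma = {
      theta <- sqrt(sigma2 / alpha)
      stats::rgamma(n, shape = alpha, scale = theta) - alpha * theta
    },
    stop("unknown family: ", family, call. = FALSE))
}

#' Theoretical moments of the effect families
#'
#' Closed-form mean, variance, skewness and excess-free kurtosis of
#' [draw_effect()] draws: used for moment-matching checks and for reading
#' off how severe a normality violation each family represents.
#'
#' @inheritParams draw_effect
#' @return A list with `mean`, `variance`, `skewness`, `kurtosis`.
#' @examples
#' effect_moments(1, "gamma", alpha = 3) # skewness 1.15, kurtosis 5
#' @export
effect_moments <- function(sigma2, family = "normal", alpha = 3) {
  base <- list(mean = 0, variance = sigma2)
  shape <- switch(family,
    normal = c(0, 3),
    uniform = c(0, 9 / 5),
    mixture = {
      # X = c*m + N(0, (m/3)^2): E X^4 = m^4 (1 + 6/9 + 3/81)
      c(0, (1 + 6 / 9 + 3 / 81) / (10 / 9)^2)
    },
    gamma = c(2 / sqrt(alpha), 3 + 6 / alpha),
    stop("unknown family: ", family, call. = FALSE))
  c(base, list(skewness = shape[1L], kurtosis = shape[2L]))
}

#' Generate a balanced two-way dataset
#'
#' Simulates `y_blr = mu + B_b + L_l + e_blr` with the three random terms
#' drawn independently from the scenario's family, each moment matched to
#' its solved variance component. When a seed is supplied each term uses
#' its own derived RNG substream, so (for example) changing the replicate
#' count does not perturb the subject or rater draws.
#'
#' @param scenario An [scenario_spec()].
#' @param seed Optional integer seed.
#' @return An [icc_data()] grid.
#' @export
generate_data <- function(scenario, seed = NULL) {
  if (!inherits(scenario, "icc_scenario"))
    stop("'scenario' must be an icc_scenario", call. = FALSE)
  d <- scenario$design
  vc <- scenario$components
  if (!is.null(seed)) {
    set.seed(seed)
    sub_seeds <- sample.int(.Machine$integer.max - 1L, 3L)
    term <- function(i, n, s2) {
      set.seed(sub_seeds[i])
      draw_effect(n, s2, scenario$family, scenario$alpha)
    }
  } else {
    term <- function(i, n, s2) draw_effect(n, s2, scenario$family,
                                           scenario$alpha)
  }
  B <- term(1L, d$b0, vc$sigma2_b)
  L <- term(2L, d$l0, vc$sigma2_l)
  e <- term(3L, d$b0 * d$l0 * d$r0, vc$sigma2_e)
  y <- scenario$mu +
    array(rep(B, times = d$l0 * d$r0), dim = c(d$b0, d$l0, d$r0)) +
    array(rep(rep(L, each = d$b0), times = d$r0),
          dim = c(d$b0, d$l0, d$r0)) +
    array(e, dim = c(d$b0, d$l0, d$r0))
  icc_data(y, d)
}
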