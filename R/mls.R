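#' Quantile constants for the modified large sample interval
#'
#' The MLS limits adjust the large-sample limits for a ratio of variance
#' components so that the interval is exact whenever all but one component
#' vanishes. The adjustment is carried by constants derived solely from
#' the confidence level and the three ANOVA degrees of freedom: per tail,
#' a `G`/`H` constant for each mean square
#' (`G = 1 - df/chi2_upper`, `H = df/chi2_lower - 1`, the exact
#' single-component corrections) and a cross-product constant for each
#' (subject, other) mean-square pair built from central F quantiles.
#'
#' @param level Two-sided confidence level in (0, 1); each tail uses
#'   `alpha/2 = (1 - level)/2`.
#' @param summary An `icc_anova` (only its degrees of freedom are used).
#'
#' @return An `mls_constants` object with `lower` and `upper` constant
#'   sets.
#' @seealso [mls_interval()]
#' @export
mls_constants <- function(level, summary) {
  check_level(level)
  if (!is_icc_anova(summary)) stop("'summary' must be an icc_anova",
                                   call. = FALSE)
  a <- (1 - level) / 2
  n1 <- summary$df_subject; n2 <- summary$df_rater; n3 <- summary$df_error
  # upper-tail F quantiles: Fu(p, d1, d2) has probability p to its right
  Fu <- function(p, d1, d2) stats::qf(1 - p, d1, d2)
  G <- function(df) 1 - 1 / Fu(a, df, Inf)
  H <- function(df) 1 / Fu(1 - a, df, Inf) - 1
  cross_low <- function(df1, df2, g1, h2) {
    f <- Fu(a, df1, df2)
    ((f - 1)^2 - g1^2 * f^2 - h2^2) / f
  }
  cross_up <- function(df1, df2, h1, g2) {
    f <- Fu(1 - a, df1, df2)
    ((1 - f)^2 - h1^2 * f^2 - g2^2) / f
  }
  lower <- list(g1 = G(n1), h2 = H(n2), h3 = H(n3))
  lower$g12 <- cross_low(n1, n2, lower$g1, lower$h2)
  lower$g13 <- cross_low(n1, n3, lower$g1, lower$h3)
  upper <- list(h1 = H(n1), g2 = G(n2), g3 = G(n3))
  upper$h12 <- cross_up(n1, n2, upper$h1, upper$g2)
  upper$h13 <- cross_up(n1, n3, upper$h1, upper$g3)
  structure(list(level = level,
                 df = c(subject = n1, rater = n2, error = n3),
                 lower = lower, upper = upper),
            class = "mls_constants")
}

#' @export
print.mls_constants <- function(x, ...) {
  cat(sprintf("MLS constants at level %.3f, df (%d, %d, %d)\n", x$level,
              x$df[1L], x$df[2L], x$df[3L]))
  cat("lower tail:\n"); print(unlist(x$lower), digits = 5)
  cat("upper tail:\n"); print(unlist(x$upper), digits = 5)
  invisible(x)
}

# One MLS bound for rho = (t1 - t3) / (t1 + cc*t2 + dd*t3), where t are the
# expected mean squares. A candidate bound x satisfies rho >= x iff
# delta(x) = (1-x) t1 - cc x t2 - (1+dd x) t3 >= 0; the bound is the root of
# [MLS bound of delta(x)] = 0, which squares to a quadratic in x.
mls_root <- function(s1, s2, s3, cc, dd, k, upper) {
  # k: list with per-mean-square constants (c1sq, c2sq, c3sq) and cross
  # terms (x12, x13) already oriented for the requested tail
  nhat <- s1 - s3
  dhat <- s1 + cc * s2 + dd * s3
  A <- dhat^2 - (k$c1sq * s1^2 + cc^2 * k$c2sq * s2^2 +
                 dd^2 * k$c3sq * s3^2 - cc * k$x12 * s1 * s2 -
                 dd * k$x13 * s1 * s3)
  B <- -2 * nhat * dhat - (-2 * k$c1sq * s1^2 + 2 * dd * k$c3sq * s3^2 +
                           cc * k$x12 * s1 * s2 +
                           (dd - 1) * k$x13 * s1 * s3)
  C <- nhat^2 - (k$c1sq * s1^2 + k$c3sq * s3^2 + k$x13 * s1 * s3)
  rho_hat <- nhat / dhat
  roots <- if (abs(A) < 1e-12 * dhat^2) {
    if (abs(B) < 1e-300) numeric(0) else -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) numeric(0)
    else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  # the valid root sits on the delta(x) = +sqrt / -sqrt branch, i.e. on the
  # correct side of the point estimate
  tol <- 1e-10
  roots <- if (upper) roots[roots >= rho_hat - tol]
           else roots[roots <= rho_hat + tol]
  if (!length(roots)) return(if (upper) 1 else 0)
  if (upper) min(roots) else max(roots)
}

#' Modified large sample confidence interval for ICC_b
#'
#' Closed-form equal-tailed limits for the between-subject ICC, obtained by
#' applying the modified-large-sample bound to the linear combination of
#' expected mean squares whose sign determines whether the ICC exceeds a
#' candidate value, and solving the resulting quadratic. Deterministic,
#' scale-invariant in the mean squares, and exact in the limits where all
#' but one variance component is zero. Raw limits outside `[0, 1]` are
#' clipped; the pre-clip values are kept in `$meta$pre_clip`.
#'
#' @param summary An `icc_anova` object.
#' @param level Confidence level in (0, 1); default 0.95.
#'
#' @return An `icc_interval` with method tag `"mls"`.
#' @examples
#' s <- anova_summary(95.450, 4.414, 0.786, icc_design(24, 10))
#' mls_interval(s)
#' @export
mls_interval <- function(summary, level = 0.95) {
  check_level(level)
  if (!is_icc_anova(summary)) stop("'summary' must be an icc_anova",
                                   call. = FALSE)
  s1 <- summary$ms_subject; s2 <- summary$ms_rater; s3 <- summary$ms_error
  if (s1 + s2 + s3 <= 0)
    stop("undefined ICC: all mean squares are zero", call. = FALSE)
  d <- summary$design
  cc <- d$l0 / d$b0                       # weight of MS_rater in the total
  dd <- d$l0 * d$r0 - 1 - cc              # weight of MS_error in the total
  kc <- mls_constants(level, summary)
  lo <- mls_root(s1, s2, s3, cc, dd,
                 list(c1sq = kc$lower$g1^2, c2sq = kc$lower$h2^2,
                      c3sq = kc$lower$h3^2, x12 = kc$lower$g12,
                      x13 = kc$lower$g13), upper = FALSE)
  up <- mls_root(s1, s2, s3, cc, dd,
                 list(c1sq = kc$upper$h1^2, c2sq = kc$upper$g2^2,
                      c3sq = kc$upper$g3^2, x12 = kc$upper$h12,
                      x13 = kc$upper$h13), upper = TRUE)
  new_icc_interval("mls", level, lo, up, estimate = icc_b(summary),
                   meta = list(pre_clip = c(lower = lo, upper = up)))
}
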