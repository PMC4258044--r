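#' Balanced two-way ANOVA mean squares
#'
#' Decomposes a balanced crossed grid into the classical subject, rater and
#' error sums of squares for the additive (no-interaction) model
#' `y_blr = mu + B_b + L_l + e_blr` and divides by their degrees of
#' freedom. With one replicate per cell the error line is the
#' interaction/residual line of the saturated additive fit.
#'
#' @param data An [icc_data()] grid.
#'
#' @return An `icc_anova` object: mean squares (`ms_subject`, `ms_rater`,
#'   `ms_error`), sums of squares (`ss_*`), degrees of freedom (`df_*`) and
#'   the design.
#' @examples
#' g <- icc_data(matrix(c(1, 3, 2, 5), 2, 2))
#' mean_squares(g) # MS 6.25 / 2.25 / 0.25
#' @export
mean_squares <- function(data) {
  if (!is_icc_data(data)) stop("'data' must be an icc_data grid",
                               call. = FALSE)
  d <- data$design
  y <- data$values
  g <- mean(y)
  sub_means <- apply(y, 1L, mean)
  rat_means <- apply(y, 2L, mean)
  ss_subject <- d$l0 * d$r0 * sum((sub_means - g)^2)
  ss_rater <- d$b0 * d$r0 * sum((rat_means - g)^2)
  ss_total <- sum((y - g)^2)
  ss_error <- ss_total - ss_subject - ss_rater
  # guard against tiny negative round-off on constant grids
  ss_error <- max(ss_error, 0)
  structure(
    list(ms_subject = ss_subject / d$df_subject,
         ms_rater = ss_rater / d$df_rater,
         ms_error = ss_error / d$df_error,
         ss_subject = ss_subject, ss_rater = ss_rater, ss_error = ss_error,
         df_subject = d$df_subject, df_rater = d$df_rater,
         df_error = d$df_error,
         design = d),
    class = "icc_anova")
}

#' ANOVA summary from published mean squares
#'
#' Builds the `icc_anova` object that the interval methods consume directly
#' from a printed ANOVA table (three observed mean squares plus the
#' design), the workflow used when only summary statistics are available.
#'
#' @param ms_subject,ms_rater,ms_error Observed mean squares, all
#'   non-negative.
#' @param design An [icc_design()].
#'
#' @return An `icc_anova` object (sums of squares are reconstructed as
#'   `MS * df`).
#' @examples
#' # ANOVA table of a 24-subject x 10-rater agreement study
#' anova_summary(95.450, 4.414, 0.786, icc_design(24, 10))
#' @export
anova_summary <- function(ms_subject, ms_rater, ms_error, design) {
  if (!is_icc_design(design)) stop("'design' must be an icc_design",
                                   call. = FALSE)
  ms <- c(ms_subject, ms_rater, ms_error)
  if (length(ms) != 3L || !all(is.finite(ms)) || any(ms < 0))
    stop("mean squares must be three finite non-negative numbers",
         call. = FALSE)
  structure(
    list(ms_subject = ms_subject, ms_rater = ms_rater, ms_error = ms_error,
         ss_subject = ms_subject * design$df_subject,
         ss_rater = ms_rater * design$df_rater,
         ss_error = ms_error * design$df_error,
         df_subject = design$df_subject, df_rater = design$df_rater,
         df_error = design$df_error,
         design = design),
    class = "icc_anova")
}

is_icc_anova <- function(x) inherits(x, "icc_anova")

#' @export
print.icc_anova <- function(x, ...) {
  tab <- data.frame(
    Df = c(x$df_subject, x$df_rater, x$df_error),
    `Sum Sq` = c(x$ss_subject, x$ss_rater, x$ss_error),
    `Mean Sq` = c(x$ms_subject, x$ms_rater, x$ms_error),
    row.names = c("Subject", "Rater", "Error"), check.names = FALSE)
  cat("Balanced two-way ANOVA (no interaction)\n")
  print(tab, digits = 6)
  invisible(x)
}

#' Method-of-moments variance components
#'
#' Inverts the expected-mean-square relations
#' `E(MS_subject) = sigma2_e + l0*r0*sigma2_b`,
#' `E(MS_rater)   = sigma2_e + b0*r0*sigma2_l`,
#' `E(MS_error)   = sigma2_e`. Negative solutions for `sigma2_b` and
#' `sigma2_l` are truncated at zero so that ICC point estimates stay in
#' `[0, 1]`; the untruncated values are kept in `$raw` because the interval
#' methods operate on the observed mean squares, not on truncated
#' components.
#'
#' @param x An `icc_anova` object.
#'
#' @return An `icc_varcomp` object with `sigma2_b`, `sigma2_l`, `sigma2_e`
#'   and the untruncated estimates in `raw`.
#' @export
variance_components <- function(x) {
  if (!is_icc_anova(x)) stop("'x' must be an icc_anova", call. = FALSE)
  d <- x$design
  raw_b <- (x$ms_subject - x$ms_error) / (d$l0 * d$r0)
  raw_l <- (x$ms_rater - x$ms_error) / (d$b0 * d$r0)
  var_comp(max(0, raw_b), max(0, raw_l), x$ms_error,
           raw = c(sigma2_b = raw_b, sigma2_l = raw_l,
                   sigma2_e = x$ms_error))
}

#' Variance-component triple
#'
#' Container for `(sigma2_b, sigma2_l, sigma2_e)`: the between-subject,
#' between-rater and error variances of the additive two-way model. Used
#' both for method-of-moments estimates and for true simulation values.
#'
#' @param sigma2_b,sigma2_l,sigma2_e Non-negative variances.
#' @param raw Optional untruncated estimates (kept by
#'   [variance_components()]).
#' @return An `icc_varcomp` object.
#' @export
var_comp <- function(sigma2_b, sigma2_l, sigma2_e, raw = NULL) {
  v <- c(sigma2_b, sigma2_l, sigma2_e)
  if (length(v) != 3L || !all(is.finite(v)) || any(v < 0))
    stop("variance components must be three finite non-negative numbers",
         call. = FALSE)
  structure(list(sigma2_b = sigma2_b, sigma2_l = sigma2_l,
                 sigma2_e = sigma2_e, raw = raw),
            class = "icc_varcomp")
}

is_icc_varcomp <- function(x) inherits(x, "icc_varcomp")

#' @export
print.icc_varcomp <- function(x, ...) {
  cat("Variance components:\n")
  print(c(sigma2_b = x$sigma2_b, sigma2_l = x$sigma2_l,
          sigma2_e = x$sigma2_e), digits = 6)
  invisible(x)
}

as_varcomp <- function(x) {
  if (is_icc_varcomp(x)) x
  else if (is_icc_anova(x)) variance_components(x)
  else if (is_icc_data(x)) variance_components(mean_squares(x))
  else stop("expected icc_varcomp, icc_anova or icc_data", call. = FALSE)
}

#' Between-subject and within-rater ICC point estimates
#'
#' `icc_b` is the proportion of total variance attributable to subjects,
#' `sigma2_b / (sigma2_b + sigma2_l + sigma2_e)`: high values mean raters
#' agree. `icc_w` is the repeatability within a single rater,
#' `(sigma2_b + sigma2_l) / (sigma2_b + sigma2_l + sigma2_e)`, and always
#' satisfies `icc_w >= icc_b`.
#'
#' @param x An `icc_varcomp`, `icc_anova` or `icc_data` object.
#' @return A single value in `[0, 1]`.
#' @examples
#' vc <- variance_components(
#'   anova_summary(95.450, 4.414, 0.786, icc_design(24, 10)))
#' icc_b(vc) # 0.9099
#' icc_w(vc) # 0.9244
#' @export
icc_b <- function(x) {
  vc <- as_varcomp(x)
  tot <- vc$sigma2_b + vc$sigma2_l + vc$sigma2_e
  if (tot <= 0)
    stop("undefined ICC: all variance components are zero", call. = FALSE)
  vc$sigma2_b / tot
}

#' @rdname icc_b
#' @export
icc_w <- function(x) {
  vc <- as_varcomp(x)
  tot <- vc$sigma2_b + vc$sigma2_l + vc$sigma2_e
  if (tot <= 0)
    stop("undefined ICC: all variance components are zero", call. = FALSE)
  (vc$sigma2_b + vc$sigma2_l) / tot
}
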