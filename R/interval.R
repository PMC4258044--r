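# Shared interval container used by all three methods.

new_icc_interval <- function(method, level, lower, upper, estimate = NA_real_,
                             meta = list()) {
  lower <- min(1, max(0, lower))
  upper <- min(1, max(0, upper))
  if (lower > upper) { # can only arise from round-off
    mid <- (lower + upper) / 2
    lower <- upper <- mid
  }
  structure(list(method = method, level = level, lower = lower,
                 upper = upper, estimate = estimate, meta = meta),
            class = "icc_interval")
}

is_icc_interval <- function(x) inherits(x, "icc_interval")

#' @export
print.icc_interval <- function(x, ...) {
  lab <- c(gci = "Generalized confidence interval",
           mls = "Modified large sample interval",
           bayes = "Noninformative-Bayes HPD interval",
           oracle = "Trivial [0, 1] interval")[x$method]
  if (is.na(lab)) lab <- x$method
  cat(sprintf("%s for ICC_b\n", lab))
  cat(sprintf("%.0f%% interval: (%.4f, %.4f)\n", 100 * x$level, x$lower,
              x$upper))
  if (is.finite(x$estimate))
    cat(sprintf("Point estimate: %.4f\n", x$estimate))
  invisible(x)
}

#' Interval width
#' @param x An `icc_interval`.
#' @return `upper - lower`.
#' @export
interval_width <- function(x) {
  stopifnot(is_icc_interval(x))
  x$upper - x$lower
}

check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level <= 0 || level >= 1)
    stop("'level' must be a single number in (0, 1)", call. = FALSE)
  level
}
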