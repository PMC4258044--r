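#' Balanced two-way crossed design
#'
#' Describes the layout of a balanced reproducibility study: `b0` subjects
#' (patients, biological samples, ...) each measured by all `l0` raters
#' (laboratories, devices, ...), with `r0` replicate measurements per
#' (subject, rater) cell. With `r0 = 1` the additive model is saturated and
#' the error mean square doubles as the interaction/residual mean square.
#'
#' @param b0 Number of subject levels (at least 2).
#' @param l0 Number of rater/laboratory levels (at least 2).
#' @param r0 Replicates per cell (at least 1, default 1).
#'
#' @return An object of class `icc_design` with elements `b0`, `l0`, `r0`
#'   and the three ANOVA degrees of freedom `df_subject`, `df_rater`,
#'   `df_error`.
#' @examples
#' icc_design(24, 10)
#' @export
icc_design <- function(b0, l0, r0 = 1L) {
  b0 <- as.integer(b0); l0 <- as.integer(l0); r0 <- as.integer(r0)
  if (length(b0) != 1L || is.na(b0) || b0 < 2L)
    stop("'b0' must be a single integer >= 2", call. = FALSE)
  if (length(l0) != 1L || is.na(l0) || l0 < 2L)
    stop("'l0' must be a single integer >= 2", call. = FALSE)
  if (length(r0) != 1L || is.na(r0) || r0 < 1L)
    stop("'r0' must be a single integer >= 1", call. = FALSE)
  df_error <- r0 * b0 * l0 - b0 - l0 + 1L
  if (df_error < 1L)
    stop("design error: error degrees of freedom ", df_error, " < 1",
         call. = FALSE)
  structure(
    list(b0 = b0, l0 = l0, r0 = r0,
         df_subject = b0 - 1L, df_rater = l0 - 1L, df_error = df_error),
    class = "icc_design")
}

#' @export
print.icc_design <- function(x, ...) {
  cat(sprintf(
    "Balanced two-way crossed design: %d subjects x %d raters x %d replicates\n",
    x$b0, x$l0, x$r0))
  cat(sprintf("Degrees of freedom: subject %d, rater %d, error %d\n",
              x$df_subject, x$df_rater, x$df_error))
  invisible(x)
}

is_icc_design <- function(x) inherits(x, "icc_design")

#' Measurement grid for a balanced two-way design
#'
#' Wraps the raw responses of a balanced crossed study as a
#' `b0 x l0 x r0` array. Most users will build one from a long-format
#' table via [read_icc_csv()] or [as_icc_data()], or simulate one with
#' [generate_data()].
#'
#' @param values A numeric `b0 x l0` matrix (when `r0 = 1`) or
#'   `b0 x l0 x r0` array of responses; all values must be finite.
#' @param design An [icc_design()]; inferred from `dim(values)` when
#'   omitted.
#'
#' @return An object of class `icc_data`: a list with `values` (3-d array)
#'   and `design`.
#' @export
icc_data <- function(values, design = NULL) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a b0 x l0 matrix or b0 x l0 x r0 array",
         call. = FALSE)
  if (is.null(design))
    design <- icc_design(dim(values)[1L], dim(values)[2L], dim(values)[3L])
  if (!is_icc_design(design)) stop("'design' must be an icc_design",
                                   call. = FALSE)
  if (!identical(dim(values), c(design$b0, design$l0, design$r0)))
    stop(sprintf("balance error: expected a %d x %d x %d grid, got %s",
                 design$b0, design$l0, design$r0,
                 paste(dim(values), collapse = " x ")), call. = FALSE)
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("balance error: grid contains missing or non-finite values",
         call. = FALSE)
  structure(list(values = values, design = design), class = "icc_data")
}

is_icc_data <- function(x) inherits(x, "icc_data")

#' @export
print.icc_data <- function(x, ...) {
  d <- x$design
  cat(sprintf("icc_data: %d x %d x %d balanced grid (%d observations)\n",
              d$b0, d$l0, d$r0, d$b0 * d$l0 * d$r0))
  invisible(x)
}

#' Convert a long-format table to an `icc_data` grid
#'
#' @param df A data frame with one row per measurement.
#' @param subject,rater,replicate,value Column names holding the subject
#'   label, rater label, replicate label and numeric response. The
#'   replicate column may be absent when each cell holds one measurement.
#'
#' @return An [icc_data()] grid, with subjects and raters ordered by first
#'   appearance in `df`.
#' @export
as_icc_data <- function(df, subject = "subject", rater = "rater",
                        replicate = "replicate", value = "value") {
  need <- c(subject, rater, value)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  v <- df[[value]]
  if (!is.numeric(v)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
    stop("parse error: non-numeric value in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  subj <- as.character(df[[subject]])
  rat <- as.character(df[[rater]])
  rep_ <- if (replicate %in% names(df)) as.character(df[[replicate]])
          else rep("1", nrow(df))
  su <- unique(subj); ru <- unique(rat); pu <- unique(rep_)
  b0 <- length(su); l0 <- length(ru); r0 <- length(pu)
  key <- paste(subj, rat, rep_, sep = "\r")
  full <- as.vector(outer(su, as.vector(outer(ru, pu, paste, sep = "\r")),
                          paste, sep = "\r"))
  if (anyDuplicated(key))
    stop("balance error: duplicated (subject, rater, replicate) record(s): ",
         paste(utils::head(gsub("\r", "/", key[duplicated(key)]), 3L),
               collapse = "; "), call. = FALSE)
  absent <- setdiff(full, key)
  if (length(absent))
    stop("balance error: missing cell(s): ",
         paste(utils::head(gsub("\r", "/", absent), 5L), collapse = "; "),
         call. = FALSE)
  arr <- array(NA_real_, dim = c(b0, l0, r0),
               dimnames = list(su, ru, pu))
  arr[cbind(match(subj, su), match(rat, ru), match(rep_, pu))] <- v
  icc_data(arr)
}

#' @export
as.data.frame.icc_data <- function(x, ...) {
  d <- x$design
  dn <- dimnames(x$values)
  su <- if (is.null(dn[[1L]])) as.character(seq_len(d$b0)) else dn[[1L]]
  ru <- if (is.null(dn[[2L]])) as.character(seq_len(d$l0)) else dn[[2L]]
  pu <- if (is.null(dn[[3L]])) as.character(seq_len(d$r0)) else dn[[3L]]
  data.frame(
    subject = rep(su, times = d$l0 * d$r0),
    rater = rep(rep(ru, each = d$b0), times = d$r0),
    replicate = rep(pu, each = d$b0 * d$l0),
    value = as.vector(x$values),
    stringsAsFactors = FALSE)
}
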