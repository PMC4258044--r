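#' Read a long-format measurement CSV
#'
#' Expects one row per measurement with a header; columns are mapped by
#' name (the replicate column may be absent for single-replicate
#' designs). Subjects and raters are ordered by first appearance. The file
#' must contain a complete balanced crossing; missing or duplicated cells
#' raise a balance error naming the offending pairs.
#'
#' @param path Path to a CSV file.
#' @param subject,rater,replicate,value Column names.
#' @return An [icc_data()] grid.
#' @export
read_icc_csv <- function(path, subject = "subject", rater = "rater",
                         replicate = "replicate", value = "value") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (value %in% names(df) && !is.numeric(df[[value]])) {
    coerced <- suppressWarnings(as.numeric(df[[value]]))
    bad <- which(is.na(coerced) & !is.na(df[[value]]))
    if (length(bad))
      stop("parse error: non-numeric value in row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), " of ", path,
           call. = FALSE)
    df[[value]] <- coerced
  }
  as_icc_data(df, subject = subject, rater = rater, replicate = replicate,
              value = value)
}

#' Write an `icc_data` grid as long-format CSV
#'
#' @param data An [icc_data()] grid.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_icc_csv <- function(data, path) {
  if (!is_icc_data(data)) stop("'data' must be an icc_data grid",
                               call. = FALSE)
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis report
#'
#' Serialises one or more interval results together with the point
#' estimates, design, seeds and package version, as JSON (machine
#' readable, round-trips exactly) or TSV (human readable).
#'
#' @param results A single `icc_interval` or a list of them.
#' @param summary The `icc_anova` the intervals were computed from (used
#'   for the point estimates and design; optional).
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_icc_report <- function(results, path, summary = NULL,
                             format = c("json", "tsv")) {
  format <- match.arg(format)
  if (is_icc_interval(results)) results <- list(results)
  if (!is.list(results) || !length(results) ||
      !all(vapply(results, is_icc_interval, logical(1L))))
    stop("'results' must be a non-empty list of icc_interval objects",
         call. = FALSE)
  point <- if (!is.null(summary)) {
    vc <- variance_components(summary)
    list(icc_b = icc_b(vc), icc_w = icc_w(vc))
  } else NULL
  design <- if (!is.null(summary))
    summary$design[c("b0", "l0", "r0")] else NULL
  rows <- lapply(results, function(r) {
    list(method = r$method, level = r$level, lower = r$lower,
         upper = r$upper,
         seed = if (!is.null(r$meta$seed)) r$meta$seed else NA)
  })
  if (format == "json") {
    payload <- list(intervals = rows, point_estimates = point,
                    design = design,
                    software = paste0("icc2way ",
                                      as.character(utils::packageVersion("icc2way"))))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  } else {
    tab <- do.call(rbind, lapply(rows, function(r)
      data.frame(method = r$method, level = r$level, lower = r$lower,
                 upper = r$upper, seed = r$seed,
                 stringsAsFactors = FALSE)))
    if (!is.null(point)) {
      tab$icc_b_hat <- point$icc_b
      tab$icc_w_hat <- point$icc_w
    }
    if (!is.null(design)) {
      tab$b0 <- design$b0; tab$l0 <- design$l0; tab$r0 <- design$r0
    }
    utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path Path written by [write_icc_report()] with
#'   `format = "json"`.
#' @return The parsed report list.
#' @export
read_icc_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
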