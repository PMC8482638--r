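#' Read a count table from CSV
#'
#' Expected header: \code{id, lower, upper}, plus \code{time_lower,
#' time_upper} when \code{has_times = TRUE}.  Comma-separated, UTF-8,
#' decimal point.  All validation failures name the offending row.
#'
#' @param path path to a CSV file.
#' @param has_times whether per-count observation-time columns are
#'   required and read.
#' @return A \code{"count_table"}: a data frame with the columns above,
#'   \code{source} attribute set to \code{path}.
#' @export
read_count_csv <- function(path, has_times = FALSE) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  needed <- c("id", "lower", "upper",
              if (has_times) c("time_lower", "time_upper"))
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw <- raw[needed]
  as_count_table(raw, source = path, has_times = has_times)
}

# Validate a raw data frame into a count_table; error messages carry the
# row id (or row number when the id itself is broken).
as_count_table <- function(raw, source = "<memory>", has_times = FALSE) {
  if (nrow(raw) < 1L)
    stop("count table must have at least one row", call. = FALSE)
  if (anyDuplicated(raw$id))
    stop("duplicate id(s): ",
         paste(unique(raw$id[duplicated(raw$id)]), collapse = ", "),
         call. = FALSE)
  num_cols <- c("lower", "upper",
                if (has_times) c("time_lower", "time_upper"))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop("non-numeric '", col, "' in row(s) with id: ",
           paste(raw$id[bad], collapse = ", "), call. = FALSE)
    raw[[col]] <- v
  }
  bad <- which(raw$lower < 0 | raw$upper < 0)
  if (length(bad))
    stop("negative count in row(s) with id: ",
         paste(raw$id[bad], collapse = ", "), call. = FALSE)
  bad <- which(raw$lower > raw$upper)
  if (length(bad))
    stop("lower exceeds upper in row(s) with id: ",
         paste(raw$id[bad], collapse = ", "), call. = FALSE)
  if (has_times) {
    bad <- which(raw$time_lower <= 0 | raw$time_upper <= 0)
    if (length(bad))
      stop("nonpositive time in row(s) with id: ",
           paste(raw$id[bad], collapse = ", "), call. = FALSE)
    bad <- which(raw$time_lower > raw$time_upper)
    if (length(bad))
      stop("time_lower exceeds time_upper in row(s) with id: ",
           paste(raw$id[bad], collapse = ", "), call. = FALSE)
  }
  rownames(raw) <- NULL
  structure(raw, source = source,
            class = c("count_table", "data.frame"))
}

#' Write a count table to CSV
#'
#' Inverse of [read_count_csv()]: \code{write_count_csv()} then
#' \code{read_count_csv()} is the identity on valid tables.
#'
#' @param table a \code{"count_table"} (or compatible data frame).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_count_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Pulse counts of 50 patients
#'
#' The bundled worked example: pulse counts of 50 patients, each recorded
#' as an indeterminate interval (patient 1 is \code{[44, 68]}, patient 50
#' is \code{[92, 100]}).  The first 11 records are real pulse-rate
#' observations; the remainder are simulated continuations published with
#' them.  The table is stored verbatim as plain CSV under
#' \code{inst/extdata}.
#'
#' @return A \code{"count_table"} with 50 rows and columns \code{id},
#'   \code{lower}, \code{upper}.
#' @examples
#' head(pulse_counts())
#' neutrosophic_mean(pulse_counts())
#' @export
pulse_counts <- function() {
  path <- system.file("extdata", "pulse_counts.csv",
                      package = "neutrochisq", mustWork = TRUE)
  tab <- read_count_csv(path)
  attr(tab, "source") <- "bundled pulse counts (50 patients)"
  tab
}

#' Render a human-readable test report
#'
#' A plain-text report of an [nchisq_test()] result: hypotheses, level,
#' degrees of freedom, critical values (2 dp), the interval statistic
#' (2 dp), its neutrosophic-form string (indeterminacy to 4 dp), the
#' decision, and the three-probability reading of the outcome -- type-I
#' error alpha, acceptance probability 1 - alpha, and the chance of
#' indeterminacy I_U.  Rendering is pure: the same result always yields
#' byte-identical text.
#'
#' @param result an \code{"nchisq_test"} object.
#' @param include_terms when \code{TRUE} and per-count contributions are
#'   available, append them (2 dp) to the report.
#' @return A single character string.
#' @export
render_report <- function(result, include_terms = FALSE) {
  stopifnot(inherits(result, "nchisq_test"))
  decision_text <- switch(result$decision,
    reject = "reject H0: the interval statistic falls in the rejection region",
    not_reject = "do not reject H0: the interval statistic lies inside the acceptance region",
    indeterminate = paste0("indeterminate: the interval statistic straddles a ",
                           "critical value; neither hypothesis is resolved"))
  lines <- c(
    result$method,
    strrep("-", nchar(result$method)),
    "H0: all counts share a common expected value",
    "H1: the counts differ significantly",
    "",
    sprintf("K = %d counts, df = %d, alpha = %.3f",
            result$k, result$df, result$alpha),
    sprintf("critical values: %.2f, %.2f",
            result$crit[["lower"]], result$crit[["upper"]]),
    sprintf("statistic: %s", format(result$statistic, digits = 2L)),
    sprintf("neutrosophic form: %s", format(result$form)),
    "",
    sprintf("decision: %s", decision_text),
    "",
    sprintf("interpretation at alpha = %.3g:", result$alpha),
    sprintf("  probability of a type-I error:       %.4g", result$alpha),
    sprintf("  probability of accepting H0:         %.4g", 1 - result$alpha),
    sprintf("  chance of indeterminacy in verdict:  %.4f", result$form$i_upper))
  if (result$form$i_upper == 0)
    lines <- c(lines, "",
               "note: the data are crisp; the test reduces to the classical chi-square statistic")
  if (include_terms && !is.null(result$terms)) {
    lines <- c(lines, "", "per-count contributions:",
               sprintf("  %3d  [%.2f, %.2f]",
                       seq_len(nrow(result$terms)),
                       result$terms$lower, result$terms$upper))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
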