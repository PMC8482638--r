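#' Interval-valued counts
#'
#' Build a validated table of interval counts.  Each row is one observed
#' count recorded as an indeterminate interval \code{[lower, upper]}: the
#' lower endpoint is the exact (determinate) part of the count, the upper
#' endpoint bounds the indeterminate part.  A "crisp" count -- one observed
#' without any indeterminacy -- has \code{lower == upper}, and the whole
#' machinery then reduces to classical count statistics.
#'
#' @param lower numeric vector of lower endpoints; nonnegative, finite.
#' @param upper numeric vector of upper endpoints; nonnegative, finite,
#'   with \code{upper >= lower} element-wise.  Defaults to \code{lower},
#'   giving crisp counts.
#' @return An object of class \code{"interval_counts"}: a data frame with
#'   columns \code{lower} and \code{upper}.
#' @examples
#' interval_counts(c(44, 62), c(68, 72))
#' interval_counts(70)          # crisp count
#' @seealso [neutrosophic_mean()], [chi2_equal_time()], [nchisq_test()]
#' @export
interval_counts <- function(lower, upper = lower) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper))
    stop("'lower' and 'upper' must have the same length", call. = FALSE)
  if (length(lower) == 0L)
    stop("at least one count is required", call. = FALSE)
  bad <- which(!is.finite(lower) | !is.finite(upper))
  if (length(bad))
    stop("non-finite count endpoint in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(lower < 0 | upper < 0)
  if (length(bad))
    stop("negative count endpoint in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(lower > upper)
  if (length(bad))
    stop("lower endpoint exceeds upper endpoint in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(data.frame(lower = lower, upper = upper),
            class = c("interval_counts", "data.frame"))
}

#' Coerce to interval counts
#'
#' @param x an object with interval-count content: an
#'   \code{interval_counts} object, a data frame with \code{lower} and
#'   \code{upper} columns (e.g. a [read_count_csv()] table), or a plain
#'   numeric vector (interpreted as crisp counts).
#' @return An \code{"interval_counts"} object.
#' @export
as_interval_counts <- function(x) {
  if (inherits(x, "interval_counts")) return(x)
  if (is.data.frame(x)) {
    if (!all(c("lower", "upper") %in% names(x)))
      stop("data frame needs 'lower' and 'upper' columns", call. = FALSE)
    return(interval_counts(x$lower, x$upper))
  }
  if (is.numeric(x)) return(interval_counts(x))
  stop("cannot coerce object of class '", class(x)[1L],
       "' to interval counts", call. = FALSE)
}

#' Which counts are crisp?
#'
#' @param x an \code{interval_counts} object.
#' @return Logical vector; \code{TRUE} where \code{lower == upper}.
#' @export
is_crisp <- function(x) {
  x <- as_interval_counts(x)
  x$lower == x$upper
}

#' Neutrosophic pair
#'
#' An indexed pair of a derived quantity: the component computed from all
#' lower endpoints and the component computed from all upper endpoints.
#' Unlike the observed intervals, a derived pair carries no ordering
#' requirement -- a test statistic's lower-data component may well exceed
#' its upper-data component (e.g. \code{[146.97, 121.78]} for the bundled
#' pulse data), because wider counts can sit closer to their own mean.
#'
#' @param l_value quantity computed from the lower endpoints; finite.
#' @param u_value quantity computed from the upper endpoints; finite.
#' @return An object of class \code{"neutro_pair"}.
#' @export
neutro_pair <- function(l_value, u_value) {
  l_value <- as.numeric(l_value)
  u_value <- as.numeric(u_value)
  if (length(l_value) != 1L || length(u_value) != 1L)
    stop("pair components must be scalars", call. = FALSE)
  if (!is.finite(l_value) || !is.finite(u_value))
    stop("pair components must be finite", call. = FALSE)
  structure(list(l_value = l_value, u_value = u_value),
            class = "neutro_pair")
}

#' @export
format.neutro_pair <- function(x, digits = 2L, ...) {
  sprintf("[%.*f, %.*f]", digits, x$l_value, digits, x$u_value)
}

#' @export
print.neutro_pair <- function(x, ...) {
  cat("neutrosophic pair", format(x, ...), "\n")
  invisible(x)
}

#' @export
as.double.neutro_pair <- function(x, ...) {
  c(x$l_value, x$u_value)
}

#' Neutrosophic-form decomposition
#'
#' Rewrite a neutrosophic pair as \code{base + coefficient * I} with
#' indeterminacy \code{I} ranging over \code{[0, i_upper]}.  The base
#' (determinate part) is the lower-data component; at \code{I = i_upper}
#' the form recovers the upper-data component.  The indeterminacy measure
#' is the relative gap between the components,
#' \deqn{I_U = |u - l| / |u|,}
#' so a crisp pair (\code{l == u}) has \code{i_upper = 0} and the form
#' collapses to the classical (exact) quantity.  \code{i_upper} is
#' scale-free: rescaling both components by a positive constant leaves it
#' unchanged.
#'
#' The coefficient carries a sign so that the form interpolates from
#' \code{l_value} (at \code{I = 0}) to \code{u_value} (at
#' \code{I = i_upper}): positive when the upper component dominates (as for
#' a sample mean of ordered intervals), negative when the lower component
#' dominates (as the dispersion statistic can).
#'
#' @param pair a [neutro_pair()], or anything accepted by it via a
#'   two-element numeric vector.
#' @return An object of class \code{"neutro_form"} with fields
#'   \code{base}, \code{coefficient}, \code{i_lower} (always 0) and
#'   \code{i_upper}.
#' @examples
#' neutro_form(neutro_pair(73.54, 91.8))       # mean form, I_U ~ 0.1989
#' neutro_form(neutro_pair(146.9733, 121.7865)) # statistic form, I_U ~ 0.2068
#' @export
neutro_form <- function(pair) {
  if (!inherits(pair, "neutro_pair")) {
    if (is.numeric(pair) && length(pair) == 2L)
      pair <- neutro_pair(pair[[1L]], pair[[2L]])
    else stop("'pair' must be a neutro_pair or a length-2 numeric",
              call. = FALSE)
  }
  l <- pair$l_value
  u <- pair$u_value
  if (u == 0) {
    if (l != 0)
      stop("degenerate form: upper component is zero with nonzero lower ",
           "component; indeterminacy measure undefined", call. = FALSE)
    return(structure(list(base = 0, coefficient = 0,
                          i_lower = 0, i_upper = 0),
                     class = "neutro_form"))
  }
  coefficient <- if (u >= l) abs(u) else -abs(u)
  i_upper <- abs(u - l) / abs(u)
  structure(list(base = l, coefficient = coefficient,
                 i_lower = 0, i_upper = i_upper),
            class = "neutro_form")
}

#' @export
format.neutro_form <- function(x, digits = 2L, i_digits = 4L, ...) {
  sprintf("%.*f %s %.*f*I;  I in [0, %.*f]",
          digits, x$base,
          if (x$coefficient >= 0) "+" else "-",
          digits, abs(x$coefficient),
          i_digits, x$i_upper)
}

#' @export
print.neutro_form <- function(x, ...) {
  cat("neutrosophic form:", format(x, ...), "\n")
  invisible(x)
}

#' Evaluate a neutrosophic form at a value of I
#'
#' @param form a \code{neutro_form}.
#' @param i value(s) of the indeterminacy I; \code{i = 0} gives the
#'   determinate part, \code{i = form$i_upper} the upper-data component.
#' @return Numeric vector \code{base + coefficient * i}.
#' @export
eval_form <- function(form, i) {
  stopifnot(inherits(form, "neutro_form"))
  form$base + form$coefficient * i
}
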