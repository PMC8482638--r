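#' Neutrosophic sample mean of K interval counts
#'
#' Component-wise arithmetic mean: the lower-data component averages the
#' lower endpoints, the upper-data component the upper endpoints.
#'
#' @param counts interval counts (anything accepted by
#'   [as_interval_counts()]).
#' @return A [neutro_pair()] of the two means.
#' @examples
#' neutrosophic_mean(pulse_counts())   # [73.54, 91.80]
#' @export
neutrosophic_mean <- function(counts) {
  counts <- as_interval_counts(counts)
  neutro_pair(mean(counts$lower), mean(counts$upper))
}

#' Per-count contributions to the equal-time statistic
#'
#' For each count i, \eqn{(N_i - \bar N)^2 / \bar N} computed
#' component-wise against the component means of the whole sample.  The
#' contributions sum to the [chi2_equal_time()] statistic.
#'
#' @inheritParams neutrosophic_mean
#' @return Data frame with columns \code{lower} and \code{upper}, one row
#'   per count.
#' @export
chi2_terms <- function(counts) {
  counts <- as_interval_counts(counts)
  m <- neutrosophic_mean(counts)
  if (m$l_value <= 0 || m$u_value <= 0)
    stop("degenerate data: a component mean is zero, the statistic's ",
         "denominators are undefined", call. = FALSE)
  data.frame(lower = (counts$lower - m$l_value)^2 / m$l_value,
             upper = (counts$upper - m$u_value)^2 / m$u_value)
}

#' Equal-time neutrosophic chi-square statistic
#'
#' Dispersion statistic for K interval counts recorded over equal periods,
#' testing the null hypothesis that all K counts share a common expected
#' value:
#' \deqn{\chi^2 = \sum_{i=1}^{K} (N_i - \bar N)^2 / \bar N,}
#' evaluated component-wise (all lower endpoints give the lower-data
#' component, all upper endpoints the upper-data component), in full
#' double precision.  On crisp data both components coincide with the
#' classical chi-square dispersion statistic.
#'
#' @inheritParams neutrosophic_mean
#' @return A [neutro_pair()] with the two statistic components.  No
#'   ordering between them is implied.
#' @examples
#' chi2_equal_time(pulse_counts())   # [146.9733, 121.7865]
#' @export
chi2_equal_time <- function(counts) {
  counts <- as_interval_counts(counts)
  if (nrow(counts) < 2L)
    stop("at least 2 counts are required", call. = FALSE)
  terms <- chi2_terms(counts)
  neutro_pair(sum(terms$lower), sum(terms$upper))
}

#' Unequal-time neutrosophic chi-square statistic
#'
#' Variant for counts recorded over periods \eqn{t_i} that need not be
#' equal.  The expected count for period i is \eqn{t_i \bar R} with pooled
#' rate \eqn{\bar R = \sum N_i / \sum t_i}, and
#' \deqn{\chi^2 = \sum_{i=1}^{K} (N_i - t_i \bar R)^2 / (t_i \bar R),}
#' all computed component-wise: lower counts with lower times give the
#' lower-data component, upper counts with upper times the upper-data
#' component.  Observation times may themselves be indeterminate
#' intervals; crisp times have equal endpoints.  With all times equal the
#' statistic reduces algebraically to [chi2_equal_time()].
#'
#' @inheritParams neutrosophic_mean
#' @param times observation times: a positive numeric vector (crisp
#'   times) or an interval table with \code{lower}/\code{upper} columns,
#'   one row per count, all entries > 0.
#' @return A [neutro_pair()] with the two statistic components.
#' @export
chi2_unequal_time <- function(counts, times) {
  counts <- as_interval_counts(counts)
  if (nrow(counts) < 2L)
    stop("at least 2 counts are required", call. = FALSE)
  times <- as_interval_counts(times)
  if (nrow(times) != nrow(counts))
    stop("'times' must supply one period per count", call. = FALSE)
  bad <- which(times$lower <= 0 | times$upper <= 0)
  if (length(bad))
    stop("nonpositive observation time in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (sum(counts$lower) <= 0 || sum(counts$upper) <= 0)
    stop("degenerate data: total count is zero in a component", call. = FALSE)
  rate_l <- sum(counts$lower) / sum(times$lower)
  rate_u <- sum(counts$upper) / sum(times$upper)
  exp_l <- times$lower * rate_l
  exp_u <- times$upper * rate_u
  neutro_pair(sum((counts$lower - exp_l)^2 / exp_l),
              sum((counts$upper - exp_u)^2 / exp_u))
}

#' Pooled neutrosophic rate
#'
#' \eqn{\bar R = \sum N_i / \sum t_i} per component; the expected count
#' for period i under the null is \eqn{t_i \bar R}.
#'
#' @inheritParams chi2_unequal_time
#' @return A [neutro_pair()] of the two pooled rates.
#' @export
neutrosophic_rate <- function(counts, times) {
  counts <- as_interval_counts(counts)
  times <- as_interval_counts(times)
  if (nrow(times) != nrow(counts))
    stop("'times' must supply one period per count", call. = FALSE)
  neutro_pair(sum(counts$lower) / sum(times$lower),
              sum(counts$upper) / sum(times$upper))
}

#' Critical region of the chi-square dispersion test
#'
#' Two-sided rejection region: the test rejects when the statistic falls
#' below the \eqn{\alpha}-quantile or above the \eqn{1-\alpha}-quantile of
#' the central chi-square distribution, so each tail carries mass
#' \eqn{\alpha}.  The reference degrees of freedom default to K itself
#' (\code{df_rule = "K"}); the classical dispersion-test convention
#' \code{df = K - 1} (one degree lost to estimating the common mean) is
#' available as \code{df_rule = "K-1"}.
#'
#' @param alpha significance level per tail, in (0, 0.5).
#' @param k number of counts, >= 2.
#' @param df_rule \code{"K"} (default) or \code{"K-1"}.
#' @return Named numeric vector \code{c(lower = ..., upper = ...)} with
#'   the two critical values, \code{lower < upper}.
#' @examples
#' critical_region(0.05, 50)   # c(34.76, 67.50)
#' @export
critical_region <- function(alpha, k, df_rule = c("K", "K-1")) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 0.5)
    stop("'alpha' must lie strictly between 0 and 0.5", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k < 2)
    stop("'k' must be an integer >= 2", call. = FALSE)
  df_rule <- match.arg(df_rule)
  df <- if (df_rule == "K") k else k - 1
  c(lower = stats::qchisq(alpha, df), upper = stats::qchisq(1 - alpha, df))
}

#' Tri-state test decision
#'
#' Compare both components of an interval statistic with the critical
#' region \code{[crit_lower, crit_upper]}.  Both components strictly
#' outside the region reject the null; both inside (endpoints count as
#' inside) retain it.  When the pair straddles a critical value -- one
#' component in, one out -- neither verdict is supportable and the
#' explicit outcome \code{"indeterminate"} is returned; the indeterminacy
#' in the data is then too large for the test to resolve the hypothesis.
#' The outcome does not depend on the order of the two components.
#'
#' @param statistic a [neutro_pair()].
#' @param crit_lower,crit_upper critical values, \code{crit_lower <
#'   crit_upper}; see [critical_region()].
#' @return One of \code{"reject"}, \code{"not_reject"},
#'   \code{"indeterminate"}.
#' @export
decide <- function(statistic, crit_lower, crit_upper) {
  stopifnot(inherits(statistic, "neutro_pair"))
  if (!(crit_lower < crit_upper))
    stop("'crit_lower' must be less than 'crit_upper'", call. = FALSE)
  s <- c(statistic$l_value, statistic$u_value)
  outside <- s < crit_lower | s > crit_upper
  if (all(outside)) "reject"
  else if (all(!outside)) "not_reject"
  else "indeterminate"
}

#' Neutrosophic chi-square test for K counts
#'
#' Run the full testing procedure on interval counts: compute the
#' equal-time statistic (or, when observation times are supplied, the
#' unequal-time statistic), decompose it into its neutrosophic form,
#' build the critical region at level \code{alpha}, and decide.  The null
#' hypothesis is that all K counts share a common expected value (e.g.
#' that the same treatment suits all patients); the alternative, that
#' they differ.
#'
#' @inheritParams neutrosophic_mean
#' @param times optional observation times (see [chi2_unequal_time()]);
#'   omit for counts recorded over equal periods.
#' @param alpha per-tail significance level, in (0, 0.5); default 0.05.
#' @param df_rule degrees-of-freedom rule, see [critical_region()].
#' @return Object of class \code{"nchisq_test"}: a list with
#'   \code{statistic} (neutro_pair), \code{form} (neutro_form),
#'   \code{terms} (per-count contributions, equal-time case only),
#'   \code{k}, \code{df}, \code{alpha}, \code{crit} (length-2 vector),
#'   \code{decision}, and \code{method}.
#' @examples
#' nchisq_test(pulse_counts(), alpha = 0.05)
#' @export
nchisq_test <- function(counts, times = NULL, alpha = 0.05,
                        df_rule = c("K", "K-1")) {
  df_rule <- match.arg(df_rule)
  counts <- as_interval_counts(counts)
  k <- nrow(counts)
  if (is.null(times)) {
    statistic <- chi2_equal_time(counts)
    terms <- chi2_terms(counts)
    method <- "equal-time neutrosophic chi-square test for K counts"
  } else {
    statistic <- chi2_unequal_time(counts, times)
    terms <- NULL
    method <- "unequal-time neutrosophic chi-square test for K counts"
  }
  crit <- critical_region(alpha, k, df_rule)
  structure(list(statistic = statistic,
                 form = neutro_form(statistic),
                 terms = terms,
                 k = k,
                 df = if (df_rule == "K") k else k - 1L,
                 alpha = alpha,
                 crit = crit,
                 decision = decide(statistic, crit[["lower"]], crit[["upper"]]),
                 method = method),
            class = "nchisq_test")
}

#' @export
print.nchisq_test <- function(x, ...) {
  cat(render_report(x))
  invisible(x)
}
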