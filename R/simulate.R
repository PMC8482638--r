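# Evaluate expr with a locally set seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

#' Simulate interval counts
#'
#' Draw K synthetic interval counts with integer endpoints uniform on
#' \code{[low, high]}, emulating count observations whose indeterminacy
#' comes from the recording process.  Two generation modes:
#' \describe{
#'   \item{\code{"sort2"} (default)}{draw two integers uniformly on
#'     \code{[low, high]} and assign min/max to lower/upper.}
#'   \item{\code{"width"}}{draw the lower endpoint uniformly on
#'     \code{[low, high]}, then a width uniformly on
#'     \code{[0, high - lower]}.}
#' }
#' Defaults (\code{k = 50}, bounds 45 to 55) mirror the Monte-Carlo study
#' conditions for pulse-like counts.
#'
#' @param k number of counts per dataset, >= 2.
#' @param low,high integer generation bounds, \code{low <= high}.
#' @param seed optional integer seed; a fixed seed gives a reproducible
#'   dataset and the caller's RNG state is left untouched.
#' @param mode \code{"sort2"} or \code{"width"}.
#' @return An [interval_counts()] table with \code{k} rows, every
#'   endpoint in \code{[low, high]}.
#' @examples
#' generate_interval_counts(k = 5, seed = 1)
#' @export
generate_interval_counts <- function(k = 50, low = 45, high = 55,
                                     seed = NULL,
                                     mode = c("sort2", "width")) {
  mode <- match.arg(mode)
  if (!is.numeric(k) || length(k) != 1L || k < 2)
    stop("'k' must be an integer >= 2", call. = FALSE)
  if (low > high)
    stop("'low' must not exceed 'high'", call. = FALSE)
  with_seed(seed, {
    vals <- seq.int(low, high)
    if (mode == "sort2") {
      a <- sample(vals, k, replace = TRUE)
      b <- sample(vals, k, replace = TRUE)
      interval_counts(pmin(a, b), pmax(a, b))
    } else {
      lo <- sample(vals, k, replace = TRUE)
      width <- vapply(high - lo,
                      function(w) sample.int(w + 1L, 1L) - 1L,
                      integer(1L))
      interval_counts(lo, lo + width)
    }
  })
}

# reps x 2 matrix of equal-time statistic components over simulated
# datasets, drawn sequentially from one seeded stream.
simulate_statistics <- function(reps, k, low, high, seed,
                                mode = "sort2") {
  with_seed(seed, {
    t(vapply(seq_len(reps), function(r) {
      s <- chi2_equal_time(generate_interval_counts(k, low, high,
                                                    seed = NULL, mode = mode))
      c(s$l_value, s$u_value)
    }, numeric(2L)))
  })
}

# Table 2 prints alpha values up to 0.99, which the two-sided alpha /
# (1 - alpha) quantile rule cannot consume; levels above 0.5 are read as
# 1 - alpha (0.92 means alpha = 0.08).
normalize_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1 || alpha == 0.5)
    stop("'alpha' must lie in (0, 1) and differ from 0.5", call. = FALSE)
  if (alpha > 0.5) 1 - alpha else alpha
}

rejection_rates <- function(stat_matrix, alpha, k, df_rule) {
  crit <- critical_region(normalize_alpha(alpha), k, df_rule)
  outside <- stat_matrix < crit[["lower"]] | stat_matrix > crit[["upper"]]
  colMeans(outside)
}

#' Monte-Carlo rejection rate of the test
#'
#' Estimate, per component, the fraction of simulated datasets whose
#' statistic component falls in the rejection region at level
#' \code{alpha}.  Each component is counted independently, so the two
#' proportions bracket the test's behaviour over the indeterminacy range.
#' When the generated data satisfy the null (a common expected count)
#' this is a type-I-error estimate; the neutral name "rejection rate" is
#' used throughout.
#'
#' Levels above 0.5 are interpreted as \code{1 - alpha} (a printed level
#' of 0.92 means \code{alpha = 0.08}) so that conventional power-study
#' grids can be fed directly.
#'
#' @param alpha significance level (see Details for levels > 0.5).
#' @param reps number of Monte-Carlo replications, >= 1.
#' @inheritParams generate_interval_counts
#' @param df_rule degrees-of-freedom rule, see [critical_region()].
#' @return Object of class \code{"power_estimate"}: list with
#'   \code{alpha}, \code{reps}, \code{power} (a [neutro_pair()] of
#'   rejection proportions), \code{seed}.
#' @export
estimate_rejection_rate <- function(alpha, reps, k = 50, low = 45,
                                    high = 55, seed = 1L,
                                    mode = c("sort2", "width"),
                                    df_rule = c("K", "K-1")) {
  mode <- match.arg(mode)
  df_rule <- match.arg(df_rule)
  if (!is.numeric(reps) || length(reps) != 1L || reps < 1)
    stop("'reps' must be >= 1", call. = FALSE)
  stats <- simulate_statistics(reps, k, low, high, seed, mode)
  rate <- rejection_rates(stats, alpha, k, df_rule)
  structure(list(alpha = alpha, reps = as.integer(reps),
                 power = neutro_pair(rate[[1L]], rate[[2L]]),
                 seed = seed),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("rejection rate at alpha = %g (%d reps, seed %s): %s\n",
              x$alpha, x$reps, format(x$seed),
              format(x$power, digits = 4L)))
  invisible(x)
}

#' Rejection-rate curve over a grid of significance levels
#'
#' Evaluate [estimate_rejection_rate()] over a grid of levels.  All
#' levels are scored against the same simulated datasets, drawn
#' sequentially from the single seeded stream (common random numbers):
#' a one-level grid therefore equals the single-level estimate exactly,
#' and the curve is free of between-level simulation noise.
#'
#' @param alphas nonempty numeric vector of significance levels.
#' @inheritParams estimate_rejection_rate
#' @return Data frame of class \code{"power_curve"} with columns
#'   \code{alpha}, \code{power_lower}, \code{power_upper}, \code{reps},
#'   \code{seed}.
#' @examples
#' power_curve(c(0.01, 0.05, 0.1), reps = 200, seed = 7)
#' @export
power_curve <- function(alphas, reps, k = 50, low = 45, high = 55,
                        seed = 1L, mode = c("sort2", "width"),
                        df_rule = c("K", "K-1")) {
  mode <- match.arg(mode)
  df_rule <- match.arg(df_rule)
  if (length(alphas) == 0L)
    stop("'alphas' must be nonempty", call. = FALSE)
  if (!is.numeric(reps) || length(reps) != 1L || reps < 1)
    stop("'reps' must be >= 1", call. = FALSE)
  stats <- simulate_statistics(reps, k, low, high, seed, mode)
  rates <- t(vapply(alphas, function(a)
    rejection_rates(stats, a, k, df_rule), numeric(2L)))
  structure(data.frame(alpha = alphas,
                       power_lower = rates[, 1L],
                       power_upper = rates[, 2L],
                       reps = as.integer(reps),
                       seed = seed),
            class = c("power_curve", "data.frame"))
}

#' Plot a rejection-rate curve
#'
#' Two curves (lower-data and upper-data components) of rejection rate
#' against significance level.
#'
#' @param curve a [power_curve()] result.
#' @param file optional path; when given the plot is written there as PNG.
#' @return The curve, invisibly.
#' @export
plot_power_curve <- function(curve, file = NULL) {
  stopifnot(inherits(curve, "power_curve"))
  draw <- function() {
    graphics::matplot(curve$alpha,
                      cbind(curve$power_lower, curve$power_upper),
                      type = "b", pch = c(1, 2), lty = c(1, 2),
                      col = c("black", "grey40"),
                      xlab = expression(alpha),
                      ylab = "rejection rate",
                      main = "Neutrosophic chi-square test: rejection rate")
    graphics::legend("bottomright", c("lower component", "upper component"),
                     pch = c(1, 2), lty = c(1, 2),
                     col = c("black", "grey40"), bty = "n")
  }
  if (is.null(file)) draw()
  else {
    grDevices::png(file, width = 800, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
  }
  invisible(curve)
}
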