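#' Hartigan's dip statistic
#'
#' The dip of a sample is the sup-norm distance between its empirical
#' distribution function and the closest unimodal distribution function; it
#' is large for multimodal samples and attains its lower bound of
#' \eqn{1/(2n)} for samples fully compatible with unimodality.  It is
#' computed here exactly through the excess-mass characterisation (half the
#' maximal difference between two-interval and one-interval excess masses),
#' which handles tied values naturally via the ECDF-with-ties formulation.
#' Constant samples return the lower bound.
#'
#' @param x Numeric vector, length at least 2.
#' @return The dip statistic, a value in \[1/(2n), 0.25\].
#' @examples
#' dip_statistic(c(0, 1))                      # 0.25, maximal for n = 2
#' dip_statistic(rep(1, 10))                   # 0.05, the lower bound 1/(2n)
#' dip_statistic(c(rep(0, 50), rep(1, 50)))    # 0.25, extreme bimodality
#' @export
dip_statistic <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("'x' must not contain missing values")
  if (length(x) < 2L) stop("dip statistic requires at least two observations")
  dip_stat_cpp(x)
}

#' Monte Carlo dip test for multimodality
#'
#' Tests the null hypothesis of unimodality by comparing the sample dip to
#' dips of \code{n_mc} samples of the same size drawn from the uniform
#' distribution on (0, 1).  The p-value uses the add-one correction
#' \eqn{p = (1 + \#\{D_{null} \ge D\}) / (n_{mc} + 1)} and so never returns
#' exactly zero.
#'
#' @param x Numeric vector, length at least 2 (3 or more recommended).
#' @param n_mc Number of Monte Carlo null samples (default 10,000).
#' @param null_dips Optional precomputed vector of null dip values for this
#'   sample size (e.g. from [dip_null_distribution()]), in which case
#'   \code{n_mc} is ignored.  Reusing one null set across many tests of
#'   equal-sized samples saves considerable time.
#' @return An object of class \code{"dip_test"} with elements
#'   \code{statistic}, \code{p_value}, \code{n} and \code{n_mc}.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(100, 0), rnorm(100, 6))
#' dip_test(x, n_mc = 500)
#' @export
dip_test <- function(x, n_mc = 10000L, null_dips = NULL) {
  D <- dip_statistic(x)
  n <- length(x)
  if (is.null(null_dips)) {
    n_mc <- as.integer(n_mc)
    if (is.na(n_mc) || n_mc < 1L) stop("'n_mc' must be a positive integer")
    null_dips <- dip_null_cpp(n, n_mc)
  } else {
    n_mc <- length(null_dips)
    if (n_mc < 1L) stop("'null_dips' must be non-empty")
  }
  p <- (1 + sum(null_dips >= D)) / (n_mc + 1)
  structure(list(statistic = D, p_value = p, n = n, n_mc = n_mc),
            class = "dip_test")
}

#' Null distribution of the dip statistic
#'
#' Dip values of \code{n_mc} uniform samples of size \code{n}, drawn from the
#' current RNG stream.  Useful to amortise the Monte Carlo null across many
#' tests of equal-sized samples.
#'
#' @param n Sample size.
#' @param n_mc Number of null samples.
#' @return Numeric vector of length \code{n_mc}.
#' @export
dip_null_distribution <- function(n, n_mc = 10000L) {
  dip_null_cpp(as.integer(n), as.integer(n_mc))
}

#' @export
print.dip_test <- function(x, ...) {
  cat("Hartigan dip test of unimodality (Monte Carlo)\n")
  cat(sprintf("  D = %.4f, n = %d, p = %.4g (%d null samples)\n",
              x$statistic, x$n, x$p_value, x$n_mc))
  invisible(x)
}
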