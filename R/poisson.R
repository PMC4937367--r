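#' Poisson cumulative distribution function
#'
#' F(k | lambda) = sum_{i=0}^{k} exp(-lambda) lambda^i / i!, the probability
#' that a Poisson count with mean `lambda` is at most `k`. This is the test
#' distribution for lagged coincidence counts: the count at a non-zero lag
#' is referred to a Poisson law whose mean is the zero-lag count.
#'
#' Evaluation is delegated to [stats::ppois()], which is numerically stable
#' for means far beyond the 1e5 scale reached by long event series.
#'
#' @param k non-negative integer count (vectorized).
#' @param lam non-negative expected count.
#' @return P(K <= k) in \[0, 1\].
#' @examples
#' poisson_cdf(0, 1)        # exp(-1)
#' poisson_cdf(127, 100)    # upper tail reference for k0 = 100
#' @export
poisson_cdf <- function(k, lam) {
  if (!is.numeric(k) || anyNA(k) || any(k < 0))
    stop("'k' must be non-negative", call. = FALSE)
  if (any(k != floor(k)))
    stop("'k' must be integer-valued", call. = FALSE)
  if (!is.numeric(lam) || anyNA(lam) || any(lam < 0))
    stop("'lam' must be non-negative", call. = FALSE)
  stats::ppois(k, lam)
}

#' Significance limits for a lagged coincidence count
#'
#' Given the zero-lag reference count `k0`, `upper_limit()` returns the
#' smallest integer count that is significantly *larger* than `k0` at level
#' `alpha` under the Poisson null, i.e. the smallest k* with
#' F(k* | k0) > 1 - alpha. Counts at or above k* are flagged as positive
#' causality. This is the dotted threshold line drawn on lag profiles.
#'
#' `lower_limit()` is the mirror image for negative causality: the largest
#' integer count with F(k | k0) < alpha, or `NA` if even a count of zero is
#' not significantly small (which happens whenever k0 is small).
#'
#' @param k0 non-negative integer zero-lag reference count.
#' @param alpha significance level, in (0, 0.5).
#' @param n_eff optional positive integer number of samples supporting the
#'   count; when given, the result also carries the threshold on the
#'   frequency scale (`count / n_eff`) as attribute `"frequency"`.
#' @return integer count threshold (with optional `"frequency"` attribute).
#' @examples
#' upper_limit(100, 0.005)
#' lower_limit(100, 0.005)
#' @export
upper_limit <- function(k0, alpha, n_eff = NULL) {
  check_alpha(alpha)
  if (!is.numeric(k0) || length(k0) != 1L || is.na(k0) || k0 < 0 ||
      k0 != floor(k0))
    stop("'k0' must be a single non-negative integer", call. = FALSE)
  k <- stats::qpois(1 - alpha, k0)
  while (stats::ppois(k, k0) <= 1 - alpha) k <- k + 1L
  k <- as.integer(k)
  if (!is.null(n_eff)) {
    if (!is.numeric(n_eff) || length(n_eff) != 1L || n_eff < 1)
      stop("'n_eff' must be a positive integer", call. = FALSE)
    attr(k, "frequency") <- k / n_eff
  }
  k
}

#' @rdname upper_limit
#' @export
lower_limit <- function(k0, alpha, n_eff = NULL) {
  check_alpha(alpha)
  if (!is.numeric(k0) || length(k0) != 1L || is.na(k0) || k0 < 0 ||
      k0 != floor(k0))
    stop("'k0' must be a single non-negative integer", call. = FALSE)
  if (stats::ppois(0, k0) >= alpha) return(NA_integer_)
  k <- stats::qpois(alpha, k0)  # smallest k with F(k) >= alpha
  while (k > 0L && stats::ppois(k - 1L, k0) >= alpha) k <- k - 1L
  k <- as.integer(k - 1L)       # largest k with F(k) < alpha
  if (!is.null(n_eff)) attr(k, "frequency") <- k / n_eff
  k
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 0.5)
    stop("'alpha' must be a single value in (0, 0.5)", call. = FALSE)
  invisible(alpha)
}
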