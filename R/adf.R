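#' Augmented Dickey-Fuller unit-root test (with constant)
#'
#' Tests the null hypothesis that `x` has a unit root (is integrated, i.e.
#' non-stationary in the random-walk sense) against the alternative of
#' stationarity around a constant mean. The test regresses the first
#' difference of the series on its lagged level, `k` lagged differences and
#' an intercept; the statistic is the t-ratio of the lagged-level
#' coefficient, referred to the Dickey-Fuller tau distribution for the
#' with-constant case. P-values are interpolated from the standard
#' critical-value table and clamped to \[0.01, 0.99\]; values at the clamp
#' boundary mean "at most 0.01" / "at least 0.99".
#'
#' Large negative statistics reject the unit root (evidence of
#' stationarity); failure to reject is the package's operational criterion
#' for non-stationarity (see [nonstationarity_check()]).
#'
#' @param x numeric series (length >= 20 after differencing and lagging).
#' @param k number of lagged differences to include; default
#'   `trunc((length(x) - 1)^(1/3))`, the common length-based rule.
#' @return a list of class `htest` with `statistic`, `p.value`,
#'   `parameter` (lag order), `method` and `data.name`.
#' @examples
#' set.seed(1)
#' adf_test(cumsum(rnorm(500)))   # unit root: large p-value
#' adf_test(rnorm(500))           # stationary: p at the 0.01 clamp
#' @export
adf_test <- function(x, k = trunc((length(x) - 1)^(1/3))) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("missing values are not allowed", call. = FALSE)
  n <- length(x)
  if (n < 20L) stop("series too short for a unit-root test (need >= 20)",
                    call. = FALSE)
  if (stats::sd(x) == 0)
    stop("constant series: unit-root test is undefined", call. = FALSE)
  k <- as.integer(k)
  if (k < 0L) stop("'k' must be non-negative", call. = FALSE)

  dy <- diff(x)
  m <- length(dy)
  yl <- x[(k + 1L):(n - 1L)]               # lagged level
  resp <- dy[(k + 1L):m]
  X <- cbind(1, yl)
  if (k > 0L) {
    dlag <- sapply(seq_len(k), function(i) dy[(k + 1L - i):(m - i)])
    X <- cbind(X, dlag)
  }
  fit <- stats::lm.fit(X, resp)
  res <- fit$residuals
  df <- length(resp) - ncol(X)
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(s2 * XtXinv[2L, 2L])
  stat <- fit$coefficients[2L] / se

  pv <- df_tau_pvalue(stat, length(resp))
  structure(list(
    statistic = c(`Dickey-Fuller` = unname(stat)),
    parameter = c(`lag order` = k),
    p.value = pv,
    alternative = "stationary",
    method = "Augmented Dickey-Fuller test (with constant)",
    data.name = deparse(substitute(x))
  ), class = "htest")
}

# Dickey-Fuller tau table, with-constant case (tau_mu): rows are sample
# sizes, columns the tabulated tail probabilities.
df_tau_table <- function() {
  list(
    n = c(25, 50, 100, 250, 500, Inf),
    probs = c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99),
    crit = rbind(
      c(-3.75, -3.33, -3.00, -2.62, -0.37,  0.00, 0.34, 0.72),
      c(-3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66),
      c(-3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63),
      c(-3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62),
      c(-3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61),
      c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60)
    )
  )
}

# internal: two-way interpolation of the tau table (over n, then over the
# statistic); clamped to [0.01, 0.99] outside the tabulated range
df_tau_pvalue <- function(stat, n) {
  tab <- df_tau_table()
  nn <- pmin(n, 1e6)
  crit_n <- apply(tab$crit, 2L, function(col)
    stats::approx(tab$n[-length(tab$n)], col[-length(col)],
                  xout = nn, rule = 2)$y)
  # beyond the largest finite row, blend toward the asymptotic row
  if (n > 500) crit_n <- tab$crit[nrow(tab$crit), ]
  stats::approx(crit_n, tab$probs, xout = stat, rule = 2)$y
}
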