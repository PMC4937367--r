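#' Count events of relations at a fixed lag
#'
#' An event of relation (ER) at lag `tau` is the joint occurrence of the
#' candidate effect `x` at sample t and the candidate cause `y` at sample
#' t - tau. `count_er()` returns K_tau, the number of such joint events over
#' the observation, using a linear (non-circular) shift: only samples
#' t in \[tau, n-1\] (0-based) contribute, so the effective support is
#' n - tau samples and the count can never exceed it. K_0 (lag zero) is the
#' symmetric joint count used as the null reference by [cer_test()].
#'
#' @param x candidate effect series (binary vector or `event_series`).
#' @param y candidate cause series, aligned with `x`.
#' @param tau non-negative integer lag in samples, `0 <= tau < length(x)`.
#' @return non-negative integer count K_tau.
#' @examples
#' x <- c(0, 1, 0, 0, 1, 0, 1)
#' y <- c(1, 0, 0, 1, 0, 1, 0)
#' count_er(x, y, 1)  # 3
#' count_er(x, y, 0) == count_er(y, x, 0)  # lag-0 symmetry
#' @export
count_er <- function(x, y, tau) {
  x <- as_event_series(x); y <- as_event_series(y)
  n <- check_aligned(x, y)
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) ||
      tau < 0 || tau != floor(tau))
    stop("'tau' must be a single non-negative integer", call. = FALSE)
  if (tau >= n)
    stop(sprintf("lag tau = %d must be smaller than the series length %d",
                 as.integer(tau), n), call. = FALSE)
  er_counts(unclass(x), unclass(y), as.integer(tau))[[1L]]
}

# internal workhorse: counts of x[t]==1 & y[t-tau]==1 for each tau in `taus`,
# over the overlap t in [tau+1, n] (1-based). x, y plain integer vectors.
er_counts <- function(x, y, taus) {
  n <- length(x)
  iy <- which(y == 1L)
  if (length(iy) == 0L) return(integer(length(taus)))
  vapply(taus, function(tau) {
    idx <- iy + tau
    if (tau > 0L) idx <- idx[idx <= n]
    sum(x[idx])
  }, integer(1))
}

#' Lag profile of event-of-relation counts
#'
#' Computes the coincidence counts K_tau for tau = 0..`tau_max`, their
#' frequencies p(M_tau) = K_tau / n_eff(tau) over the shrinking overlap
#' n_eff(tau) = n - tau, and the per-`alpha` significance limits derived
#' from the zero-lag reference K_0 ([upper_limit()], [lower_limit()]).
#' This is the quantity plotted in the package's lag-profile figures: the
#' frequency of joint events against delay, with a dotted line at the
#' zero-lag upper limit.
#'
#' @inheritParams count_er
#' @param tau_max largest lag scanned (positive integer, `< length(x)`).
#' @param alpha significance level for the limit lines.
#' @return an object of class `er_profile`: a list with elements `lags`
#'   (0..tau_max), `counts`, `n_eff`, `frequencies`, `k0`, `upper_limit`,
#'   `lower_limit` (counts; `NA` lower limit when k0 is too small), `alpha`,
#'   `n`, and the channel labels.
#' @examples
#' sim <- simulate_network(two_node_config(p_interaction = 0.6,
#'                                         delay = make_delay("fixed", 4),
#'                                         n = 2000, seed = 1))
#' pr <- er_profile(sim$series$X, sim$series$Y, tau_max = 10, alpha = 0.005)
#' pr
#' @export
er_profile <- function(x, y, tau_max = 20, alpha = 0.005) {
  x <- as_event_series(x); y <- as_event_series(y)
  n <- check_aligned(x, y)
  check_tau_max(tau_max, n)
  check_alpha(alpha)
  lags <- 0L:as.integer(tau_max)
  counts <- er_counts(unclass(x), unclass(y), lags)
  n_eff <- n - lags
  k0 <- counts[1L]
  structure(list(
    lags = lags,
    counts = counts,
    n_eff = n_eff,
    frequencies = counts / n_eff,
    k0 = k0,
    upper_limit = upper_limit(k0, alpha),
    lower_limit = lower_limit(k0, alpha),
    alpha = alpha,
    n = n,
    effect = series_label(x, "x"),
    cause = series_label(y, "y")
  ), class = "er_profile")
}

check_tau_max <- function(tau_max, n) {
  if (!is.numeric(tau_max) || length(tau_max) != 1L || is.na(tau_max) ||
      tau_max < 1 || tau_max != floor(tau_max))
    stop("'tau_max' must be a single positive integer", call. = FALSE)
  if (tau_max >= n)
    stop(sprintf("'tau_max' (%d) must be smaller than the series length %d",
                 as.integer(tau_max), n), call. = FALSE)
  invisible(tau_max)
}

#' @export
print.er_profile <- function(x, ...) {
  cat(sprintf("Event-of-relation lag profile: %s (cause) -> %s (effect)\n",
              x$cause, x$effect))
  cat(sprintf("  n = %d samples, lags 0..%d, K_0 = %d\n",
              x$n, max(x$lags), x$k0))
  cat(sprintf("  upper limit at alpha = %g: %d counts (frequency %.4f)\n",
              x$alpha, x$upper_limit, x$upper_limit / x$n))
  over <- x$lags[x$lags > 0L & x$counts >= x$upper_limit]
  if (length(over))
    cat("  lags at/above the upper limit:", paste(over, collapse = ", "), "\n")
  else cat("  no lag reaches the upper limit\n")
  invisible(x)
}

#' Plot a lag profile
#'
#' Frequency of events of relations against lag, with the zero-lag upper
#' limit drawn as a dotted horizontal line (on the frequency scale,
#' `upper_limit / n`).
#'
#' @param x an `er_profile`.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.er_profile <- function(x, ...) {
  graphics::plot(x$lags, x$frequencies, type = "h", lwd = 2,
                 xlab = "delay (samples)", ylab = "frequency of ER",
                 main = sprintf("%s -> %s", x$cause, x$effect),
                 ylim = c(0, max(x$frequencies, x$upper_limit / x$n) * 1.1),
                 ...)
  graphics::abline(h = x$upper_limit / x$n, lty = 3)
  invisible(x)
}
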