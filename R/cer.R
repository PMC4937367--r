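#' Lag-resolved causal test on events of relations
#'
#' Tests whether the candidate cause `y` drives the candidate effect `x`
#' (direction y -> x) by comparing the coincidence count K_tau at every lag
#' tau = 1..`tau_max` against the zero-lag reference K_0 with a Poisson
#' approximation to the binomial test. The per-lag p-value is the Poisson
#' CDF p_tau = F(K_tau | K_0). Under the increase tail (the default —
#' a cause is normally taken to raise the probability of its effect), lag
#' tau is flagged as positive causality when p_tau > 1 - alpha; under the
#' decrease tail, as negative causality when p_tau < alpha; the two-sided
#' test splits alpha evenly between the tails.
#'
#' Because both counts are plain tallies of joint events, no parametric
#' model of the series themselves is involved, and the test applies
#' unchanged to non-stationary signals.
#'
#' Lag 0 is never reported as causal: simultaneous co-occurrence carries no
#' direction (no information transmission is instantaneous), so K_0 serves
#' as the null reference. When K_0 falls below `min_events` the Poisson
#' reference is meaningless (F(k | 0) = 1 for every k, so everything would
#' be "significant"); the test then returns status `"insufficient-events"`
#' and flags nothing.
#'
#' @param x candidate effect series (binary vector or `event_series`).
#' @param y candidate cause series, aligned with `x`.
#' @param tau_max largest lag scanned, in samples (default 20).
#' @param alpha significance level in (0, 0.5) (default 0.005; with many
#'   scanned lags a small alpha keeps family-wise errors down).
#' @param tail `"increase"` (default), `"decrease"`, or `"two-sided"`.
#' @param overlap_correction if `TRUE`, the Poisson mean at lag tau is
#'   rescaled to K_0 (n - tau) / n to account for the shrinking overlap of
#'   the linear shift; the default `FALSE` compares raw counts, which is
#'   accurate whenever `tau_max` is small relative to `length(x)`.
#' @param bonferroni if `TRUE`, alpha is divided by `tau_max` to correct for
#'   the multiplicity of the lag scan (off by default).
#' @param min_events minimum zero-lag count required to run the test
#'   (default 5).
#' @return an object of class `cer_test`: a list with `direction`
#'   (c(cause, effect) labels), `lags` (1..tau_max), `counts`, `k0`,
#'   `n_eff`, `pvalues`, `significant` (data frame with columns `lag` and
#'   `sign`, +1 positive / -1 negative causality), `status` (`"tested"` or
#'   `"insufficient-events"`), `alpha`, `alpha_effective`, `tail`,
#'   `upper_limit`, `lower_limit`, `n`, and the call parameters.
#' @examples
#' cfg <- two_node_config(p_interaction = 0.6, delay = make_delay("fixed", 4),
#'                        n = 5000, seed = 42)
#' sim <- simulate_network(cfg)
#' cer_test(sim$series$X, sim$series$Y, tau_max = 20, alpha = 0.005)
#' @seealso [bidirectional_scan()] to test both directions at once,
#'   [er_profile()] for the underlying lag profile.
#' @export
cer_test <- function(x, y, tau_max = 20, alpha = 0.005,
                     tail = c("increase", "decrease", "two-sided"),
                     overlap_correction = FALSE, bonferroni = FALSE,
                     min_events = 5) {
  x <- as_event_series(x); y <- as_event_series(y)
  tail <- match.arg(tail)
  n <- check_aligned(x, y)
  check_tau_max(tau_max, n)
  check_alpha(alpha)
  tau_max <- as.integer(tau_max)

  lags <- seq_len(tau_max)
  xv <- unclass(x); yv <- unclass(y)
  k0 <- er_counts(xv, yv, 0L)[[1L]]
  counts <- er_counts(xv, yv, lags)
  n_eff <- n - lags
  lambda <- if (overlap_correction) k0 * n_eff / n else rep(k0, tau_max)
  pvalues <- stats::ppois(counts, lambda)

  alpha_eff <- if (bonferroni) alpha / tau_max else alpha
  status <- if (k0 < min_events) "insufficient-events" else "tested"
  significant <- if (status == "tested")
    sig_lags(pvalues, lags, alpha_eff, tail)
  else data.frame(lag = integer(0), sign = integer(0))

  structure(list(
    direction = c(cause = series_label(y, "y"), effect = series_label(x, "x")),
    lags = lags, counts = counts, k0 = k0, n_eff = n_eff,
    pvalues = pvalues,
    significant = significant,
    status = status,
    alpha = alpha, alpha_effective = alpha_eff, tail = tail,
    overlap_correction = overlap_correction,
    upper_limit = upper_limit(k0, alpha_eff),
    lower_limit = lower_limit(k0, alpha_eff),
    min_events = min_events,
    n = n
  ), class = "cer_test")
}

# internal: significant lag set with sign from per-lag Poisson CDF values
sig_lags <- function(pvalues, lags, alpha, tail) {
  pos <- neg <- logical(length(lags))
  if (tail == "increase") {
    pos <- pvalues > 1 - alpha
  } else if (tail == "decrease") {
    neg <- pvalues < alpha
  } else {
    pos <- pvalues > 1 - alpha / 2
    neg <- pvalues < alpha / 2
  }
  data.frame(lag = c(lags[pos], lags[neg]),
             sign = c(rep(1L, sum(pos)), rep(-1L, sum(neg))))
}

# internal: re-derive the significant set of an existing test at another alpha
# (used by the Monte-Carlo evaluator so one scan serves several alpha levels)
with_alpha <- function(res, alpha) {
  res$alpha <- alpha
  res$alpha_effective <- alpha
  res$significant <- if (res$status == "tested")
    sig_lags(res$pvalues, res$lags, alpha, res$tail)
  else data.frame(lag = integer(0), sign = integer(0))
  res
}

#' @export
print.cer_test <- function(x, ...) {
  cat(sprintf("CER test: %s -> %s  (n = %d, lags 1..%d, alpha = %g, %s tail)\n",
              x$direction[["cause"]], x$direction[["effect"]],
              x$n, max(x$lags), x$alpha, x$tail))
  cat(sprintf("  K_0 = %d (upper limit %d)\n", x$k0, x$upper_limit))
  if (x$status == "insufficient-events") {
    cat(sprintf("  status: insufficient events (K_0 < %d); no test performed\n",
                x$min_events))
  } else if (nrow(x$significant) == 0L) {
    cat("  no significant lags: no evidence of causality in this direction\n")
  } else {
    s <- x$significant
    lab <- ifelse(s$sign > 0, "+", "-")
    cat("  significant lags:",
        paste(sprintf("%d (%s)", s$lag, lab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarize a CER test as a per-lag table
#'
#' @param object a `cer_test`.
#' @param ... ignored.
#' @return a data frame with one row per lag: `lag`, `count`, `n_eff`,
#'   `frequency`, `pvalue`, `significant` (signed integer, 0 when not
#'   flagged).
#' @export
summary.cer_test <- function(object, ...) {
  sig <- integer(length(object$lags))
  if (nrow(object$significant))
    sig[match(object$significant$lag, object$lags)] <- object$significant$sign
  out <- data.frame(
    lag = object$lags,
    count = object$counts,
    n_eff = object$n_eff,
    frequency = object$counts / object$n_eff,
    pvalue = object$pvalues,
    significant = sig
  )
  attr(out, "k0") <- object$k0
  attr(out, "status") <- object$status
  class(out) <- c("summary.cer_test", "data.frame")
  out
}

#' @export
plot.cer_test <- function(x, ...) {
  freq <- c(x$k0 / x$n, x$counts / x$n_eff)
  graphics::plot(c(0L, x$lags), freq, type = "h", lwd = 2,
                 xlab = "delay (samples)", ylab = "frequency of ER",
                 main = sprintf("%s -> %s", x$direction[["cause"]],
                                x$direction[["effect"]]),
                 ylim = c(0, max(freq, x$upper_limit / x$n) * 1.1), ...)
  graphics::abline(h = x$upper_limit / x$n, lty = 3)
  if (nrow(x$significant))
    graphics::points(x$significant$lag,
                     (x$counts / x$n_eff)[x$significant$lag], pch = 19)
  invisible(x)
}

#' Bidirectional lag scan of a pair of event series
#'
#' Runs [cer_test()] in both directions of the pair `(a, b)` with identical
#' parameters and presents them as one profile over lags
#' `-tau_max .. +tau_max`. The zero-lag count is shared between the two
#' directions (joint occurrence without delay is symmetric). Following the
#' convention used for directed-pair figures, the count at negative lag
#' -tau is `count_er(b, a, tau)` — i.e. the `a -> b` direction (`a` leading)
#' occupies the negative side of the axis, and `b -> a` the positive side.
#'
#' @param a,b aligned event series.
#' @inheritParams cer_test
#' @return an object of class `cer_scan`: list with `forward`
#'   (`cer_test` for a -> b), `reverse` (b -> a), `pair` labels, shared
#'   `k0`, combined `lags` (-tau_max..tau_max) and `counts`, `alpha`,
#'   `tail`, `upper_limit`, `n`.
#' @examples
#' cfg <- two_node_config(p_interaction = 0.6, delay = make_delay("fixed", 4),
#'                        n = 5000, seed = 7)
#' sim <- simulate_network(cfg)
#' sc <- bidirectional_scan(sim$series$Y, sim$series$X, tau_max = 10)
#' sc
#' @export
bidirectional_scan <- function(a, b, tau_max = 20, alpha = 0.005,
                               tail = c("increase", "decrease", "two-sided"),
                               overlap_correction = FALSE, bonferroni = FALSE,
                               min_events = 5) {
  a <- as_event_series(a); b <- as_event_series(b)
  tail <- match.arg(tail)
  forward <- cer_test(b, a, tau_max = tau_max, alpha = alpha, tail = tail,
                      overlap_correction = overlap_correction,
                      bonferroni = bonferroni, min_events = min_events)
  reverse <- cer_test(a, b, tau_max = tau_max, alpha = alpha, tail = tail,
                      overlap_correction = overlap_correction,
                      bonferroni = bonferroni, min_events = min_events)
  tau_max <- as.integer(tau_max)
  structure(list(
    pair = c(a = series_label(a, "a"), b = series_label(b, "b")),
    forward = forward,   # a -> b (a as cause), negative-lag side
    reverse = reverse,   # b -> a (b as cause), positive-lag side
    k0 = forward$k0,
    lags = seq.int(-tau_max, tau_max),
    counts = c(rev(forward$counts), forward$k0, reverse$counts),
    alpha = alpha, tail = tail,
    upper_limit = forward$upper_limit,
    n = forward$n
  ), class = "cer_scan")
}

#' @export
print.cer_scan <- function(x, ...) {
  cat(sprintf("Bidirectional CER scan of pair (%s, %s), alpha = %g\n",
              x$pair[["a"]], x$pair[["b"]], x$alpha))
  cat(sprintf("  shared K_0 = %d (upper limit %d)\n", x$k0, x$upper_limit))
  dirline <- function(res) {
    if (res$status == "insufficient-events") return("insufficient events")
    if (nrow(res$significant) == 0L) return("no significant lags")
    s <- res$significant
    paste(sprintf("%d (%s)", s$lag, ifelse(s$sign > 0, "+", "-")),
          collapse = ", ")
  }
  cat(sprintf("  %s -> %s: %s\n", x$pair[["a"]], x$pair[["b"]],
              dirline(x$forward)))
  cat(sprintf("  %s -> %s: %s\n", x$pair[["b"]], x$pair[["a"]],
              dirline(x$reverse)))
  invisible(x)
}

#' @export
plot.cer_scan <- function(x, ...) {
  n_eff <- x$n - abs(x$lags)
  freq <- x$counts / n_eff
  graphics::plot(x$lags, freq, type = "h", lwd = 2,
                 xlab = sprintf("delay (samples); negative: %s leads",
                                x$pair[["a"]]),
                 ylab = "frequency of ER",
                 main = sprintf("pair (%s, %s)", x$pair[["a"]], x$pair[["b"]]),
                 ylim = c(0, max(freq, x$upper_limit / x$n) * 1.1), ...)
  graphics::abline(h = x$upper_limit / x$n, lty = 3)
  graphics::abline(v = 0, col = "grey", lty = 2)
  invisible(x)
}
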