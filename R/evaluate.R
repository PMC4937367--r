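#' Outcome labels for Monte-Carlo evaluation
#'
#' The six mutually exclusive outcomes of one replicate of a directed-pair
#' test, given the ground truth:
#' for a truly causal pair, `strongly_correct` (detection in the right
#' direction with every flagged lag inside the true delay support),
#' `weakly_correct` (right direction but some flagged lag outside the
#' support), `missing_detection` (no detection in either direction) and
#' `error_type_I` (detection in the wrong direction — this dominates any
#' simultaneous correct-direction detection so that the categories stay
#' mutually exclusive); for a truly non-causal pair, `error_type_II` (any
#' detection at all) and `true_negative`.
#'
#' @return character vector of the six labels, in canonical order.
#' @export
outcome_levels <- function() {
  c("strongly_correct", "weakly_correct", "missing_detection",
    "error_type_I", "error_type_II", "true_negative")
}

#' Classify one replicate against its ground truth
#'
#' @param forward [cer_test()] result for the true (or nominal forward)
#'   causal direction.
#' @param reverse [cer_test()] result for the opposite direction, computed
#'   with identical `alpha` and `tau_max`.
#' @param truth ground-truth record: a list with `causal` (logical) and,
#'   for causal truth, `support` (integer vector of true delay lags).
#' @return one of [outcome_levels()].
#' @examples
#' cfg <- two_node_config(p_interaction = 0.6,
#'                        delay = make_delay("fixed", 4), seed = 3)
#' sim <- simulate_network(cfg)
#' fwd <- cer_test(sim$series$X, sim$series$Y)
#' rev <- cer_test(sim$series$Y, sim$series$X)
#' classify_outcome(fwd, rev, truth = list(causal = TRUE, support = 4))
#' @export
classify_outcome <- function(forward, reverse, truth) {
  if (!inherits(forward, "cer_test") || !inherits(reverse, "cer_test"))
    stop("'forward' and 'reverse' must be cer_test results", call. = FALSE)
  if (!isTRUE(all.equal(forward$alpha_effective, reverse$alpha_effective)) ||
      !identical(forward$lags, reverse$lags))
    stop("forward and reverse tests must use identical alpha and tau_max",
         call. = FALSE)
  if (is.null(truth) || is.null(truth$causal))
    stop("'truth' must be a list with at least element 'causal'",
         call. = FALSE)
  fwd_lags <- forward$significant$lag
  rev_any <- nrow(reverse$significant) > 0L
  if (isTRUE(truth$causal)) {
    if (is.null(truth$support))
      stop("causal ground truth requires the true delay 'support'",
           call. = FALSE)
    if (rev_any) return("error_type_I")
    if (length(fwd_lags) == 0L) return("missing_detection")
    if (all(fwd_lags %in% truth$support)) return("strongly_correct")
    return("weakly_correct")
  }
  if (length(fwd_lags) > 0L || rev_any) return("error_type_II")
  "true_negative"
}

#' Monte-Carlo evaluation of detection and error rates
#'
#' Simulates `n_reps` independent two-node replicates for every interaction
#' level, runs the bidirectional lag scan once per replicate, classifies the
#' outcome at every requested `alpha` (the per-lag Poisson CDF values do not
#' depend on alpha, so one scan serves all levels), and aggregates outcome
#' rates per (alpha, interaction) cell. An interaction level of 0 simulates
#' the companion null scenario: ground truth is non-causal and the
#' applicable outcomes are `error_type_II` / `true_negative`.
#'
#' @param delay a [delay_distribution()] shared by all causal replicates.
#' @param interaction_levels numeric vector of interaction probabilities
#'   (0 allowed, meaning a non-causal control cell).
#' @param alphas significance levels to evaluate.
#' @param n_reps replicates per (interaction) level.
#' @param p_base constant base probability or [random_walk_spec()].
#' @param n series length per replicate.
#' @param tau_max largest scanned lag.
#' @param tail test tail (see [cer_test()]).
#' @param seed integer seed making the whole experiment reproducible.
#' @return an object of classes `cer_evaluation` and `data.frame`: one row
#'   per (alpha, interaction, outcome) with columns `alpha`,
#'   `p_interaction`, `outcome`, `count`, `rate`, `n_reps`. Rates sum to 1
#'   within each (alpha, interaction) cell. Attributes record the seed and
#'   scenario parameters.
#' @examples
#' rep <- run_experiment(make_delay("fixed", 4),
#'                       interaction_levels = c(0, 0.6),
#'                       alphas = 0.005, n_reps = 20, n = 2000, seed = 1)
#' subset(rep, rate > 0)
#' @export
run_experiment <- function(delay,
                           interaction_levels = c(0.2, 0.4, 0.6, 0.8),
                           alphas = c(0.05, 0.005, 0.0005),
                           n_reps = 2000,
                           p_base = 0.3, n = 5000, tau_max = 20,
                           tail = "increase", seed = NULL) {
  if (!inherits(delay, "delay_distribution"))
    stop("'delay' must be a delay_distribution", call. = FALSE)
  if (!is.numeric(n_reps) || n_reps < 1)
    stop("'n_reps' must be a positive integer", call. = FALSE)
  for (a in alphas) check_alpha(a)
  n_reps <- as.integer(n_reps)
  levels <- outcome_levels()

  counts <- array(0L,
                  dim = c(length(alphas), length(interaction_levels),
                          length(levels)),
                  dimnames = list(alpha = alphas,
                                  p_interaction = interaction_levels,
                                  outcome = levels))
  with_seed(seed, {
    for (j in seq_along(interaction_levels)) {
      p_int <- interaction_levels[j]
      truth <- if (p_int > 0)
        list(causal = TRUE, support = delay$support)
      else list(causal = FALSE)
      for (r in seq_len(n_reps)) {
        cfg <- two_node_config(p_base = p_base, p_interaction = p_int,
                               delay = delay, n = n, seed = NULL)
        sim <- simulate_network(cfg)
        scan <- bidirectional_scan(sim$series$Y, sim$series$X,
                                   tau_max = tau_max, alpha = alphas[1],
                                   tail = tail)
        for (i in seq_along(alphas)) {
          fwd <- with_alpha(scan$forward, alphas[i])
          rev <- with_alpha(scan$reverse, alphas[i])
          out <- classify_outcome(fwd, rev, truth)
          counts[i, j, out] <- counts[i, j, out] + 1L
        }
      }
    }
  })
  report <- expand.grid(alpha = alphas, p_interaction = interaction_levels,
                        outcome = levels, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  report$count <- as.vector(counts)
  report$rate <- report$count / n_reps
  report$n_reps <- n_reps
  structure(report,
            class = c("cer_evaluation", "data.frame"),
            seed = seed, n = n, tau_max = tau_max, tail = tail,
            delay = delay)
}

#' @export
print.cer_evaluation <- function(x, ...) {
  cat(sprintf("Monte-Carlo CER evaluation: %d replicates per cell\n",
              x$n_reps[1L]))
  shown <- x[x$rate > 0, c("alpha", "p_interaction", "outcome", "rate")]
  rownames(shown) <- NULL
  print.data.frame(shown, ...)
  invisible(x)
}

#' Plot outcome rates as grouped bars
#'
#' One panel of stacked outcome rates per alpha level, with one bar per
#' interaction probability.
#'
#' @param x a `cer_evaluation`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.cer_evaluation <- function(x, ...) {
  alphas <- unique(x$alpha)
  old <- graphics::par(mfrow = c(1, length(alphas)))
  on.exit(graphics::par(old))
  for (a in alphas) {
    sub <- x[x$alpha == a, ]
    m <- tapply(sub$rate, list(sub$outcome, sub$p_interaction), sum)
    m <- m[outcome_levels(), , drop = FALSE]
    graphics::barplot(m, main = sprintf("alpha = %g", a),
                      xlab = "interaction probability", ylab = "rate",
                      legend.text = (a == alphas[1L]), ...)
  }
  invisible(x)
}

#' Sliding-window entropy of an event series
#'
#' Shannon entropy (bits) of the in-window event fraction q:
#' H = -q log2(q) - (1-q) log2(1-q), with H = 0 at q = 0 or 1, computed in
#' a window slid one sample at a time. A diagnostic for time-varying firing
#' probability: for non-stationary series the entropy wanders, and shorter
#' windows track the fluctuations more erratically.
#'
#' @param x event series (binary vector or `event_series`).
#' @param window window length in samples (positive, `<= length(x)`).
#' @return numeric vector of length `length(x) - window + 1`; element i is
#'   the entropy of the window starting at sample i. Attribute `"window"`
#'   records the window length.
#' @examples
#' windowed_entropy(rep(c(0, 1), 50), window = 10)[1]  # 1 bit
#' @export
windowed_entropy <- function(x, window) {
  x <- as_event_series(x)
  n <- length(x)
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window != floor(window))
    stop("'window' must be a single positive integer", call. = FALSE)
  if (window > n)
    stop(sprintf("'window' (%d) exceeds the series length (%d)",
                 as.integer(window), n), call. = FALSE)
  cs <- c(0, cumsum(unclass(x)))
  q <- (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
  h <- numeric(length(q))
  inner <- q > 0 & q < 1
  qi <- q[inner]
  h[inner] <- -qi * log2(qi) - (1 - qi) * log2(1 - qi)
  attr(h, "window") <- as.integer(window)
  h
}

#' Non-stationarity diagnostic for a probability or event series
#'
#' Runs the augmented Dickey-Fuller unit-root test ([adf_test()]) and
#' translates it into a stationarity verdict. The unit-root hypothesis is
#' the ADF *null*, so failing to reject it (p > 0.05) is the evidence that
#' the series behaves like an integrated, non-stationary process; rejecting
#' it certifies stationarity. Constant series are reported as
#' `"degenerate"` (the test is undefined).
#'
#' @param x numeric series: either a time-varying probability trajectory or
#'   a binary event series (length >= 20).
#' @param alpha rejection level for the unit-root null (default 0.05).
#' @return a list of class `nonstationarity_check` with `statistic`,
#'   `p.value`, `verdict` (`"non-stationary"`, `"stationary"` or
#'   `"degenerate"`) and the lag order used.
#' @examples
#' p <- random_walk_probability(2000, seed = 1)
#' nonstationarity_check(p)$verdict
#' @export
nonstationarity_check <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  if (length(x) < 20L)
    stop("series too short (need length >= 20)", call. = FALSE)
  if (stats::sd(x) == 0) {
    return(structure(list(statistic = NA_real_, p.value = NA_real_,
                          lag_order = NA_integer_, verdict = "degenerate"),
                     class = "nonstationarity_check"))
  }
  t <- adf_test(x)
  structure(list(statistic = unname(t$statistic),
                 p.value = t$p.value,
                 lag_order = unname(t$parameter),
                 verdict = if (t$p.value > alpha) "non-stationary"
                           else "stationary"),
            class = "nonstationarity_check")
}

#' @export
print.nonstationarity_check <- function(x, ...) {
  if (x$verdict == "degenerate") {
    cat("Non-stationarity check: constant series (degenerate)\n")
  } else {
    cat(sprintf(
      "Non-stationarity check: ADF = %.3f, p = %.3f, lag order %d -> %s\n",
      x$statistic, x$p.value, x$lag_order, x$verdict))
  }
  invisible(x)
}
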