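#' Discrete delay distributions for simulated interactions
#'
#' A delay distribution assigns probabilities to positive integer lags (in
#' samples). Every source firing in [simulate_network()] draws its own delay
#' from this distribution, so a single run shows coincidence mass at every
#' supported lag. `make_delay()` builds the shapes used throughout the
#' package's simulation studies:
#'
#' * `"fixed"` — a single atom at `tau`;
#' * `"uniform"` — equal mass on `range[1]..range[2]` (default 1..100, the
#'   wide "arbitrary delay" control in which no single lag should stand out);
#' * `"bimodal"` — two atoms (default lags 2 and 5, mass 0.5 each);
#' * `"gaussian"` — an explicit discrete bell, e.g. support {2,3,4,5,6} with
#'   probabilities {0.015, 0.21, 0.55, 0.21, 0.015}.
#'
#' @param kind one of `"fixed"`, `"uniform"`, `"bimodal"`, `"gaussian"`.
#' @param tau atom for `kind = "fixed"`.
#' @param range integer length-2 vector for `kind = "uniform"`.
#' @param support integer lags for `"bimodal"` / `"gaussian"`.
#' @param probabilities matching probabilities for `"gaussian"` (must sum
#'   to 1); `"bimodal"` always uses equal mass.
#' @return an object of class `delay_distribution`.
#' @examples
#' make_delay("fixed", tau = 4)
#' make_delay("gaussian", support = 2:6,
#'            probabilities = c(0.015, 0.21, 0.55, 0.21, 0.015))
#' @export
make_delay <- function(kind = c("fixed", "uniform", "bimodal", "gaussian"),
                       tau = NULL, range = c(1L, 100L),
                       support = c(2L, 5L), probabilities = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    fixed = {
      if (is.null(tau)) stop("'tau' is required for a fixed delay",
                             call. = FALSE)
      delay_distribution(tau, 1)
    },
    uniform = {
      if (length(range) != 2L || range[1] > range[2])
        stop("'range' must be c(min, max) with min <= max", call. = FALSE)
      s <- seq.int(range[1], range[2])
      delay_distribution(s, rep(1 / length(s), length(s)))
    },
    bimodal = delay_distribution(support,
                                 rep(1 / length(support), length(support))),
    gaussian = {
      if (is.null(probabilities))
        stop("'probabilities' are required for a gaussian delay",
             call. = FALSE)
      delay_distribution(support, probabilities)
    }
  )
}

#' @rdname make_delay
#' @export
delay_distribution <- function(support, probabilities) {
  if (!is.numeric(support) || length(support) < 1L || anyNA(support) ||
      any(support < 1) || any(support != floor(support)))
    stop("delay support must be positive integer lags", call. = FALSE)
  if (anyDuplicated(support))
    stop("delay support must not contain duplicates", call. = FALSE)
  if (length(probabilities) != length(support) || anyNA(probabilities) ||
      any(probabilities < 0))
    stop("'probabilities' must be non-negative and match the support",
         call. = FALSE)
  if (abs(sum(probabilities) - 1) > 1e-12)
    stop("delay probabilities must sum to 1", call. = FALSE)
  structure(list(support = as.integer(support),
                 probabilities = as.numeric(probabilities)),
            class = "delay_distribution")
}

#' @export
print.delay_distribution <- function(x, ...) {
  cat("Delay distribution (samples):\n")
  print(stats::setNames(x$probabilities, x$support))
  invisible(x)
}

# internal: one delay per source firing
draw_delays <- function(delay, n) {
  if (length(delay$support) == 1L) return(rep(delay$support, n))
  sample(delay$support, n, replace = TRUE, prob = delay$probabilities)
}

#' Random-walk specification for a non-stationary event probability
#'
#' Describes a bounded Gaussian random walk used as a time-varying firing
#' probability: p\[t\] = reflect(p\[t-1\] + e_t) with e_t ~ N(0, step_sd^2),
#' reflected at the bounds. The defaults (initial 0.3, step sd 0.005 per
#' sample, bounds \[0.05, 0.6\]) produce slowly wandering rates whose
#' unit-root character is confirmed by [nonstationarity_check()].
#'
#' @param initial starting probability, inside `bounds`.
#' @param step_sd standard deviation of the per-sample Gaussian step;
#'   0 gives a constant series.
#' @param bounds length-2 vector `c(lo, hi)` with `0 <= lo < hi <= 1`.
#' @return an object of class `random_walk_spec`.
#' @export
random_walk_spec <- function(initial = 0.3, step_sd = 0.005,
                             bounds = c(0.05, 0.6)) {
  if (length(bounds) != 2L || anyNA(bounds) ||
      bounds[1] < 0 || bounds[2] > 1 || bounds[1] >= bounds[2])
    stop("'bounds' must satisfy 0 <= lo < hi <= 1", call. = FALSE)
  if (length(initial) != 1L || is.na(initial) ||
      initial < bounds[1] || initial > bounds[2])
    stop("'initial' must lie inside the bounds", call. = FALSE)
  if (length(step_sd) != 1L || is.na(step_sd) || step_sd < 0)
    stop("'step_sd' must be non-negative", call. = FALSE)
  structure(list(initial = initial, step_sd = step_sd, bounds = bounds),
            class = "random_walk_spec")
}

#' Generate a reflected random-walk probability series
#'
#' @param n series length in samples.
#' @param spec a [random_walk_spec()].
#' @param seed optional integer seed; when given the global RNG state is
#'   left untouched.
#' @return numeric vector of length `n`, every value inside the bounds.
#' @examples
#' p <- random_walk_probability(10000, random_walk_spec(), seed = 1)
#' range(p)
#' @export
random_walk_probability <- function(n, spec = random_walk_spec(),
                                    seed = NULL) {
  if (!inherits(spec, "random_walk_spec")) spec <- do.call(random_walk_spec, spec)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n))
    stop("'n' must be a positive integer", call. = FALSE)
  with_seed(seed, {
    if (spec$step_sd == 0) {
      rep(spec$initial, n)
    } else {
      walk <- spec$initial + cumsum(stats::rnorm(n, 0, spec$step_sd))
      reflect_into(walk, spec$bounds[1], spec$bounds[2])
    }
  })
}

# internal: fold an unconstrained walk into [lo, hi] by reflection at the
# boundaries (triangle-wave identity: exact for any overshoot size)
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  z <- (x - lo) %% (2 * w)
  lo + pmin(z, 2 * w - z)
}

#' Node and interaction specifications for the interaction simulator
#'
#' `node_spec()` describes one node: its label and its base (spontaneous)
#' event probability, either a constant in \[0, 1\] or a
#' [random_walk_spec()] for non-stationary firing. `interaction_spec()`
#' describes one directed link: when the source node fires at time t, the
#' target is forced to 1 at time t + d with probability `p_interaction`,
#' where d is drawn per firing from the link's delay distribution.
#'
#' @param label node name.
#' @param base_probability constant probability or a [random_walk_spec()].
#' @return `node_spec`: an object of class `node_spec`.
#' @export
node_spec <- function(label, base_probability = 0.3) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("'label' must be a non-empty string", call. = FALSE)
  if (!inherits(base_probability, "random_walk_spec")) {
    if (!is.numeric(base_probability) || length(base_probability) != 1L ||
        is.na(base_probability) ||
        base_probability < 0 || base_probability > 1)
      stop("constant 'base_probability' must lie in [0, 1]", call. = FALSE)
  }
  structure(list(label = label, base_probability = base_probability),
            class = "node_spec")
}

#' @rdname node_spec
#' @param source,target labels of the linked nodes (must differ).
#' @param p_interaction probability in \[0, 1\] that a source firing induces
#'   a target event after the drawn delay.
#' @param delay a [delay_distribution()] (or [make_delay()] result).
#' @return `interaction_spec`: an object of class `interaction_spec`.
#' @export
interaction_spec <- function(source, target, p_interaction, delay) {
  if (!is.character(source) || !is.character(target) ||
      length(source) != 1L || length(target) != 1L)
    stop("'source' and 'target' must be single labels", call. = FALSE)
  if (identical(source, target))
    stop("self-interactions are not allowed (source == target)",
         call. = FALSE)
  if (!is.numeric(p_interaction) || length(p_interaction) != 1L ||
      is.na(p_interaction) || p_interaction < 0 || p_interaction > 1)
    stop("'p_interaction' must lie in [0, 1]", call. = FALSE)
  if (!inherits(delay, "delay_distribution"))
    stop("'delay' must be a delay_distribution (see make_delay())",
         call. = FALSE)
  structure(list(source = source, target = target,
                 p_interaction = p_interaction, delay = delay),
            class = "interaction_spec")
}

#' Simulation configuration
#'
#' Bundles nodes, directed interactions, series length and seed. The
#' directed graph over the interactions must be acyclic (parallel links
#' between the same ordered pair are allowed, e.g. two links at different
#' fixed delays).
#'
#' @param nodes list of [node_spec()] objects.
#' @param interactions list of [interaction_spec()] objects (possibly empty).
#' @param n series length in samples.
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(nodes, interactions = list(), n = 5000, seed = NULL) {
  if (inherits(nodes, "node_spec")) nodes <- list(nodes)
  if (inherits(interactions, "interaction_spec"))
    interactions <- list(interactions)
  if (!length(nodes) || !all(vapply(nodes, inherits, TRUE, "node_spec")))
    stop("'nodes' must be a non-empty list of node_spec objects",
         call. = FALSE)
  labels <- vapply(nodes, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("node labels must be unique", call. = FALSE)
  if (!all(vapply(interactions, inherits, TRUE, "interaction_spec")))
    stop("'interactions' must be interaction_spec objects", call. = FALSE)
  for (ia in interactions)
    if (!all(c(ia$source, ia$target) %in% labels))
      stop(sprintf("interaction %s -> %s references an unknown node",
                   ia$source, ia$target), call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n))
    stop("'n' must be a positive integer", call. = FALSE)
  order <- topo_order(labels, interactions)  # errors on a cycle
  structure(list(nodes = nodes, interactions = interactions,
                 n = as.integer(n), seed = seed, order = order),
            class = "sim_config")
}

# internal: Kahn topological sort; errors if the interaction graph is cyclic
topo_order <- function(labels, interactions) {
  src <- vapply(interactions, `[[`, "", "source")
  tgt <- vapply(interactions, `[[`, "", "target")
  indeg <- stats::setNames(integer(length(labels)), labels)
  for (t in tgt) indeg[t] <- indeg[t] + 1L
  order <- character(0)
  queue <- labels[indeg == 0L]
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    out <- which(src == v)
    for (i in out) {
      indeg[tgt[i]] <- indeg[tgt[i]] - 1L
      if (indeg[tgt[i]] == 0L) queue <- c(queue, tgt[i])
    }
    src[out] <- NA_character_
  }
  if (length(order) != length(labels))
    stop("the interaction graph contains a cycle; only acyclic networks can be simulated",
         call. = FALSE)
  order
}

#' Two-node cause/effect configuration
#'
#' Convenience wrapper for the canonical two-node benchmark: cause node `Y`
#' drives effect node `X` through a single directed link. Both nodes share
#' the same base-probability specification.
#'
#' @param p_base constant base probability or a [random_walk_spec()]
#'   (default 0.3, the stationary benchmark rate).
#' @param p_interaction interaction probability of the Y -> X link; 0 gives
#'   a non-causal (independent) pair.
#' @param delay a [delay_distribution()]; ignored when `p_interaction = 0`.
#' @param n series length (default 5000).
#' @param seed integer seed.
#' @return a [sim_config()] with nodes `Y` (cause) and `X` (effect).
#' @export
two_node_config <- function(p_base = 0.3, p_interaction = 0.6,
                            delay = make_delay("fixed", tau = 4),
                            n = 5000, seed = NULL) {
  nodes <- list(node_spec("Y", p_base), node_spec("X", p_base))
  interactions <- if (p_interaction > 0)
    list(interaction_spec("Y", "X", p_interaction, delay))
  else list()
  sim_config(nodes, interactions, n = n, seed = seed)
}

#' Simulate a network of interacting binary event series
#'
#' Implements the discrete spike-interaction model: at every sample t each
#' node fires spontaneously with its base probability p\[t\] (constant or a
#' reflected random walk), and every firing of a source node independently
#' draws a delay d from the link's delay distribution and, with the link's
#' interaction probability, forces the target to 1 at t + d. Induced events
#' landing on an existing 1 are idempotent, and events induced beyond the
#' end of the series are discarded. Nodes are processed in topological
#' order, so induced events propagate along directed paths within a run.
#'
#' @param config a [sim_config()].
#' @return a list with components
#'   * `series`: named list of `event_series`, one per node;
#'   * `truth`: ground-truth record — a list with `interactions` (a data
#'     frame with columns `source`, `target`, `p_interaction`) and
#'     `delays` (list of delay supports per interaction);
#'   * `base_probabilities`: named list of the realized per-sample base
#'     probability vectors (constants are stored as length-1);
#'   * `config`: the input configuration.
#' @examples
#' cfg <- two_node_config(p_interaction = 0.6,
#'                        delay = make_delay("bimodal", support = c(2, 5)),
#'                        n = 5000, seed = 11)
#' sim <- simulate_network(cfg)
#' sim$truth$interactions
#' @export
simulate_network <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("'config' must be a sim_config object", call. = FALSE)
  n <- config$n
  labels <- vapply(config$nodes, `[[`, "", "label")
  with_seed(config$seed, {
    series <- vector("list", length(labels))
    names(series) <- labels
    base_p <- vector("list", length(labels))
    names(base_p) <- labels
    # spontaneous firing, node by node in config order (deterministic draws)
    for (nd in config$nodes) {
      bp <- nd$base_probability
      if (inherits(bp, "random_walk_spec")) {
        p <- random_walk_probability(n, bp)
        base_p[[nd$label]] <- p
      } else {
        p <- bp
        base_p[[nd$label]] <- bp
      }
      series[[nd$label]] <- as.integer(stats::runif(n) < p)
    }
    # induced events, in topological order so they cascade along paths
    for (v in config$order) {
      incoming <- Filter(function(ia) ia$target == v, config$interactions)
      for (ia in incoming) {
        src_events <- which(series[[ia$source]] == 1L)
        if (!length(src_events)) next
        d <- draw_delays(ia$delay, length(src_events))
        hit <- stats::runif(length(src_events)) < ia$p_interaction
        landing <- src_events[hit] + d[hit]
        landing <- landing[landing <= n]
        if (length(landing)) series[[v]][landing] <- 1L
      }
    }
    truth <- list(
      interactions = data.frame(
        source = vapply(config$interactions, `[[`, "", "source"),
        target = vapply(config$interactions, `[[`, "", "target"),
        p_interaction = vapply(config$interactions, `[[`, 0, "p_interaction")
      ),
      delays = lapply(config$interactions, `[[`, "delay")
    )
    list(series = mapply(event_series, series, labels,
                         SIMPLIFY = FALSE),
         truth = truth,
         base_probabilities = base_p,
         config = config)
  })
}

# internal: evaluate expr under a locally seeded RNG, restoring global state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
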