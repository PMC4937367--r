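test_that("make_delay builds the documented shapes", {
  f <- make_delay("fixed", tau = 4)
  expect_identical(f$support, 4L)
  expect_identical(f$probabilities, 1)

  u <- make_delay("uniform", range = c(1, 100))
  expect_identical(u$support, 1:100)
  expect_equal(u$probabilities, rep(0.01, 100))

  b <- make_delay("bimodal")
  expect_identical(b$support, c(2L, 5L))
  expect_equal(b$probabilities, c(0.5, 0.5))

  g <- make_delay("gaussian", support = 2:6,
                  probabilities = c(0.015, 0.21, 0.55, 0.21, 0.015))
  expect_equal(sum(g$probabilities), 1)
})

test_that("delay distributions are validated", {
  expect_error(delay_distribution(0:2, rep(1/3, 3)), "positive integer")
  expect_error(delay_distribution(c(2, 5), c(0.5, 0.6)), "sum to 1")
  expect_error(delay_distribution(c(2, 2), c(0.5, 0.5)), "duplicates")
  expect_error(make_delay("gaussian", support = 2:3), "probabilities")
})

test_that("random-walk probabilities respect bounds, initial value and seed", {
  spec <- random_walk_spec(initial = 0.3, step_sd = 0.005,
                           bounds = c(0.05, 0.6))
  p <- random_walk_probability(10000, spec, seed = 1)
  expect_true(all(p >= 0.05 & p <= 0.6))
  expect_identical(p, random_walk_probability(10000, spec, seed = 1))

  # zero step scale degenerates to a constant at the initial value
  flat <- random_walk_probability(50, random_walk_spec(step_sd = 0), seed = 2)
  expect_identical(flat, rep(0.3, 50))

  expect_error(random_walk_spec(bounds = c(0.7, 0.2)), "lo < hi")
  expect_error(random_walk_spec(initial = 0.9, bounds = c(0, 0.5)),
               "inside the bounds")
})

test_that("random-walk trajectories behave like unit-root processes", {
  # boundary reflections add a little mean reversion, so a bounded walk can
  # occasionally reject the unit root; require a large majority, not all
  hits <- 0L
  for (seed in 1:10) {
    p <- random_walk_probability(10000, seed = seed)
    if (nonstationarity_check(p)$verdict == "non-stationary")
      hits <- hits + 1L
  }
  expect_gte(hits, 7L)
})

test_that("simulation is reproducible and respects degenerate configs", {
  cfg <- two_node_config(p_interaction = 0.5, n = 800, seed = 77)
  s1 <- simulate_network(cfg)
  s2 <- simulate_network(cfg)
  expect_identical(s1$series, s2$series)

  silent <- sim_config(list(node_spec("A", 0)), n = 200, seed = 1)
  expect_identical(sum(simulate_network(silent)$series$A), 0L)
})

test_that("marginal rates match the configured probabilities", {
  sim <- simulate_network(sim_config(list(node_spec("A", 0.3)),
                                     n = 5000, seed = 5))
  rate <- mean(unclass(sim$series$A))
  expect_lt(abs(rate - 0.3), 4 * sqrt(0.3 * 0.7 / 5000))
})

test_that("induction only adds events (rate conservation)", {
  base_cfg <- two_node_config(p_interaction = 0, n = 4000, seed = 42)
  driven_cfg <- two_node_config(p_interaction = 0.8, n = 4000, seed = 42)
  base <- simulate_network(base_cfg)
  driven <- simulate_network(driven_cfg)
  # same seed: spontaneous draws coincide, induced events only set 1s
  expect_true(all(unclass(driven$series$X) >= unclass(base$series$X)))
  expect_identical(driven$series$Y, base$series$Y)
})

test_that("independent nodes show cross-coincidences at chance level", {
  sim <- simulate_network(two_node_config(p_interaction = 0, n = 20000,
                                          seed = 8))
  x <- sim$series$X; y <- sim$series$Y
  expected <- mean(x) * mean(y)
  for (tau in c(0L, 3L, 9L)) {
    k <- count_er(x, y, tau)
    n_eff <- 20000 - tau
    se <- sqrt(expected * (1 - expected) / n_eff)
    expect_lt(abs(k / n_eff - expected), 4 * se)
  }
})

test_that("fixed-delay simulations place the coincidence mode at the design lag", {
  for (tau_true in c(2L, 6L)) {
    s <- sim_pair(0.5, make_delay("fixed", tau_true), n = 5000,
                  seed = 100 + tau_true)
    counts <- vapply(1:10, function(tau) count_er(s$x, s$y, tau), 0L)
    expect_identical(which.max(counts), as.integer(tau_true))
  }
})

test_that("per-event delay draws spread mass over the support in one run", {
  s <- sim_pair(0.6, make_delay("bimodal", support = c(2L, 5L)),
                n = 8000, seed = 9)
  counts <- vapply(1:8, function(tau) count_er(s$x, s$y, tau), 0L)
  baseline <- stats::median(counts[-c(2, 5)])
  expect_gt(counts[2], baseline * 1.15)
  expect_gt(counts[5], baseline * 1.15)
})

test_that("cyclic interaction graphs are rejected", {
  d <- make_delay("fixed", 2)
  nodes <- list(node_spec("A"), node_spec("B"))
  cyc <- list(interaction_spec("A", "B", 0.5, d),
              interaction_spec("B", "A", 0.5, d))
  expect_error(sim_config(nodes, cyc, n = 100), "cycle")
  expect_error(interaction_spec("A", "A", 0.5, d), "source == target")
})

test_that("parallel links (bilateral effect) raise mass at both delays", {
  d4 <- make_delay("fixed", 4); d6 <- make_delay("fixed", 6)
  cfg <- sim_config(
    list(node_spec("Y", 0.3), node_spec("X", 0.3)),
    list(interaction_spec("Y", "X", 0.3, d4),
         interaction_spec("Y", "X", 0.3, d6)),
    n = 8000, seed = 10)
  sim <- simulate_network(cfg)
  res <- cer_test(sim$series$X, sim$series$Y, tau_max = 10, alpha = 0.005)
  expect_true(all(c(4L, 6L) %in% res$significant$lag))
})

test_that("events induced past the end of the series are discarded", {
  # single source event at the last sample: no room for any induced event
  cfg <- sim_config(
    list(node_spec("S", 0), node_spec("T", 0)),
    list(interaction_spec("S", "T", 1, make_delay("fixed", 3))),
    n = 50, seed = 3)
  sim <- simulate_network(cfg)
  expect_identical(sum(sim$series$T), 0L)
})
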