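# Independent oracles used across the suite.

# Direct log-space term summation of the Poisson CDF, independent of ppois:
# F(k | lam) = sum_{i=0}^{k} exp(-lam + i log(lam) - log(i!))
poisson_cdf_oracle <- function(k, lam) {
  if (lam == 0) return(1)
  i <- 0:k
  sum(exp(-lam + i * log(lam) - lgamma(i + 1)))
}

# Brute-force coincidence count by explicit enumeration over time indices
count_er_oracle <- function(x, y, tau) {
  n <- length(x)
  hits <- 0L
  for (t in seq.int(tau + 1L, n))
    if (x[t] == 1L && y[t - tau] == 1L) hits <- hits + 1L
  hits
}

# Smallest k* with F(k* | k0) > 1 - alpha, scanning upward with the oracle
upper_limit_oracle <- function(k0, alpha) {
  k <- 0L
  while (poisson_cdf_oracle(k, k0) <= 1 - alpha) k <- k + 1L
  k
}

# Evaluate expr under a temporary seed without disturbing the global stream
with_fixed_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Convenience: simulated two-node pair, returning plain vectors
sim_pair <- function(p_interaction, delay = make_delay("fixed", 4),
                     n = 5000, seed = NULL, p_base = 0.3) {
  sim <- simulate_network(two_node_config(p_base = p_base,
                                          p_interaction = p_interaction,
                                          delay = delay, n = n, seed = seed))
  list(x = sim$series$X, y = sim$series$Y, truth = sim$truth)
}
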