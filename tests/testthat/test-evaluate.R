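# Build a cer_test-shaped stub with a chosen significant set; classify_outcome
# only inspects alpha/lags/significant, so stubs keep these tests exact.
stub_test <- function(sig_lags, tau_max = 20, alpha = 0.005) {
  structure(list(
    lags = seq_len(tau_max), alpha = alpha, alpha_effective = alpha,
    status = "tested",
    significant = data.frame(lag = as.integer(sig_lags),
                             sign = rep(1L, length(sig_lags)))
  ), class = "cer_test")
}

test_that("classify_outcome reproduces the outcome taxonomy", {
  truth4 <- list(causal = TRUE, support = 4L)
  none <- stub_test(integer(0))

  expect_identical(classify_outcome(stub_test(4), none, truth4),
                   "strongly_correct")
  expect_identical(classify_outcome(stub_test(c(4, 9)), none, truth4),
                   "weakly_correct")
  expect_identical(classify_outcome(none, none, truth4), "missing_detection")
  # reverse detection dominates, even alongside a correct forward hit
  expect_identical(classify_outcome(stub_test(4), stub_test(2), truth4),
                   "error_type_I")

  null_truth <- list(causal = FALSE)
  expect_identical(classify_outcome(stub_test(7), none, null_truth),
                   "error_type_II")
  expect_identical(classify_outcome(none, stub_test(7), null_truth),
                   "error_type_II")
  expect_identical(classify_outcome(none, none, null_truth), "true_negative")
})

test_that("classify_outcome enforces matched parameters and ground truth", {
  t1 <- stub_test(4); t2 <- stub_test(4, alpha = 0.05)
  expect_error(classify_outcome(t1, t2, list(causal = FALSE)), "identical")
  expect_error(classify_outcome(t1, t1, NULL), "truth")
  expect_error(classify_outcome(t1, t1, list(causal = TRUE)), "support")
})

test_that("distributed-delay flags inside the support count as strongly correct", {
  truth <- list(causal = TRUE, support = 2:6)
  none <- stub_test(integer(0))
  expect_identical(classify_outcome(stub_test(c(3, 4, 5)), none, truth),
                   "strongly_correct")
  expect_identical(classify_outcome(stub_test(c(4, 8)), none, truth),
                   "weakly_correct")
})

test_that("run_experiment rates sum to one per cell and stay reproducible", {
  rep1 <- run_experiment(make_delay("fixed", 4),
                         interaction_levels = c(0, 0.6),
                         alphas = c(0.05, 0.005),
                         n_reps = 15, n = 1500, tau_max = 10, seed = 99)
  sums <- tapply(rep1$rate, list(rep1$alpha, rep1$p_interaction), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  rep2 <- run_experiment(make_delay("fixed", 4),
                         interaction_levels = c(0, 0.6),
                         alphas = c(0.05, 0.005),
                         n_reps = 15, n = 1500, tau_max = 10, seed = 99)
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))
})

test_that("single-replicate cells are 0/1 indicators", {
  rep1 <- run_experiment(make_delay("fixed", 3), interaction_levels = 0.8,
                         alphas = 0.005, n_reps = 1, n = 1200,
                         tau_max = 8, seed = 5)
  expect_true(all(rep1$rate %in% c(0, 1)))
  expect_identical(sum(rep1$rate), 1)
})

test_that("null cells only ever produce error_type_II or true_negative", {
  rep1 <- run_experiment(make_delay("fixed", 4), interaction_levels = 0,
                         alphas = 0.05, n_reps = 25, n = 1000,
                         tau_max = 8, seed = 17)
  occupied <- rep1$outcome[rep1$rate > 0]
  expect_true(all(occupied %in% c("error_type_II", "true_negative")))
})

test_that("windowed entropy matches the binary entropy of the window fraction", {
  expect_identical(unique(as.numeric(windowed_entropy(rep(1, 40), 10))), 0)
  expect_identical(unique(as.numeric(windowed_entropy(rep(0, 40), 10))), 0)
  h <- windowed_entropy(rep(c(0, 1), 50), window = 10)
  expect_equal(as.numeric(h), rep(1, 91))  # every window is half ones

  set.seed(201)
  x <- rbinom(300, 1, 0.3)
  h2 <- windowed_entropy(x, 50)
  q1 <- mean(x[1:50])
  expect_equal(h2[1], -q1 * log2(q1) - (1 - q1) * log2(1 - q1))
  expect_identical(length(h2), 300L - 50L + 1L)
  expect_error(windowed_entropy(x, 301), "exceeds")
})

test_that("shorter windows track a wandering rate more erratically", {
  p <- random_walk_probability(10000, seed = 300)
  x <- with_fixed_seed(301, as.integer(runif(10000) < p))
  h_long <- windowed_entropy(x, 1000)
  h_short <- windowed_entropy(x, 500)
  expect_gt(stats::var(diff(h_short)), stats::var(diff(h_long)))
})

test_that("nonstationarity_check separates random walks from noise", {
  rw_hits <- noise_hits <- 0L
  for (seed in 1:8) {
    rw <- with_fixed_seed(seed, cumsum(rnorm(2000)))
    noise <- with_fixed_seed(100 + seed, rnorm(2000))
    if (nonstationarity_check(rw)$verdict == "non-stationary")
      rw_hits <- rw_hits + 1L
    if (nonstationarity_check(noise)$verdict == "stationary")
      noise_hits <- noise_hits + 1L
  }
  expect_gte(rw_hits, 7L)
  expect_gte(noise_hits, 7L)
  expect_identical(nonstationarity_check(rep(0.3, 100))$verdict, "degenerate")
  expect_error(nonstationarity_check(rnorm(10)), "short")
})
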