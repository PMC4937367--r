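test_that("a fixed-delay interaction is recovered at exactly its lag", {
  for (seed in c(21, 22, 23)) {
    s <- sim_pair(0.6, make_delay("fixed", 4), n = 5000, seed = seed)
    res <- cer_test(s$x, s$y, tau_max = 20, alpha = 0.005)
    expect_identical(res$status, "tested")
    expect_true(4L %in% res$significant$lag)
    expect_true(all(res$significant$sign == 1L))
  }
})

test_that("a bi-delay interaction shows both designed lags", {
  s <- sim_pair(0.6, make_delay("bimodal", support = c(2L, 5L)),
                n = 5000, seed = 31)
  res <- cer_test(s$x, s$y, tau_max = 20, alpha = 0.005)
  expect_true(all(c(2L, 5L) %in% res$significant$lag))
})

test_that("degenerate series yield insufficient-events, not an error", {
  zeros <- rep(0, 100)
  y <- rbinom(100, 1, 0.5)
  res <- cer_test(zeros, y, tau_max = 5, alpha = 0.01)
  expect_identical(res$status, "insufficient-events")
  expect_identical(nrow(res$significant), 0L)
  # sparse but non-empty reference below the guard behaves the same
  x2 <- c(1, rep(0, 99))
  res2 <- cer_test(x2, x2, tau_max = 5, alpha = 0.01)
  expect_identical(res2$status, "insufficient-events")
})

test_that("all-one series test without flags under the increase tail", {
  ones <- rep(1, 200)
  res <- cer_test(ones, ones, tau_max = 10, alpha = 0.01)
  expect_identical(res$status, "tested")
  expect_identical(nrow(res$significant), 0L)
})

test_that("p-values are monotone in the count for a fixed reference", {
  set.seed(41)
  s <- sim_pair(0.6, make_delay("fixed", 3), n = 3000, seed = 41)
  res <- cer_test(s$x, s$y, tau_max = 15)
  ord <- order(res$counts)
  expect_true(all(diff(res$pvalues[ord]) >= 0))
})

test_that("the significance rule matches the tail definition exactly", {
  s <- sim_pair(0.6, make_delay("fixed", 4), n = 4000, seed = 51)
  for (tail in c("increase", "decrease", "two-sided")) {
    res <- cer_test(s$x, s$y, tau_max = 12, alpha = 0.01, tail = tail)
    a <- res$alpha_effective
    pos <- res$lags[if (tail == "increase") res$pvalues > 1 - a
                    else if (tail == "two-sided") res$pvalues > 1 - a / 2
                    else rep(FALSE, length(res$lags))]
    neg <- res$lags[if (tail == "decrease") res$pvalues < a
                    else if (tail == "two-sided") res$pvalues < a / 2
                    else rep(FALSE, length(res$lags))]
    expect_setequal(res$significant$lag[res$significant$sign == 1L], pos)
    expect_setequal(res$significant$lag[res$significant$sign == -1L], neg)
  }
})

test_that("negative causality is flagged through the decrease tail", {
  # suppressing interaction: cause events veto the effect 3 samples later
  set.seed(61)
  n <- 5000
  y <- rbinom(n, 1, 0.3)
  x <- rbinom(n, 1, 0.3)
  idx <- which(y == 1) + 3
  x[idx[idx <= n]] <- 0L
  res <- cer_test(x, y, tau_max = 10, alpha = 0.005, tail = "decrease")
  expect_true(3L %in% res$significant$lag)
  expect_true(all(res$significant$sign == -1L))
})

test_that("bonferroni and overlap-correction knobs act as documented", {
  s <- sim_pair(0.6, make_delay("fixed", 4), n = 5000, seed = 71)
  plain <- cer_test(s$x, s$y, tau_max = 20, alpha = 0.005)
  bonf <- cer_test(s$x, s$y, tau_max = 20, alpha = 0.005, bonferroni = TRUE)
  expect_equal(bonf$alpha_effective, 0.005 / 20)
  expect_true(all(bonf$significant$lag %in% plain$significant$lag))
  corr <- cer_test(s$x, s$y, tau_max = 20, alpha = 0.005,
                   overlap_correction = TRUE)
  # rescaled reference shrinks with the overlap, so p-values cannot drop
  expect_true(all(corr$pvalues >= plain$pvalues))
})

test_that("per-lag rejection under the null stays near the nominal level", {
  # independent stationary pairs; the guard band is 3 binomial SEs
  set.seed(81)
  n_reps <- 400
  tau_max <- 5
  rejections <- 0L
  for (r in seq_len(n_reps)) {
    x <- as.integer(runif(5000) < 0.3)
    y <- as.integer(runif(5000) < 0.3)
    res <- cer_test(x, y, tau_max = tau_max, alpha = 0.005)
    rejections <- rejections + nrow(res$significant)
  }
  m <- n_reps * tau_max
  se <- sqrt(0.005 * 0.995 / m)
  expect_lte(rejections / m, 0.005 + 3 * se)
})

test_that("summary returns one calibrated row per lag", {
  s <- sim_pair(0.6, make_delay("fixed", 4), n = 3000, seed = 91)
  res <- cer_test(s$x, s$y, tau_max = 8)
  tab <- summary(res)
  expect_identical(nrow(tab), 8L)
  expect_identical(tab$lag, 1:8)
  expect_equal(tab$frequency, tab$count / tab$n_eff)
  expect_identical(sum(tab$significant != 0L), nrow(res$significant))
})
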