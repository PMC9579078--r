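# small toy score matrices with known structure, centered like real scores
toy_scores <- function(n = 40, p = 2, seed = 71) {
  set.seed(seed)
  S <- matrix(stats::rnorm(n * p), n, p)
  sweep(S, 2, colMeans(S))
}

test_that("sup-type statistics equal exhaustive enumeration at all splits", {
  for (seed in 71:73) {
    S <- toy_scores(40, 2, seed)
    x <- stats::runif(40)
    o <- build_ordering(x, "continuous")
    pr <- cumulative_process(S, o)
    got <- stat_maxlm(pr, null_sample = 1)
    expect_equal(got$statistic, brute_max_lm(S, x), tolerance = 1e-10)

    # reversing the covariate leaves the statistic unchanged
    o_rev <- build_ordering(-x, "continuous")
    got_rev <- stat_maxlm(cumulative_process(S, o_rev), null_sample = 1)
    expect_equal(got_rev$statistic, got$statistic, tolerance = 1e-10)

    expect_equal(stat_dm(pr)$statistic, brute_dm(S, x), tolerance = 1e-10)
  }
})

test_that("LMuo equals its within-level definition and is label-invariant", {
  S <- toy_scores(45, 3)
  g <- factor(rep(c("u", "v", "w"), 15))
  o <- build_ordering(g, "unordered")
  got <- stat_lmuo(S, o)
  expect_equal(got$statistic, brute_lmuo(S, as.integer(g)), tolerance = 1e-10)
  expect_equal(got$p_value,
               stats::pchisq(got$statistic, df = 3 * 2, lower.tail = FALSE))

  # permuting level labels changes nothing
  g2 <- factor(as.character(g), levels = c("w", "u", "v"))
  expect_equal(stat_lmuo(S, build_ordering(g2, "unordered"))$statistic,
               got$statistic, tolerance = 1e-10)
  expect_error(stat_lmuo(S, build_ordering(stats::runif(45), "continuous")),
               "unordered")
})

test_that("maxLMo enumerates level cuts and reduces to one-cut LM for m = 2", {
  S <- toy_scores(48, 2)
  lev <- factor(rep(c("lo", "mid", "hi"), c(14, 16, 18)),
                levels = c("lo", "mid", "hi"), ordered = TRUE)
  o <- build_ordering(lev, "ordered")
  got <- stat_maxlmo(S, o, null_sample = 1)
  # brute force over the two cut points
  Iinv <- solve(crossprod(S) / 48)
  cuts <- c(14, 30)
  vals <- sapply(cuts, function(i) {
    # cumulative over sorted order: first i rows after sorting by level
    cs <- colSums(S[order(as.integer(lev))[1:i], , drop = FALSE])
    t <- i / 48
    drop(t(cs) %*% Iinv %*% cs) / 48 / (t * (1 - t))
  })
  expect_equal(got$statistic, max(vals), tolerance = 1e-10)

  # order reversal symmetry
  lev_rev <- factor(as.character(lev), levels = c("hi", "mid", "lo"),
                    ordered = TRUE)
  got_rev <- stat_maxlmo(S, build_ordering(lev_rev, "ordered"),
                         null_sample = 1)
  expect_equal(got_rev$statistic, got$statistic, tolerance = 1e-10)

  # m = 2: single cut; Monte Carlo p agrees with the chi-square_P tail
  lev2 <- factor(rep(c("a", "b"), 24), levels = c("a", "b"), ordered = TRUE)
  o2 <- build_ordering(lev2, "ordered")
  got2 <- stat_maxlmo(S, o2, reps = 20000, seed = 4)
  t <- sum(lev2 == "a") / 48
  cs <- colSums(S[order(as.integer(lev2))[1:sum(lev2 == "a")], , drop = FALSE])
  expect_equal(got2$statistic,
               drop(t(cs) %*% Iinv %*% cs) / 48 / (t * (1 - t)),
               tolerance = 1e-10)
  p_chi <- stats::pchisq(got2$statistic, df = 2, lower.tail = FALSE)
  expect_lt(abs(got2$p_value - p_chi),
            3 * sqrt(p_chi * (1 - p_chi) / 20000) + 1e-4)
})

test_that("DM analytic p-value matches the Brownian-bridge simulation", {
  S <- toy_scores(60, 2)
  o <- build_ordering(stats::runif(60), "continuous")
  got <- stat_dm(cumulative_process(S, o))
  ngrid <- 500
  sim <- bridge_dm_null(ngrid, 2, reps = 20000, seed = 9)
  p_mc <- mean(sim >= got$statistic)
  # compare at the Siegmund-corrected level to remove grid discretization
  p_corr <- 1 - (1 - scoreflux:::bb_crossing_prob(
    got$statistic + 0.5826 / sqrt(ngrid)))^2
  se <- sqrt(p_mc * (1 - p_mc) / 20000)
  expect_lt(abs(p_corr - p_mc), 3 * se + 0.005)

  # conventional univariate critical point: crossing probability near 0.05
  expect_equal(scoreflux:::bb_crossing_prob(1.358), 0.05, tolerance = 0.002)
  sim1 <- bridge_dm_null(500, 1, reps = 20000, seed = 10)
  expect_lt(abs(mean(sim1 >= 1.358) - 0.05), 3 * sqrt(0.05 * 0.95 / 20000) + 0.005)

  # degenerate all-zero process
  pr0 <- cumulative_process(toy_scores(30, 2), build_ordering(stats::runif(30),
                                                              "continuous"))
  pr0$cumsum[] <- 0
  got0 <- stat_dm(pr0)
  expect_equal(got0$statistic, 0)
  expect_equal(got0$p_value, 1)
})

test_that("test results carry valid statistics, p-values, and provenance", {
  S <- toy_scores(40, 2)
  o <- build_ordering(stats::runif(40), "continuous")
  res <- stat_maxlm(cumulative_process(S, o), reps = 500, seed = 2)
  expect_s3_class(res, "invtest")
  expect_gte(res$statistic, 0)
  expect_gte(res$p_value, 0)
  expect_lte(res$p_value, 1)
  expect_match(res$pvalue_method, "Monte Carlo")
  expect_match(res$pvalue_method, "seed 2")
  expect_output(print(res), "f\\(efp\\)")
})

test_that("the two-group LMuo statistic is chi-square distributed under the null", {
  # refit per replication so the MLE zero-sum constraint holds, which is what
  # reduces the degrees of freedom to P * (m - 1) = P
  n_reps <- 400
  stat <- numeric(n_reps)
  d_true <- seq(-1, 1, length.out = 6)
  for (r in seq_len(n_reps)) {
    set.seed(5000 + r)
    th <- stats::rnorm(300)
    u <- sapply(d_true, function(b) stats::rbinom(300, 1, stats::plogis(th - b)))
    g <- factor(rep(c("A", "B"), 150))
    fit <- fit_rasch_cml(u)
    stat[r] <- stat_lmuo(scores(fit), build_ordering(g, "unordered"))$statistic
  }
  ks <- stats::ks.test(stat, stats::pchisq, df = 5)
  expect_gt(ks$p.value, 0.01)
})
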