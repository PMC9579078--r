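test_that("2PL EM agrees with an independent direct optimizer", {
  set.seed(21)
  N <- 400
  th <- stats::rnorm(N)
  a_true <- c(1, 1.4, 0.7)
  d_true <- c(-0.8, 0.3, 0.9)
  u <- sapply(1:3, function(j)
    stats::rbinom(N, 1, stats::plogis(a_true[j] * th + d_true[j])))
  fit <- fit_mml(u, "2pl", nodes = 41)
  expect_true(fit$converged)

  # independent route: trapezoid-rule marginal likelihood, quasi-Newton on
  # the full 6-parameter vector (no EM, different quadrature)
  grid <- seq(-6, 6, length.out = 241)
  w <- stats::dnorm(grid) * c(diff(grid)[1])
  negll <- function(p) {
    L <- matrix(1, N, length(grid))
    for (j in 1:3) {
      pr <- stats::plogis(p[2 * j - 1] * grid + p[2 * j])
      L <- L * t(outer(pr, u[, j], function(q, y) ifelse(y == 1, q, 1 - q)))
    }
    -sum(log(L %*% w))
  }
  opt <- stats::optim(rep(c(1, 0), 3), negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  expect_equal(unname(fit$params), opt$par, tolerance = 5e-3)
})

test_that("1PL imposes the shared-slope constraint and recovers intercepts", {
  set.seed(22)
  N <- 600
  th <- stats::rnorm(N)
  d_true <- c(-1, -0.3, 0.4, 1.1)
  u <- sapply(d_true, function(d) stats::rbinom(N, 1, stats::plogis(1.2 * th + d)))
  fit <- fit_mml(u, "1pl", nodes = 41)
  expect_length(fit$params, 5)                        # J intercepts + 1 slope
  expect_equal(length(unique(fit$item_par$a)), 1L)    # all slopes equal
  expect_equal(unname(fit$params[1:4]), d_true, tolerance = 0.3)
  expect_equal(unname(fit$params[5]), 1.2, tolerance = 0.3)
})

test_that("marginal log-likelihood is non-decreasing across EM iterations", {
  dat <- sim_rasch_fixture(n = 150, J = 4, seed = 23)
  fit <- fit_mml(dat$resp, "2pl", nodes = 21)
  expect_true(all(diff(fit$loglik_path) > -1e-8))
  expect_equal(sum(fit$caselik), fit$loglik, tolerance = 1e-8)
})

test_that("impact estimation recovers group trait distributions", {
  set.seed(24)
  N <- 800
  grp <- factor(rep(c("ref", "foc"), each = N / 2), levels = c("ref", "foc"))
  th <- c(stats::rnorm(N / 2, 0, 1), stats::rnorm(N / 2, 0.6, 1))
  a_true <- c(1.2, 0.9, 1, 1.1, 0.8)
  d_true <- c(-1, -0.4, 0, 0.5, 1)
  u <- sapply(1:5, function(j)
    stats::rbinom(N, 1, stats::plogis(a_true[j] * th + d_true[j])))
  fit <- fit_mml(u, "2pl", impact = grp, nodes = 31)
  expect_equal(fit$impact_groups$mu[1], 0)            # reference fixed
  expect_equal(fit$impact_groups$sigma2[1], 1)
  expect_equal(fit$impact_groups$mu[2], 0.6, tolerance = 0.25)
  # the group variance is weakly identified by few dichotomous items: its
  # MLE sampling error at this design is large, so only a loose band holds
  expect_equal(fit$impact_groups$sigma2[2], 1, tolerance = 0.6)

  # identical generating distributions: polytomous items pin down the group
  # variance much more tightly; average over replications to separate the
  # MLE's own sampling noise from a systematic failure to recover N(0,1)
  dl <- list(c(1, 0, -1), c(0.5, -0.1, -0.8), c(0.8, 0.2, -0.6),
             c(1.2, -0.3, -1), c(0.4, 0, -0.5))
  est <- sapply(25:27, function(s) {
    set.seed(s)
    th0 <- stats::rnorm(N)
    u0 <- sapply(1:5, function(j) {
      P <- gpcm_probs(a_true[j], dl[[j]], th0)
      apply(P, 1, function(p) sample(0:3, 1, prob = p))
    })
    fit0 <- suppressWarnings(fit_mml(u0, "gpcm", impact = grp, nodes = 31,
                                     maxit = 1000))
    c(fit0$impact_groups$mu[2], fit0$impact_groups$sigma2[2])
  })
  expect_equal(mean(est[1, ]), 0, tolerance = 0.15)
  expect_equal(mean(est[2, ]), 1, tolerance = 0.2)
})

test_that("GPCM fits polytomous data and validates categories", {
  set.seed(26)
  N <- 300
  th <- stats::rnorm(N)
  u1 <- apply(gpcm_probs(1, c(1, -0.2, -1), th), 1,
              function(p) sample(0:3, 1, prob = p))
  u2 <- apply(gpcm_probs(0.8, c(0.5, -0.5), th), 1,
              function(p) sample(0:2, 1, prob = p))
  u3 <- apply(gpcm_probs(1.1, c(0.8, 0, -0.7), th), 1,
              function(p) sample(0:3, 1, prob = p))
  u <- cbind(i1 = u1, i2 = u2, i3 = u3)       # mixed category counts
  fit <- fit_mml(u, "gpcm", nodes = 31)
  expect_true(fit$converged)
  expect_length(fit$params, (1 + 3) + (1 + 2) + (1 + 3))
  expect_equal(sum(fit$caselik), fit$loglik, tolerance = 1e-8)

  u_bad <- u; u_bad[u_bad[, 1] == 2, 1] <- 3      # category 2 unobserved
  expect_error(fit_mml(u_bad, "gpcm"), "category 2")
  expect_error(fit_mml(u, "2pl"), "dichotomous")
  expect_warning(fit_mml(u, "gpcm", impact = rep("one", N), nodes = 11,
                         maxit = 200),
                 "single group")
})
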