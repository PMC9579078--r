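test_that("simulation is deterministic under its seed", {
  d1 <- simulate_responses(sim_rasch_fixture(n = 50, J = 3, seed = 5)$truth$design)
  d2 <- simulate_responses(sim_rasch_fixture(n = 50, J = 3, seed = 5)$truth$design)
  expect_identical(d1$resp, d2$resp)
  expect_identical(d1$covariates, d2$covariates)
  # and the RNG state of the session is left untouched
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(simulate_responses(d1$truth$design)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("degenerate trait distribution gives exact binomial margins", {
  des <- sim_design("rasch", d = c(0, 0), n_persons = 10000, theta_sd = 0,
                    seed = 6)
  dat <- simulate_responses(des)
  # theta = 0, intercept 0: every response is Bernoulli(1/2)
  n <- length(dat$resp)
  ci <- stats::qbinom(c(0.005, 0.995), n, 0.5) / n
  expect_gte(mean(dat$resp), ci[1])
  expect_lte(mean(dat$resp), ci[2])
})

test_that("generated category frequencies match model-implied expectations", {
  des <- sim_design("gpcm", d = list(c(0.5, -0.5, -0.2), c(1, -1)),
                    a = c(1, 0.7), n_persons = 10000, seed = 7)
  dat <- simulate_responses(des)
  q <- scoreflux:::gauss_hermite_normal(61)
  for (j in 1:2) {
    expected <- colSums(q$weights * gpcm_probs(des$a[j], des$d[[j]], q$nodes))
    observed <- tabulate(dat$resp[, j] + 1L, length(expected)) / 10000
    # 4 binomial standard errors per category
    expect_true(all(abs(observed - expected) <
                      4 * sqrt(expected * (1 - expected) / 10000)))
  }
})

test_that("the truth record reconstructs per-person parameters and flags DIF", {
  dat0 <- sim_rasch_fixture(n = 60, J = 4, seed = 8, delta = 0)
  expect_true(dat0$truth$dif_free)

  dat1 <- sim_rasch_fixture(n = 60, J = 4, seed = 8, delta = 0.5, dif_item = 2)
  expect_false(dat1$truth$dif_free)
  pp <- person_params(dat1$truth)
  affected <- dat1$covariates$g == "B"
  base_d <- dat1$truth$design$d[[2]]
  expect_equal(pp$d[[2]][affected, 1], rep(base_d + 0.5, sum(affected)))
  expect_equal(pp$d[[2]][!affected, 1], rep(base_d, sum(!affected)))
  expect_equal(pp$a, matrix(1, 60, 4))

  # linear-in-covariate DIF uses the standardized covariate
  des <- sim_design("rasch", d = c(0, 0, 0), n_persons = 40,
                    covariates = list(x = list(kind = "continuous")),
                    dif = list(list(item = 1, par = "d", covariate = "x",
                                    form = "linear", delta = 0.3)),
                    seed = 9)
  dat2 <- simulate_responses(des)
  pp2 <- person_params(dat2$truth)
  z <- as.numeric(scale(dat2$covariates$x))
  expect_equal(pp2$d[[1]][, 1], 0.3 * z, tolerance = 1e-12)
})

test_that("impact designs draw abilities from group-specific distributions", {
  des <- sim_design("rasch", d = rep(0, 3), n_persons = 4000,
                    covariates = list(g = list(kind = "categorical",
                                               levels = c("a", "b"))),
                    impact = list(covariate = "g", mu = c(0, 1),
                                  sigma2 = c(1, 1)),
                    seed = 10)
  dat <- simulate_responses(des)
  th <- dat$truth$theta
  expect_equal(mean(th[dat$covariates$g == "a"]), 0, tolerance = 0.1)
  expect_equal(mean(th[dat$covariates$g == "b"]), 1, tolerance = 0.1)
})

test_that("rejection-rate studies tabulate p-values with failures excluded", {
  des <- sim_rasch_fixture(n = 80, J = 4, seed = 11)$truth$design
  st <- rejection_rate_study(des,
                             fit_spec = list(model = "rasch"),
                             test_spec = list(covariate = "g",
                                              kind = "unordered",
                                              functional = "LMuo"),
                             n_reps = 20, alpha = 1)
  expect_equal(st$rejection_rate, 1)            # alpha = 1 boundary
  expect_equal(st$n_reps + st$n_failed, 20)
  pv <- attr(st, "p_values")
  expect_length(pv, 20)
  expect_true(all(pv[!is.na(pv)] >= 0 & pv[!is.na(pv)] <= 1))

  expect_error(sim_design("rasch", d = c(0, 0), n_persons = 10, seed = 1,
                          dif = list(list(item = 9, par = "d",
                                          covariate = "x", delta = 1))),
               "out of range")
  expect_error(sim_design("rasch", d = c(0, 0), n_persons = 10),
               "seed")
})
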