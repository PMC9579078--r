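test_that("analytic scores equal finite-difference scores for every model", {
  dat <- sim_rasch_fixture(n = 120, J = 4, seed = 51)

  fit_c <- fit_rasch_cml(dat$resp)
  expect_lt(max(abs(scores(fit_c) - fd_scores(fit_c))), 1e-5)

  fit_2 <- fit_mml(dat$resp, "2pl", nodes = 21)
  expect_lt(max(abs(scores(fit_2) - fd_scores(fit_2))), 1e-5)

  fit_1 <- fit_mml(dat$resp, "1pl", nodes = 21)
  expect_lt(max(abs(scores(fit_1) - fd_scores(fit_1))), 1e-5)

  # polytomous with impact: includes mu_g / sigma2_g score columns
  set.seed(52)
  th <- stats::rnorm(250)
  dl <- list(c(0.8, 0, -0.8), c(0.5, -0.2, -0.9), c(1, 0.3, -0.6))
  u <- sapply(1:3, function(j) {
    P <- gpcm_probs(c(1, 1.2, 0.8)[j], dl[[j]], th)
    apply(P, 1, function(p) sample(0:3, 1, prob = p))
  })
  grp <- factor(rep(c("a", "b"), length.out = 250))
  fit_g <- fit_mml(u, "gpcm", impact = grp, nodes = 21, maxit = 1000)
  S <- scores(fit_g)
  expect_lt(max(abs(S - fd_scores(fit_g))), 1e-5)
  expect_true(all(c("mu_b", "sigma2_b") %in% colnames(S)))
  expect_identical(fit_g$par_index$group, 13:14)
})

test_that("score columns sum to zero at the MLE", {
  dat <- sim_rasch_fixture(n = 150, J = 5, seed = 53)
  for (fit in list(fit_rasch_cml(dat$resp),
                   fit_mml(dat$resp, "2pl", nodes = 21))) {
    cs <- colSums(scores(fit))
    expect_lt(max(abs(cs)), 1e-4)
  }
})

test_that("shared-slope score column is the sum of item-wise slope scores", {
  dat <- sim_rasch_fixture(n = 150, J = 4, seed = 54)
  fit1 <- fit_mml(dat$resp, "1pl", nodes = 21)
  # rebuild as an unconstrained-parametrization fit at the same estimates
  fit2 <- fit1
  fit2$mml_model <- "2pl"
  fit2$params <- scoreflux:::pack_mml("2pl", fit1$item_par$a, fit1$item_par$d,
                                      0, 1, 1, colnames(dat$resp))
  S1 <- scores(fit1)
  S2 <- scores(fit2)
  a_cols <- grep("^a_", colnames(S2))
  expect_equal(unname(S1[, "a"]), unname(rowSums(S2[, a_cols])),
               tolerance = 1e-10)
})

test_that("permuting respondents permutes score rows identically", {
  dat <- sim_rasch_fixture(n = 80, J = 4, seed = 55)
  set.seed(1); perm <- sample(80)
  f1 <- fit_rasch_cml(dat$resp)
  f2 <- fit_rasch_cml(dat$resp[perm, ])
  expect_equal(f1$params, f2$params, tolerance = 1e-8)
  expect_equal(scores(f2), scores(f1)[perm, ], tolerance = 1e-8)
})

test_that("CML and 1PL-MML item score columns are highly correlated", {
  # diagnostic agreement between the two estimation routes, not an identity
  dat <- sim_rasch_fixture(n = 400, J = 5, seed = 56)
  Sc <- scores(fit_rasch_cml(dat$resp))
  Sm <- scores(fit_mml(dat$resp, "1pl", nodes = 21))
  cors <- sapply(2:5, function(j)
    stats::cor(Sc[, paste0("b_item", j)], Sm[, paste0("d_item", j)]))
  expect_true(all(abs(cors) > 0.9))
})

test_that("covariance root whitens scores and fails hard on rank deficiency", {
  set.seed(57)
  S <- matrix(stats::rnorm(300), 100, 3)
  S <- sweep(S, 2, colMeans(S))
  cr <- covariance_root(S)
  # textbook computation of the OPG covariance
  I_hand <- matrix(0, 3, 3)
  for (i in 1:100) I_hand <- I_hand + tcrossprod(S[i, ])
  I_hand <- I_hand / 100
  expect_equal(cr$info, I_hand, tolerance = 1e-12)
  white <- S %*% cr$root
  expect_equal(crossprod(white) / 100, diag(3), tolerance = 1e-8)
  expect_error(covariance_root(cbind(S, S[, 1])), "singular")
})
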