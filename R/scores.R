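#' Case-wise score contributions
#'
#' Computes the \eqn{N \times P} matrix of case-wise score contributions
#' \eqn{s(\hat\Psi; u_i)}: the gradient of each person's log-likelihood
#' contribution with respect to the free model parameters, evaluated at the
#' estimate. At the maximum likelihood estimate every column sums to zero;
#' the covariate-ordered cumulative sums of these rows are the raw material
#' of all score-based invariance tests.
#'
#' For CML Rasch fits, entry \eqn{(i, j)} is the expected response of a
#' person with raw score \eqn{r_i} on item \eqn{j} minus the observed
#' response, obtained from ratios of elementary symmetric functions; persons
#' with raw score 0 or \eqn{J} have zero rows. For MML fits, scores are
#' posterior-weighted quadrature sums, e.g.
#' \eqn{\sum_k f_{ik}\, (u_{ij} - P_j(\theta_k))\, \theta_k} for a slope
#' parameter, with the intercept analogue dropping the factor
#' \eqn{\theta_k}; GPCM intercept scores use step indicators minus step
#' probabilities. Under impact, columns for the non-reference group means and
#' variances are appended after the item parameters.
#'
#' @param fit an [irtfit] object.
#' @param ... unused.
#' @return a numeric matrix with one row per person and one column per free
#'   parameter, with parameter labels as column names.
#' @export
scores <- function(fit, ...) UseMethod("scores")

#' @export
scores.rasch_cml <- function(fit, ...) {
  resp <- fit$resp
  N <- nrow(resp); J <- ncol(resp)
  b <- fit$all_difficulties
  eps <- exp(-b)
  es <- esf(eps, order = 1L)
  r <- fit$raw_scores
  # pi[s, j] = E(u_j | raw score s), s = 1..J-1
  pi_sj <- t(es$d1[, 2:J, drop = FALSE]) * rep(eps, each = J - 1L) /
    es$gamma[2:J]
  S <- matrix(0, N, J)
  interior <- r > 0L & r < J
  S[interior, ] <- pi_sj[r[interior], , drop = FALSE] -
    resp[interior, , drop = FALSE]
  S <- S[, -1L, drop = FALSE]
  colnames(S) <- names(fit$params)
  S
}

#' @export
scores.irtfit <- function(fit, ...) {
  if (is.null(fit$mml_model))
    stop("no scores method for model '", fit$model, "'")
  if (is.null(fit$quadrature))
    stop("fit carries no quadrature metadata; cannot compute MML scores")
  G <- if (is.null(fit$impact_groups)) 1L
       else length(fit$impact_groups$levels)
  mu <- if (G > 1L) fit$impact_groups$mu else 0
  sig2 <- if (G > 1L) fit$impact_groups$sigma2 else 1
  gidx <- if (G > 1L) lapply(seq_len(G), function(g)
    which(fit$impact_groups$index == g)) else list(seq_len(fit$n_obs))
  quad <- fit$quadrature
  post <- mml_posteriors(fit$resp, fit$item_par$a, fit$item_par$d,
                         mu, sig2, quad, gidx)
  S <- mml_score_matrix(fit$resp, fit$mml_model, fit$item_par$a,
                        fit$item_par$d, mu, sig2, quad, gidx, post)
  colnames(S) <- names(fit$params)
  S
}

# posterior node weights per group (list of N_g x Q matrices)
mml_posteriors <- function(resp, a, d, mu, sig2, quad, gidx) {
  J <- ncol(resp)
  lapply(seq_along(gidx), function(g) {
    th <- mu[g] + sqrt(sig2[g]) * quad$nodes
    ig <- gidx[[g]]
    L <- matrix(0, length(ig), length(th))
    for (j in seq_len(J)) {
      logP <- log(pmax(gpcm_probs(a[j], d[[j]], th), 1e-300))
      L <- L + t(logP[, resp[ig, j] + 1L, drop = FALSE])
    }
    A <- sweep(L, 2L, log(quad$weights), "+")
    E <- exp(A - apply(A, 1L, max))
    E / rowSums(E)
  })
}

mml_score_matrix <- function(resp, model, a, d, mu, sig2, quad, gidx, post) {
  N <- nrow(resp); J <- ncol(resp)
  G <- length(gidx)
  K <- vapply(d, length, 0L)
  n_item_par <- if (model == "1pl") J + 1L else J + sum(K)
  P <- n_item_par + 2L * (G - 1L)
  S <- matrix(0, N, P)
  for (g in seq_len(G)) {
    ig <- gidx[[g]]
    th <- mu[g] + sqrt(sig2[g]) * quad$nodes
    f <- post[[g]]
    fth <- as.numeric(f %*% th)
    pos <- 0L
    sa_sum <- 0
    gvec <- numeric(length(th))
    for (j in seq_len(J)) {
      u <- resp[ig, j]
      mo <- gpcm_moments(a[j], d[[j]], th)
      sa <- u * fth - as.numeric(f %*% (th * mo$EX))
      sd_ <- vapply(seq_len(K[j]), function(v)
        (u >= v) - as.numeric(f %*% mo$Pge[, v]), numeric(length(ig)))
      if (model == "1pl") {
        S[ig, j] <- sd_[, 1L]
        sa_sum <- sa_sum + sa
      } else {
        S[ig, pos + 1L] <- sa
        S[ig, pos + 1L + seq_len(K[j])] <- sd_
        pos <- pos + 1L + K[j]
      }
      gvec <- gvec + a[j] * mo$EX
    }
    if (model == "1pl") S[ig, J + 1L] <- sa_sum
    if (g > 1L) {
      ci <- as.numeric(resp[ig, , drop = FALSE] %*% a)
      col0 <- n_item_par + 2L * (g - 2L)
      S[ig, col0 + 1L] <- ci - as.numeric(f %*% gvec)
      S[ig, col0 + 2L] <- (ci * as.numeric(f %*% quad$nodes) -
                             as.numeric(f %*% (quad$nodes * gvec))) /
        (2 * sqrt(sig2[g]))
    }
  }
  S
}

#' Per-person log-likelihood contributions
#'
#' Returns the length-\eqn{N} vector of case-wise log-likelihood
#' contributions \eqn{\ell(\Psi; u_i)}: the conditional log-likelihood given
#' the raw score for CML Rasch fits (zero for perfect and zero scorers), and
#' the quadrature-approximated marginal log-likelihood for MML fits. The sum
#' over persons equals the fit's total log-likelihood. A parameter vector
#' other than the estimate may be supplied, which makes this the natural
#' target for finite-difference validation of [scores()].
#'
#' @param fit an [irtfit] object.
#' @param resp response matrix; defaults to the one stored in the fit.
#' @param params optional replacement for the free parameter vector
#'   (same layout and length as `fit$params`).
#' @return numeric vector of length \eqn{N}.
#' @export
caselik <- function(fit, resp = NULL, params = NULL) {
  if (is.null(resp)) resp <- fit$resp
  resp <- validate_resp(resp)
  if (ncol(resp) != fit$n_items)
    stop("response matrix has ", ncol(resp), " items but the fit has ",
         fit$n_items)
  if (is.null(params)) params <- fit$params
  if (length(params) != length(fit$params))
    stop("'params' must match the fit's free parameter vector (length ",
         length(fit$params), ")")
  if (fit$model == "rasch_cml") {
    b <- c(0, params)
    return(caselik_rasch(b, resp))
  }
  up <- unpack_mml(fit, params)
  G <- if (is.null(fit$impact_groups)) 1L
       else length(fit$impact_groups$levels)
  gidx <- if (G > 1L) lapply(seq_len(G), function(g)
    which(fit$impact_groups$index == g)) else list(seq_len(nrow(resp)))
  quad <- fit$quadrature
  cl <- numeric(nrow(resp))
  for (g in seq_len(G)) {
    th <- up$mu[g] + sqrt(up$sig2[g]) * quad$nodes
    ig <- gidx[[g]]
    L <- matrix(0, length(ig), length(th))
    for (j in seq_len(ncol(resp))) {
      logP <- log(pmax(gpcm_probs(up$a[j], up$d[[j]], th), 1e-300))
      L <- L + t(logP[, resp[ig, j] + 1L, drop = FALSE])
    }
    A <- sweep(L, 2L, log(quad$weights), "+")
    m <- apply(A, 1L, max)
    cl[ig] <- m + log(rowSums(exp(A - m)))
  }
  cl
}

#' Inverse square root of the score covariance matrix
#'
#' Estimates the covariance of the case-wise score contributions by the
#' outer product of gradients, \eqn{\hat I = S^\top S / N}, and returns its
#' symmetric inverse square root via eigendecomposition. Pre-multiplying the
#' scaled cumulative score sums by this factor standardizes the fluctuation
#' process so that each component converges to an independent Brownian
#' bridge under the null hypothesis.
#'
#' Rank deficiency is a hard failure, not silently ridged: eigenvalues below
#' `1e-10` times the largest indicate unidentified or redundant parameters,
#' and the error suggests testing a parameter subset instead.
#'
#' @param S score matrix (persons in rows, parameters in columns).
#' @return list with `root` (the \eqn{P \times P} inverse square root),
#'   `info` (\eqn{\hat I}), and `eigenvalues`.
#' @export
covariance_root <- function(S) {
  S <- as.matrix(S)
  N <- nrow(S)
  info <- crossprod(S) / N
  e <- eigen(info, symmetric = TRUE)
  if (any(e$values < 1e-10 * max(e$values)))
    stop("score covariance matrix is numerically singular ",
         "(relative eigenvalue < 1e-10); the tested parameters are not ",
         "jointly identified -- consider testing a parameter subset")
  root <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  dimnames(root) <- dimnames(info)
  list(root = root, info = info, eigenvalues = e$values)
}
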