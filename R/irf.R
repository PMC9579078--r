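#' Two-parameter logistic item response function
#'
#' Probability of a positive response under the 2PL model in slope/intercept
#' parametrization, \eqn{P(u = 1 \mid a, d, \theta) =
#' \exp(a\theta + d) / (1 + \exp(a\theta + d))}, evaluated overflow-safely.
#'
#' @param a item slope.
#' @param d item intercept.
#' @param theta ability value(s); vectorized.
#' @return probabilities, same length as `theta`.
#' @export
irf_2pl <- function(a, d, theta) {
  stopifnot(is.finite(a), is.finite(d), all(is.finite(theta)))
  stats::plogis(a * theta + d)
}

#' Generalized partial credit model category probabilities
#'
#' Adjacent-categories logistic model with cumulative numerators: for
#' categories \eqn{c = 0, \dots, K},
#' \eqn{P(X = c) \propto \exp(c\, a\theta + \sum_{v \le c} d_v)}, with the
#' empty sum for \eqn{c = 0} (reference category). With \eqn{K = 1} this is
#' exactly the 2PL for category 1, so dichotomous items are the special case.
#'
#' @param a item slope.
#' @param d numeric vector of K item intercepts (one per category step).
#' @param theta ability value(s); vectorized.
#' @return a `length(theta) x (K + 1)` matrix of category probabilities; rows
#'   sum to 1.
#' @export
gpcm_probs <- function(a, d, theta) {
  stopifnot(is.finite(a), all(is.finite(d)), all(is.finite(theta)))
  K <- length(d)
  eta <- outer(theta, seq_len(K) * a) +
    matrix(cumsum(d), length(theta), K, byrow = TRUE)
  eta <- cbind(0, eta)
  eta <- eta - apply(eta, 1L, max)
  p <- exp(eta)
  p / rowSums(p)
}

# probabilist Gauss-Hermite rule for N(0,1): Golub-Welsch on the Jacobi
# matrix of the Hermite recurrence He_{k+1} = x He_k - k He_{k-1}
gauss_hermite_normal <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = 1))
  off <- sqrt(seq_len(n - 1L))
  Jm <- diag(0, n)
  Jm[cbind(seq_len(n - 1L), 2:n)] <- off
  Jm[cbind(2:n, seq_len(n - 1L))] <- off
  e <- eigen(Jm, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (e$vectors[1L, ord])^2)
}
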