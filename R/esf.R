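#' Elementary symmetric functions and their partial derivatives
#'
#' Computes the elementary symmetric functions (ESF)
#' \eqn{\gamma_r(\epsilon_1, \dots, \epsilon_J)} for orders \eqn{r = 0, \dots, J},
#' using the numerically stable summation recursion
#' \eqn{\gamma_r^{(1:j)} = \gamma_r^{(1:j-1)} + \epsilon_j \gamma_{r-1}^{(1:j-1)}}.
#' The ESFs are the combinatorial backbone of conditional maximum likelihood
#' estimation in Rasch-type models: \eqn{\gamma_r} is the sum over all response
#' patterns with raw score \eqn{r} of the product of the involved item easiness
#' parameters \eqn{\epsilon_j = \exp(-b_j)}.
#'
#' First partial derivatives are
#' \eqn{\partial \gamma_r / \partial \epsilon_j = \gamma^{(-j)}_{r-1}}, the
#' ESF of order \eqn{r-1} with item \eqn{j} removed; second partials are the
#' order \eqn{r-2} ESFs with two distinct items removed. Both are computed by
#' re-running the same summation recursion on the reduced parameter set, never
#' by subset enumeration or by the (unstable) backward difference.
#'
#' @param eps numeric vector of \eqn{J \ge 1} strictly positive, finite
#'   easiness values.
#' @param order derivative order: 0 returns only the values, 1 adds first
#'   partials, 2 adds second partials.
#' @return A list with components:
#'   \item{gamma}{numeric vector of length \eqn{J + 1}, \eqn{\gamma_0, \dots, \gamma_J}.}
#'   \item{d1}{(order >= 1) a \eqn{J \times (J + 1)} matrix; row \eqn{j},
#'     column \eqn{r + 1} holds \eqn{\partial \gamma_r / \partial \epsilon_j};
#'     column 1 (\eqn{r = 0}) is zero.}
#'   \item{d2}{(order = 2) a \eqn{J \times J \times (J + 1)} array with
#'     \eqn{\partial^2 \gamma_r / \partial \epsilon_j \partial \epsilon_k};
#'     the diagonal \eqn{j = k} is zero.}
#' @examples
#' esf(c(1, 2, 3))$gamma        # 1, 6, 11, 6
#' esf(rep(1, 3))$gamma         # binomial coefficients 1, 3, 3, 1
#' @export
esf <- function(eps, order = 0L) {
  if (!is.numeric(eps) || length(eps) < 1L)
    stop("'eps' must be a non-empty numeric vector")
  if (any(!is.finite(eps)) || any(eps <= 0))
    stop("all easiness values must be finite and strictly positive")
  order <- as.integer(order)
  J <- length(eps)
  out <- list(gamma = esf_values(eps))
  if (order >= 1L) {
    d1 <- matrix(0, J, J + 1L)
    for (j in seq_len(J)) {
      # d gamma_r / d eps_j = gamma_{r-1} of the leave-one-out set
      d1[j, 1L + seq_len(J)] <- esf_values(eps[-j])
    }
    out$d1 <- d1
  }
  if (order >= 2L) {
    d2 <- array(0, c(J, J, J + 1L))
    if (J >= 2L) {
      for (j in seq_len(J - 1L)) {
        for (k in (j + 1L):J) {
          g2 <- esf_values(eps[-c(j, k)])       # length J - 1 (orders 0..J-2)
          d2[j, k, 2L + seq_len(J - 1L)] <- g2
          d2[k, j, ] <- d2[j, k, ]
        }
      }
    }
    out$d2 <- d2
  }
  out
}

# Summation recursion for gamma_0..gamma_J; gamma_0 = 1 (empty product).
esf_values <- function(eps) {
  J <- length(eps)
  g <- c(1, numeric(J))
  for (j in seq_len(J)) {
    idx <- seq_len(j)
    g[idx + 1L] <- g[idx + 1L] + eps[j] * g[idx]
  }
  g
}
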