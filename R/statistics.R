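#' @rdname invariance_test
#' @export
stat_dm <- function(process) {
  stopifnot(inherits(process, "score_process"))
  B <- process$cumsum[-1L, , drop = FALSE]
  absB <- abs(B)
  stat <- max(absB)
  loc <- which(absB == stat, arr.ind = TRUE)[1L, ]
  p1 <- bb_crossing_prob(stat)
  p <- 1 - (1 - p1)^process$n_pars
  test_result("DM", stat, p, process$pars, process$n_obs, process$n_pars,
              pvalue_method = "analytic (Brownian-bridge crossing series, 100 terms)",
              location = unname(loc["row"]))
}

# P(sup |bridge| > c) = 2 * sum_{k>=1} (-1)^{k+1} exp(-2 k^2 c^2)
bb_crossing_prob <- function(c, terms = 100L) {
  if (c <= 0) return(1)
  k <- seq_len(terms)
  p <- 2 * sum((-1)^(k + 1) * exp(-2 * k^2 * c^2))
  min(max(p, 0), 1)
}

#' @rdname invariance_test
#' @param null_sample optional pre-simulated null distribution sample of the
#'   statistic (as produced by [bridge_lm_null()]), reused instead of fresh
#'   Monte Carlo simulation; useful in replication studies where the boundary
#'   grid is the same across replications.
#' @param pvalue_grid `"boundaries"` (default) simulates the null
#'   distribution of the maximum over exactly the observed admissible
#'   boundary proportions -- the null law of the evaluated functional.
#'   `"continuous"` simulates the continuous-time supremum over the trimming
#'   window on a dense grid, the classical asymptotic reference
#'   distribution; with heavily tied covariates the latter is stochastically
#'   larger, hence more conservative.
#' @export
stat_maxlm <- function(process, reps = 50000L, seed = NULL, null_sample = NULL,
                       pvalue_grid = c("boundaries", "continuous")) {
  stopifnot(inherits(process, "score_process"))
  pvalue_grid <- match.arg(pvalue_grid)
  N <- process$n_obs
  adm <- admissible_boundaries(process)
  t <- adm / N
  ss <- rowSums(process$cumsum[adm + 1L, , drop = FALSE]^2)
  lm <- ss / (t * (1 - t))
  k <- which.max(lm)
  stat <- lm[k]
  if (is.null(null_sample)) {
    grid <- if (pvalue_grid == "boundaries") t else
      seq(process$trim[1L], process$trim[2L], length.out = 801L)
    null_sample <- bridge_lm_null(grid, process$n_pars, reps = reps, seed = seed)
  }
  p <- (sum(null_sample >= stat) + 1) / (length(null_sample) + 1)
  test_result("maxLM", stat, p, process$pars, N, process$n_pars,
              pvalue_method = sprintf("Monte Carlo (%d Brownian-bridge replications%s)",
                                      length(null_sample),
                                      if (is.null(seed)) "" else paste0(", seed ", seed)),
              location = adm[k],
              location_value = process$ordering$sorted_values[adm[k]])
}

admissible_boundaries <- function(process) {
  N <- process$n_obs
  lo <- floor(N * process$trim[1L])
  hi <- ceiling(N * process$trim[2L])
  adm <- process$boundaries[process$boundaries >= lo & process$boundaries <= hi]
  if (!length(adm))
    stop("no admissible covariate boundary inside the trimming window [",
         process$trim[1L], ", ", process$trim[2L], "]")
  adm
}

#' @rdname invariance_test
#' @export
stat_lmuo <- function(S, ordering, pars = NULL) {
  stopifnot(inherits(ordering, "covariate_ordering"))
  if (ordering$kind != "unordered")
    stop("stat_lmuo() requires an unordered covariate ordering")
  S <- select_pars(as.matrix(S), pars)
  N <- nrow(S)
  cr <- covariance_root(S)
  m <- length(ordering$levels)
  nl <- ordering$level_sizes
  if (any(nl == 0L)) stop("empty covariate level")
  stat <- 0
  for (l in seq_len(m)) {
    W <- colSums(S[ordering$group == l, , drop = FALSE])
    z <- cr$root %*% W
    stat <- stat + sum(z^2) / nl[l]
  }
  df <- ncol(S) * (m - 1L)
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  test_result("LMuo", stat, p, colnames(S), N, ncol(S),
              pvalue_method = sprintf("chi-square, %d df", df))
}

#' @rdname invariance_test
#' @export
stat_maxlmo <- function(S, ordering, pars = NULL, reps = 50000L, seed = NULL,
                        null_sample = NULL) {
  stopifnot(inherits(ordering, "covariate_ordering"))
  if (ordering$kind != "ordered")
    stop("stat_maxlmo() requires an ordered covariate ordering")
  S <- select_pars(as.matrix(S), pars)
  N <- nrow(S)
  m <- length(ordering$levels)
  cr <- covariance_root(S)
  Bs <- apply(S[ordering$sort_index, , drop = FALSE] %*% cr$root, 2L, cumsum) /
    sqrt(N)
  cut <- cumsum(ordering$level_sizes)[-m]
  t <- cut / N
  lm <- rowSums(matrix(Bs[cut, ], length(cut)) ^ 2) / (t * (1 - t))
  k <- which.max(lm)
  stat <- lm[k]
  if (is.null(null_sample))
    null_sample <- bridge_lm_null(t, ncol(S), reps = reps, seed = seed)
  p <- (sum(null_sample >= stat) + 1) / (length(null_sample) + 1)
  test_result("maxLMo", stat, p, colnames(S), N, ncol(S),
              pvalue_method = sprintf("Monte Carlo (%d Brownian-bridge replications%s)",
                                      length(null_sample),
                                      if (is.null(seed)) "" else paste0(", seed ", seed)),
              location = k,
              location_value = ordering$levels[k])
}

#' Monte Carlo null distributions of Brownian-bridge functionals
#'
#' `bridge_lm_null()` simulates the null distribution of the maximally
#' selected LM functional \eqn{\sup_l \|B(t_l)\|^2 / (t_l (1 - t_l))} of a
#' \eqn{P}-dimensional standard Brownian bridge evaluated on the grid of
#' observed boundary proportions `times`. `bridge_dm_null()` simulates
#' \eqn{\sup_{t, p} |B_p(t)|} on an equispaced grid of `ngrid` points.
#' Simulation is exact on the grid (Gaussian increments, bridged by
#' subtracting \eqn{t W(1)}) and chunked to bound memory.
#'
#' @param times strictly increasing evaluation proportions in (0, 1).
#' @param p number of independent bridge components.
#' @param reps number of Monte Carlo replications.
#' @param seed optional integer seed (local RNG state).
#' @param chunk replications per memory chunk.
#' @return numeric vector of `reps` simulated statistic values.
#' @export
bridge_lm_null <- function(times, p, reps = 50000L, seed = NULL, chunk = 5000L) {
  stopifnot(all(times > 0), all(times < 1), !is.unsorted(times))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  sdinc <- sqrt(diff(c(0, times, 1)))
  m <- length(times)
  out <- numeric(0)
  done <- 0L
  while (done < reps) {
    nc <- min(chunk, reps - done)
    ssq <- matrix(0, m, nc)
    for (comp in seq_len(p)) {
      W <- apply(matrix(stats::rnorm((m + 1L) * nc, sd = sdinc), m + 1L, nc),
                 2L, cumsum)
      B <- W[seq_len(m), , drop = FALSE] -
        outer(times, W[m + 1L, ])
      ssq <- ssq + B^2
    }
    lm <- ssq / (times * (1 - times))
    out <- c(out, apply(lm, 2L, max))
    done <- done + nc
  }
  out
}

#' @rdname bridge_lm_null
#' @param ngrid number of equispaced grid points for the double-maximum
#'   functional.
#' @export
bridge_dm_null <- function(ngrid, p, reps = 50000L, seed = NULL, chunk = 5000L) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  times <- seq_len(ngrid) / ngrid
  sdinc <- sqrt(rep(1 / ngrid, ngrid))
  out <- numeric(0)
  done <- 0L
  while (done < reps) {
    nc <- min(chunk, reps - done)
    mx <- numeric(nc)
    for (comp in seq_len(p)) {
      W <- apply(matrix(stats::rnorm(ngrid * nc, sd = sdinc), ngrid, nc),
                 2L, cumsum)
      B <- W - outer(times, W[ngrid, ])
      mx <- pmax(mx, apply(abs(B), 2L, max))
    }
    out <- c(out, mx)
    done <- done + nc
  }
  out
}

test_result <- function(functional, statistic, p_value, pars, n_obs, n_pars,
                        pvalue_method, location = NULL, location_value = NULL) {
  stopifnot(statistic >= 0, p_value >= 0, p_value <= 1)
  structure(list(
    functional = functional,
    statistic = unname(statistic),
    p_value = unname(p_value),
    pars = pars,
    n_obs = n_obs,
    n_pars = n_pars,
    pvalue_method = pvalue_method,
    location = location,
    location_value = location_value
  ), class = "invtest")
}

#' @export
print.invtest <- function(x, ...) {
  cat("Score-based measurement invariance test\n\n")
  cat(sprintf("functional: %s   parameters tested: %d   N = %d\n",
              x$functional, x$n_pars, x$n_obs))
  cat(sprintf("f(efp) = %.4g, p-value = %.4g\n", x$statistic, x$p_value))
  cat("p-value method:", x$pvalue_method, "\n")
  if (!is.null(x$location_value))
    cat("maximum attained at covariate value:", format(x$location_value), "\n")
  invisible(x)
}
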