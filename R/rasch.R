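#' Fit the dichotomous Rasch model by conditional maximum likelihood
#'
#' Estimates item difficulties \eqn{b_j} (item response function
#' \eqn{P(u_{ij} = 1) = \mathrm{logit}^{-1}(\theta_i - b_j)}) by maximizing the
#' conditional likelihood of the response patterns given the raw scores, which
#' eliminates the person parameters through elementary symmetric functions.
#' Estimation is by Newton iterations on the ESF recursion (see [esf()]);
#' analytic gradient and Hessian, with step halving.
#'
#' Identification fixes the first item's difficulty at 0, so the free
#' parameter vector is \eqn{(b_2, \dots, b_J)}. Persons with raw score 0 or
#' \eqn{J} have a constant conditional likelihood: they contribute zero to the
#' conditional log-likelihood and a zero row of score contributions, but are
#' retained in \eqn{N} so that person indices stay aligned with covariates.
#'
#' @param resp integer matrix (or data frame) of 0/1 responses, persons in
#'   rows, items in columns. Column names are used as item labels.
#' @param tol convergence tolerance: Newton stops when the sup-norm of the
#'   conditional score gradient falls below `tol`.
#' @param maxit maximum number of Newton iterations.
#' @return An object of class `c("rasch_cml", "irtfit")`; see [irt_fit()] for
#'   the common structure.
#' @seealso [irt_fit()] for the unified fitting front end, [scores()] for
#'   case-wise score contributions.
#' @export
fit_rasch_cml <- function(resp, tol = 1e-8, maxit = 100L) {
  resp <- validate_resp(resp)
  if (any(resp > 1L))
    stop("fit_rasch_cml() requires dichotomous (0/1) responses; ",
         "use fit_mml(model = \"gpcm\") for polytomous items")
  N <- nrow(resp); J <- ncol(resp)
  csum <- colSums(resp)
  bad <- which(csum == 0L | csum == N)
  if (length(bad))
    stop("item(s) without response variance: ",
         paste(colnames(resp)[bad], collapse = ", "))

  r <- rowSums(resp)                       # raw scores
  interior <- r > 0L & r < J
  # person counts per raw score 1..J-1 and per-score item totals
  nr <- tabulate(r[interior], nbins = J - 1L)
  sr <- matrix(0, J - 1L, J)               # sum of u_.j within each score group
  for (s in which(nr > 0L))
    sr[s, ] <- colSums(resp[interior & r == s, , drop = FALSE])

  # start: centered marginal logits, item 1 anchored at 0
  p <- pmin(pmax(csum / N, 0.02), 0.98)
  b <- stats::qlogis(1 - p)
  b <- b - b[1L]

  condloglik <- function(b) {
    g <- esf_values(exp(-b))
    -sum(sr * b[col(sr)]) - sum(nr * log(g[2:J]))
  }
  ll <- condloglik(b)
  converged <- FALSE
  iter <- 0L
  free <- 2:J
  while (iter < maxit) {
    iter <- iter + 1L
    eps <- exp(-b)
    es <- esf(eps, order = 2L)
    # pi[s, j] = E(u_j | raw score s); cross[s, j, k] = E(u_j u_k | s)
    gr <- es$gamma[2:J]
    pi_sj <- t(es$d1[, 2:J, drop = FALSE]) * rep(eps, each = J - 1L) / gr
    grad <- colSums(nr * pi_sj) - colSums(sr)      # d l / d b_j, length J
    H <- matrix(0, J, J)
    for (s in seq_len(J - 1L)) {
      if (nr[s] == 0L) next
      cross <- es$d2[, , s + 1L] * tcrossprod(eps) / es$gamma[s + 1L]
      covm <- cross - tcrossprod(pi_sj[s, ])
      diag(covm) <- pi_sj[s, ] * (1 - pi_sj[s, ])
      H <- H - nr[s] * covm                        # Hessian of cond. loglik
    }
    if (max(abs(grad[free])) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(H[free, free], grad[free]),
                     error = function(e) grad[free] / max(abs(diag(H[free, free])), 1))
    bnew <- b; bnew[free] <- b[free] - step
    llnew <- condloglik(bnew)
    halve <- 0L
    while (!is.finite(llnew) || llnew < ll - 1e-12) {
      step <- step / 2
      bnew <- b; bnew[free] <- b[free] - step
      llnew <- condloglik(bnew)
      halve <- halve + 1L
      if (halve > 30L) break
    }
    b <- bnew; ll <- llnew
  }
  if (!converged) warning("CML Newton iterations reached 'maxit' (", maxit,
                          ") without meeting the gradient tolerance")

  params <- b[free]
  names(params) <- paste0("b_", colnames(resp)[free])
  cl <- caselik_rasch(b, resp, r)
  structure(list(
    model = "rasch_cml",
    params = params,
    all_difficulties = stats::setNames(b, colnames(resp)),
    loglik = sum(cl),
    caselik = cl,
    converged = converged,
    iterations = iter,
    identification = sprintf("difficulty of item '%s' fixed at 0", colnames(resp)[1L]),
    resp = resp,
    raw_scores = r,
    n_obs = N,
    n_items = J
  ), class = c("rasch_cml", "irtfit"))
}

# per-person conditional log-likelihood; zero for raw scores 0 and J
caselik_rasch <- function(b, resp, r = rowSums(resp)) {
  J <- length(b)
  g <- esf_values(exp(-b))
  cl <- -as.numeric(resp %*% b) - log(g[r + 1L])
  cl[r == 0L | r == J] <- 0
  cl
}

validate_resp <- function(resp) {
  resp <- as.matrix(resp)
  if (is.null(colnames(resp)))
    colnames(resp) <- paste0("item", seq_len(ncol(resp)))
  if (nrow(resp) < 2L || ncol(resp) < 2L)
    stop("need at least 2 persons and 2 items")
  if (any(is.na(resp)))
    stop("missing responses are not supported; first missing entry at row ",
         which(rowSums(is.na(resp)) > 0)[1L])
  if (any(resp != round(resp)) || any(resp < 0))
    stop("responses must be non-negative integers (0, 1, ..., K)")
  storage.mode(resp) <- "integer"
  resp
}
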