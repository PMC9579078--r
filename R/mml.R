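#' Fit 1PL, 2PL, or generalized partial credit models by marginal ML
#'
#' Marginal maximum likelihood estimation via the EM algorithm with
#' fixed-node Gauss-Hermite quadrature. The latent trait is standard normal;
#' with an `impact` grouping, the reference (first) group is fixed at
#' \eqn{N(0, 1)} and the remaining groups' means \eqn{\mu_g} and variances
#' \eqn{\sigma_g^2} are estimated as free parameters (multiple-group
#' estimation), with the quadrature grid rescaled per group as
#' \eqn{\theta = \mu_g + \sigma_g x}.
#'
#' Models: `"2pl"` has item response function
#' \eqn{P_{ij} = \exp(a_j\theta_i + d_j)/(1 + \exp(a_j\theta_i + d_j))};
#' `"1pl"` constrains all slopes equal; `"gpcm"` is the adjacent-categories
#' logistic model of [gpcm_probs()] with item slopes \eqn{a_j} and cumulative
#' intercepts \eqn{d_{jk}}, which collapses to the 2PL for two categories.
#'
#' The E-step computes posterior trait weights on the (per-group) quadrature
#' grid; the M-step maximizes the expected complete-data log-likelihood per
#' item by Newton iterations, and updates group distribution parameters by
#' direct quasi-Newton ascent of the marginal log-likelihood. The marginal
#' log-likelihood is non-decreasing across iterations. Iteration stops when
#' the largest absolute parameter change falls below `tol` and the score
#' column sums are numerically zero; if `maxit` is reached first, a warning is
#' printed and the fit is flagged as not converged.
#'
#' @param resp integer response matrix, persons in rows, items in columns;
#'   entries in `0..K_j`. For `"1pl"`/`"2pl"` all items must be dichotomous;
#'   for `"gpcm"` every category `0..K_j` must be observed for every item.
#' @param model `"1pl"`, `"2pl"`, or `"gpcm"`.
#' @param impact optional factor (or vector) of group labels modeling impact:
#'   genuine group differences in the trait distribution, as opposed to DIF.
#' @param maxit maximum number of EM iterations (default 500).
#' @param tol convergence tolerance on the maximum absolute parameter change.
#' @param nodes number of Gauss-Hermite quadrature nodes (default 61).
#' @return An object of class `c("<model>_mml", "irtfit")`; see [irt_fit()].
#' @export
fit_mml <- function(resp, model = c("2pl", "1pl", "gpcm"), impact = NULL,
                    maxit = 500L, tol = 1e-5, nodes = 61L) {
  model <- match.arg(model)
  resp <- validate_resp(resp)
  N <- nrow(resp); J <- ncol(resp)
  K <- apply(resp, 2L, max)
  if (model %in% c("1pl", "2pl") && any(K != 1L))
    stop("model '", model, "' requires dichotomous items; item(s) ",
         paste(colnames(resp)[K != 1L], collapse = ", "), " are polytomous")
  for (j in seq_len(J)) {
    seen <- sort(unique(resp[, j]))
    miss <- setdiff(0:K[j], seen)
    if (length(miss))
      stop("item '", colnames(resp)[j], "': category ", miss[1L],
           " is never observed")
  }

  if (!is.null(impact)) {
    impact <- as.factor(impact)
    if (length(impact) != N)
      stop("'impact' must have one group label per person")
    if (nlevels(impact) < 2L) {
      warning("'impact' has a single group; impact modeling is ignored")
      impact <- NULL
    }
  }
  groups <- if (is.null(impact)) factor(rep("all", N)) else impact
  glev <- levels(groups)
  G <- length(glev)
  gidx <- lapply(glev, function(l) which(groups == l))

  quad <- gauss_hermite_normal(nodes)
  mu <- numeric(G); sig2 <- rep(1, G)     # group 1 = reference, fixed

  # starting values: unit slopes, marginal adjacent-category logits
  a <- rep(1, J)
  d <- lapply(seq_len(J), function(j) {
    cnt <- tabulate(resp[, j] + 1L, nbins = K[j] + 1L) + 0.5
    log(cnt[-1L] / cnt[-length(cnt)])
  })

  estep <- function(a, d, mu, sig2) {
    cl <- numeric(N)
    f <- vector("list", G)
    logw <- log(quad$weights)
    for (g in seq_len(G)) {
      th <- mu[g] + sqrt(sig2[g]) * quad$nodes
      ig <- gidx[[g]]
      L <- matrix(0, length(ig), nodes)
      for (j in seq_len(J)) {
        logP <- log(pmax(gpcm_probs(a[j], d[[j]], th), 1e-300))
        L <- L + t(logP[, resp[ig, j] + 1L, drop = FALSE])
      }
      A <- sweep(L, 2L, logw, "+")
      m <- apply(A, 1L, max)
      E <- exp(A - m)
      den <- rowSums(E)
      cl[ig] <- m + log(den)
      f[[g]] <- E / den
    }
    list(caselik = cl, post = f)
  }

  flat <- function(a, d, mu, sig2) pack_mml(model, a, d, mu, sig2, G)
  prev <- flat(a, d, mu, sig2)
  converged <- FALSE
  iter <- 0L
  es <- estep(a, d, mu, sig2)
  llpath <- sum(es$caselik)
  repeat {
    iter <- iter + 1L
    # expected category tables on the stacked per-group grids
    theta_glob <- unlist(lapply(seq_len(G), function(g)
      mu[g] + sqrt(sig2[g]) * quad$nodes))
    Rlist <- lapply(seq_len(J), function(j) {
      do.call(rbind, lapply(seq_len(G), function(g) {
        u <- resp[gidx[[g]], j]
        ind <- matrix(0, length(u), K[j] + 1L)
        ind[cbind(seq_along(u), u + 1L)] <- 1
        crossprod(es$post[[g]], ind)
      }))
    })
    if (model == "1pl") {
      upd <- onepl_mstep(theta_glob, Rlist, a[1L], vapply(d, `[`, 0, 1L))
      a <- rep(upd$a, J)
      d <- as.list(upd$d)
    } else {
      for (j in seq_len(J)) {
        upd <- gpcm_item_mstep(theta_glob, Rlist[[j]], a[j], d[[j]])
        a[j] <- upd$a; d[[j]] <- upd$d
      }
    }
    if (G > 1L) {
      for (g in 2:G) {
        upd <- update_group(resp[gidx[[g]], , drop = FALSE], a, d,
                            mu[g], sig2[g], quad)
        mu[g] <- upd$mu; sig2[g] <- upd$sig2
      }
    }
    es <- estep(a, d, mu, sig2)
    llpath <- c(llpath, sum(es$caselik))
    cur <- flat(a, d, mu, sig2)
    delta <- max(abs(cur - prev))
    prev <- cur
    if (delta < tol) {
      # require first-order conditions before declaring convergence, so that
      # score columns sum to numerical zero
      g0 <- mml_grad_norm(resp, model, a, d, mu, sig2, quad, gidx, es$post)
      if (g0 < 1e-6 * max(1, N / 100)) { converged <- TRUE; break }
    }
    if (iter >= maxit) break
  }
  if (!converged)
    warning("EM reached 'maxit' (", maxit, ") before meeting the convergence ",
            "tolerance; treat estimates with care")

  params <- pack_mml(model, a, d, mu, sig2, G,
                     item_names = colnames(resp), group_names = glev)
  n_item_par <- length(params) - 2L * (G - 1L)
  structure(list(
    model = paste0(c(`1pl` = "onepl", `2pl` = "twopl", gpcm = "gpcm")[model], "_mml"),
    params = params,
    item_par = list(a = a, d = d),
    impact_groups = if (G > 1L) list(levels = glev, mu = mu, sigma2 = sig2,
                                     index = as.integer(groups)) else NULL,
    loglik = sum(es$caselik),
    caselik = es$caselik,
    loglik_path = llpath,
    converged = converged,
    iterations = iter,
    identification = if (G > 1L)
      sprintf("latent trait N(0,1) in reference group '%s'", glev[1L])
    else "latent trait fixed at N(0,1)",
    quadrature = list(nodes = quad$nodes, weights = quad$weights),
    par_index = list(item = seq_len(n_item_par),
                     group = if (G > 1L) n_item_par + seq_len(2L * (G - 1L))),
    resp = resp,
    groups = groups,
    n_obs = N,
    n_items = J,
    n_cat = K,
    mml_model = model
  ), class = c(paste0(c(`1pl` = "onepl", `2pl` = "twopl", gpcm = "gpcm")[model], "_mml"),
               "irtfit"))
}

# flat named parameter vector; item-major (slope first, then intercepts),
# group distribution parameters appended
pack_mml <- function(model, a, d, mu, sig2, G, item_names = NULL,
                     group_names = NULL) {
  J <- length(d)
  if (is.null(item_names)) item_names <- paste0("item", seq_len(J))
  if (model == "1pl") {
    v <- c(vapply(d, `[`, 0, 1L), a[1L])
    nm <- c(paste0("d_", item_names), "a")
  } else {
    v <- unlist(lapply(seq_len(J), function(j) c(a[j], d[[j]])))
    nm <- unlist(lapply(seq_len(J), function(j) {
      K <- length(d[[j]])
      c(paste0("a_", item_names[j]),
        if (K == 1L) paste0("d_", item_names[j])
        else paste0("d_", item_names[j], "_", seq_len(K)))
    }))
  }
  if (G > 1L) {
    if (is.null(group_names)) group_names <- paste0("g", seq_len(G))
    v <- c(v, as.numeric(rbind(mu[-1L], sig2[-1L])))
    nm <- c(nm, as.character(rbind(paste0("mu_", group_names[-1L]),
                                   paste0("sigma2_", group_names[-1L]))))
  }
  stats::setNames(v, nm)
}

# inverse of pack_mml given the shape metadata of a fit
unpack_mml <- function(fit, params) {
  J <- fit$n_items; K <- fit$n_cat
  G <- if (is.null(fit$impact_groups)) 1L else length(fit$impact_groups$levels)
  if (fit$mml_model == "1pl") {
    d <- as.list(params[seq_len(J)])
    a <- rep(params[J + 1L], J)
    pos <- J + 1L
  } else {
    a <- numeric(J); d <- vector("list", J); pos <- 0L
    for (j in seq_len(J)) {
      a[j] <- params[pos + 1L]
      d[[j]] <- as.numeric(params[pos + 1L + seq_len(K[j])])
      pos <- pos + 1L + K[j]
    }
  }
  mu <- numeric(G); sig2 <- rep(1, G)
  if (G > 1L) {
    extra <- params[pos + seq_len(2L * (G - 1L))]
    mu[-1L] <- extra[seq(1L, length(extra), by = 2L)]
    sig2[-1L] <- extra[seq(2L, length(extra), by = 2L)]
  }
  list(a = a, d = d, mu = mu, sig2 = sig2)
}

# expectations of the category variable and its step indicators at each node
gpcm_moments <- function(a, d, theta) {
  K <- length(d)
  P <- gpcm_probs(a, d, theta)
  cvec <- 0:K
  EX <- as.numeric(P %*% cvec)
  VX <- as.numeric(P %*% cvec^2) - EX^2
  Pge <- sapply(seq_len(K), function(v)
    rowSums(P[, (v + 1L):(K + 1L), drop = FALSE]))
  EXge <- sapply(seq_len(K), function(v)
    as.numeric(P[, (v + 1L):(K + 1L), drop = FALSE] %*% (v:K)))
  Pge <- matrix(Pge, ncol = K); EXge <- matrix(EXge, ncol = K)
  list(P = P, EX = EX, VX = VX, Pge = Pge, EXge = EXge)
}

# Newton maximization of one item's expected complete-data log-likelihood
# R: nodes x categories table of posterior-expected counts
gpcm_item_mstep <- function(theta, R, a, d, free_a = TRUE, maxiter = 50L) {
  K <- length(d)
  n <- rowSums(R)
  S1 <- as.numeric(R %*% (0:K))
  Sge <- sapply(seq_len(K), function(v)
    rowSums(R[, (v + 1L):(K + 1L), drop = FALSE]))
  Sge <- matrix(Sge, ncol = K)
  qfun <- function(a, d) sum(R * log(pmax(gpcm_probs(a, d, theta), 1e-300)))
  qv <- qfun(a, d)
  for (it in seq_len(maxiter)) {
    mo <- gpcm_moments(a, d, theta)
    gd <- colSums(Sge - n * mo$Pge)
    ga <- sum(theta * (S1 - n * mo$EX))
    gr <- if (free_a) c(ga, gd) else gd
    if (max(abs(gr)) < 1e-9) break
    Hdd <- -crossprod(mo$Pge * sqrt(n), mo$Pge * sqrt(n))
    for (v in seq_len(K)) for (w in seq_len(K))
      Hdd[v, w] <- -sum(n * (mo$Pge[, max(v, w)] - mo$Pge[, v] * mo$Pge[, w]))
    Had <- -vapply(seq_len(K), function(v)
      sum(n * theta * (mo$EXge[, v] - mo$EX * mo$Pge[, v])), 0)
    Haa <- -sum(n * theta^2 * mo$VX)
    H <- if (free_a) rbind(c(Haa, Had), cbind(Had, Hdd)) else Hdd
    step <- tryCatch(solve(H, gr), error = function(e) gr / max(abs(diag(H)), 1))
    for (h in 0:30) {
      anew <- if (free_a) a - step[1L] / 2^h else a
      dnew <- d - (if (free_a) step[-1L] else step) / 2^h
      qnew <- qfun(anew, dnew)
      if (is.finite(qnew) && qnew >= qv - 1e-12) break
    }
    a <- anew; d <- dnew; qv <- qnew
  }
  list(a = a, d = d)
}

# joint Newton for the 1PL: per-item intercepts plus one shared slope
onepl_mstep <- function(theta, Rlist, a, dvec, maxiter = 50L) {
  J <- length(dvec)
  n <- rowSums(Rlist[[1L]])
  S1 <- vapply(Rlist, function(R) as.numeric(R %*% c(0, 1)), numeric(length(theta)))
  qfun <- function(a, dvec) {
    s <- 0
    for (j in seq_len(J))
      s <- s + sum(Rlist[[j]] * log(pmax(gpcm_probs(a, dvec[j], theta), 1e-300)))
    s
  }
  qv <- qfun(a, dvec)
  for (it in seq_len(maxiter)) {
    P <- vapply(seq_len(J), function(j) stats::plogis(a * theta + dvec[j]),
                numeric(length(theta)))
    gd <- colSums(S1 - n * P)
    ga <- sum(theta * (rowSums(S1) - n * rowSums(P)))
    gr <- c(ga, gd)
    if (max(abs(gr)) < 1e-9) break
    W <- n * P * (1 - P)
    Hdd <- diag(-colSums(W), J)
    Had <- -colSums(theta * W)
    Haa <- -sum(theta^2 * rowSums(W))
    H <- rbind(c(Haa, Had), cbind(Had, Hdd))
    step <- tryCatch(solve(H, gr), error = function(e) gr / max(abs(diag(H)), 1))
    for (h in 0:30) {
      anew <- a - step[1L] / 2^h
      dnew <- dvec - step[-1L] / 2^h
      qnew <- qfun(anew, dnew)
      if (is.finite(qnew) && qnew >= qv - 1e-12) break
    }
    a <- anew; dvec <- dnew; qv <- qnew
  }
  list(a = a, d = dvec)
}

# quasi-Newton ascent of one group's marginal log-likelihood in (mu, log sigma)
update_group <- function(respg, a, d, mu, sig2, quad) {
  J <- ncol(respg)
  negll <- function(p) {
    th <- p[1L] + exp(p[2L]) * quad$nodes
    L <- matrix(0, nrow(respg), length(th))
    for (j in seq_len(J)) {
      logP <- log(pmax(gpcm_probs(a[j], d[[j]], th), 1e-300))
      L <- L + t(logP[, respg[, j] + 1L, drop = FALSE])
    }
    A <- sweep(L, 2L, log(quad$weights), "+")
    m <- apply(A, 1L, max)
    -sum(m + log(rowSums(exp(A - m))))
  }
  grad <- function(p) {
    th <- p[1L] + exp(p[2L]) * quad$nodes
    L <- matrix(0, nrow(respg), length(th))
    gvec <- numeric(length(th))
    for (j in seq_len(J)) {
      logP <- log(pmax(gpcm_probs(a[j], d[[j]], th), 1e-300))
      L <- L + t(logP[, respg[, j] + 1L, drop = FALSE])
      gvec <- gvec + a[j] * gpcm_moments(a[j], d[[j]], th)$EX
    }
    A <- sweep(L, 2L, log(quad$weights), "+")
    m <- apply(A, 1L, max)
    E <- exp(A - m); f <- E / rowSums(E)
    ci <- as.numeric(respg %*% a)
    dmu <- sum(ci - f %*% gvec)
    dsig <- sum((ci * as.numeric(f %*% quad$nodes) -
                   as.numeric(f %*% (quad$nodes * gvec)))) * exp(p[2L])
    c(-dmu, -dsig)
  }
  res <- stats::optim(c(mu, log(sqrt(sig2))), negll, grad, method = "BFGS",
                      control = list(maxit = 10L, reltol = 1e-12))
  list(mu = res$par[1L], sig2 = exp(2 * res$par[2L]))
}

# sup-norm of the marginal score column sums (first-order conditions)
mml_grad_norm <- function(resp, model, a, d, mu, sig2, quad, gidx, post) {
  fit <- list(mml_model = model, n_items = ncol(resp),
              n_cat = apply(resp, 2L, max),
              impact_groups = if (length(gidx) > 1L)
                list(levels = seq_along(gidx), mu = mu, sigma2 = sig2,
                     index = NULL) else NULL)
  S <- mml_score_matrix(resp, model, a, d, mu, sig2, quad, gidx, post)
  max(abs(colSums(S)))
}
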