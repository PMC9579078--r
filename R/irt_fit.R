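#' Fit an item response model
#'
#' Unified fitting front end. `model = "rasch"` fits the dichotomous Rasch
#' model by conditional maximum likelihood (see [fit_rasch_cml()]); the
#' remaining models are estimated by marginal maximum likelihood with the
#' EM algorithm (see [fit_mml()]): `"1pl"` (shared slope), `"2pl"`, and
#' `"gpcm"` for polytomous items. Impact -- genuine group differences in
#' the latent trait distribution, as opposed to DIF -- can be modeled for
#' the MML models via multiple-group estimation.
#'
#' @param resp integer response matrix, persons in rows, items in columns.
#' @param model `"rasch"`, `"1pl"`, `"2pl"`, or `"gpcm"`.
#' @param impact optional group labels for multiple-group (impact)
#'   estimation; MML models only.
#' @param ... passed on to [fit_rasch_cml()] or [fit_mml()]
#'   (`maxit`, `tol`, `nodes`).
#' @return an object of class `"irtfit"` with components `model`, `params`
#'   (named free-parameter vector \eqn{\hat\Psi}), `loglik`, `caselik`,
#'   `converged`, `iterations`, `identification`, and for MML fits
#'   `quadrature` and (with impact) `impact_groups`.
#' @seealso [scores()], [caselik()], [invariance_test()]
#' @export
irt_fit <- function(resp, model = c("rasch", "1pl", "2pl", "gpcm"),
                    impact = NULL, ...) {
  model <- match.arg(model)
  if (model == "rasch") {
    if (!is.null(impact))
      stop("impact modeling requires marginal estimation; ",
           "use model = '1pl' (or '2pl'/'gpcm')")
    fit_rasch_cml(resp, ...)
  } else {
    fit_mml(resp, model = model, impact = impact, ...)
  }
}

#' @export
print.irtfit <- function(x, ...) {
  lab <- c(rasch_cml = "Rasch model (conditional ML)",
           onepl_mml = "1PL model (marginal ML)",
           twopl_mml = "2PL model (marginal ML)",
           gpcm_mml = "generalized partial credit model (marginal ML)")[x$model]
  cat(lab, "\n")
  cat(sprintf("%d persons, %d items, %d free parameters\n",
              x$n_obs, x$n_items, length(x$params)))
  cat(sprintf("log-likelihood: %.4f (%sconverged in %d iterations)\n",
              x$loglik, if (x$converged) "" else "NOT ", x$iterations))
  cat("identification:", x$identification, "\n")
  invisible(x)
}

#' @export
coef.irtfit <- function(object, ...) object$params

#' @export
logLik.irtfit <- function(object, ...) {
  structure(object$loglik, df = length(object$params), class = "logLik")
}

#' @export
summary.irtfit <- function(object, ...) {
  print(object)
  cat("\nParameter estimates:\n")
  print(round(object$params, 4))
  if (!is.null(object$impact_groups)) {
    cat("\nLatent trait distribution by group:\n")
    print(data.frame(group = object$impact_groups$levels,
                     mean = object$impact_groups$mu,
                     variance = object$impact_groups$sigma2))
  }
  invisible(object)
}

#' Simulate responses from a fitted model
#'
#' Draws new response matrices from the estimated item parameters, with
#' abilities drawn from the estimated (group-wise, if impact was modeled)
#' latent trait distribution. For CML Rasch fits the trait is drawn from
#' N(0,1), which the conditional approach leaves unspecified.
#'
#' @param object an [irtfit] object.
#' @param nsim number of response matrices to draw.
#' @param seed optional seed.
#' @param ... unused.
#' @return a list of `nsim` response matrices.
#' @export
simulate.irtfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  N <- object$n_obs
  if (object$model == "rasch_cml") {
    a <- rep(1, object$n_items)
    d <- as.list(-object$all_difficulties)
  } else {
    a <- object$item_par$a
    d <- object$item_par$d
  }
  gmu <- rep(0, N); gsd <- rep(1, N)
  if (!is.null(object$impact_groups)) {
    gi <- object$impact_groups$index
    gmu <- object$impact_groups$mu[gi]
    gsd <- sqrt(object$impact_groups$sigma2[gi])
  }
  lapply(seq_len(nsim), function(s) {
    th <- stats::rnorm(N, gmu, gsd)
    out <- vapply(seq_along(a), function(j)
      draw_categories(gpcm_probs(a[j], d[[j]], th)), integer(N))
    colnames(out) <- colnames(object$resp)
    out
  })
}

# one categorical draw per row of a probability matrix
draw_categories <- function(P) {
  u <- stats::runif(nrow(P))
  cum <- P
  for (k in seq_len(ncol(P) - 1L) + 1L) cum[, k] <- cum[, k] + cum[, k - 1L]
  as.integer(rowSums(u > cum))
}
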