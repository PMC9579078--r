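#' Design of a synthetic item response study
#'
#' Describes everything needed to generate response data with a known IRT
#' structure: true item parameters, person covariates, optional impact
#' (group differences in the trait distribution), and optional DIF
#' (covariate-dependent item parameters). Two DIF effect forms are
#' supported: a group shift `delta` applied to the affected parameter for a
#' subset of the sample (for a continuous covariate, the upper half at the
#' median split, i.e. DIF between the first and second half of the
#' covariate-ordered sample; for a categorical one, named levels), and a
#' shift linear in the standardized covariate (`form = "linear"`), the
#' minimal smooth extension of the two-group form.
#'
#' @param model `"rasch"`, `"2pl"`, or `"gpcm"`.
#' @param d true item intercepts: a numeric vector (dichotomous) or a list
#'   of per-item threshold vectors (GPCM). For `"rasch"`, `d` holds
#'   *intercepts*, i.e. minus the difficulties.
#' @param a true item slopes; scalar 1 for `"rasch"`, recycled to J.
#' @param n_persons number of respondents.
#' @param covariates named list of covariate specifications. Continuous:
#'   `list(kind = "continuous", dist = "uniform"|"normal")`. Categorical:
#'   `list(kind = "categorical", levels = ..., probs = ..., ordered = TRUE/FALSE)`.
#' @param impact optional `list(covariate = <name>, mu = ..., sigma2 = ...)`
#'   giving one trait mean/variance per level of a categorical covariate
#'   (reference level first, conventionally 0/1).
#' @param dif optional list of DIF specifications:
#'   `list(item =, par = "a"|"d"|<threshold index>, covariate =,
#'   form = "group"|"linear", delta =, levels = <affected levels>)`.
#' @param theta_sd trait standard deviation when no impact is given
#'   (`0` fixes every ability at the mean, useful for exact checks).
#' @param seed integer seed; mandatory so that every dataset is reproducible.
#' @return an object of class `"sim_design"`.
#' @export
sim_design <- function(model = c("rasch", "2pl", "gpcm"), d, a = 1,
                       n_persons, covariates = list(), impact = NULL,
                       dif = NULL, theta_sd = 1, seed) {
  model <- match.arg(model)
  if (missing(seed)) stop("a 'seed' is mandatory in a simulation design")
  if (!is.list(d)) d <- as.list(d)
  J <- length(d)
  a <- rep_len(a, J)
  if (model == "rasch" && any(a != 1))
    stop("the Rasch model has unit slopes")
  if (model != "gpcm" && any(lengths(d) != 1L))
    stop("dichotomous models take a single intercept per item")
  if (length(covariates) && is.null(names(covariates)))
    stop("covariates must be named")
  for (cv in covariates) {
    if (!cv$kind %in% c("continuous", "categorical"))
      stop("covariate kind must be 'continuous' or 'categorical'")
    if (cv$kind == "categorical") {
      pr <- cv$probs %||% rep(1 / length(cv$levels), length(cv$levels))
      if (length(pr) != length(cv$levels) || any(pr < 0) ||
          abs(sum(pr) - 1) > 1e-8)
        stop("invalid level probabilities")
    }
  }
  if (!is.null(impact)) {
    if (!impact$covariate %in% names(covariates))
      stop("impact covariate '", impact$covariate, "' is not declared")
    nlev <- length(covariates[[impact$covariate]]$levels)
    if (length(impact$mu) != nlev || length(impact$sigma2) != nlev)
      stop("impact needs one mu and sigma2 per level")
  }
  for (df_ in dif) {
    if (df_$item < 1 || df_$item > J) stop("DIF item out of range")
    if (!df_$covariate %in% names(covariates))
      stop("DIF covariate '", df_$covariate, "' is not declared")
  }
  structure(list(model = model, a = a, d = d, n_persons = n_persons,
                 covariates = covariates, impact = impact, dif = dif,
                 theta_sd = theta_sd, seed = as.integer(seed)),
            class = "sim_design")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Generate response data from a simulation design
#'
#' Draws covariates, group-wise abilities, applies any DIF modifications to
#' the per-person item parameters, and samples responses from the model's
#' category probabilities. Fully reproducible: the same design (including
#' its seed) always yields the same data.
#'
#' @param design a [sim_design()] object.
#' @return list with `resp` (response matrix), `covariates` (data frame),
#'   and `truth`: the design, the drawn abilities, and per-DIF-entry
#'   per-person shifts, sufficient to reconstruct every person's item
#'   parameters via [person_params()]. `truth$dif_free` flags a DIF-free
#'   dataset.
#' @export
simulate_responses <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(design$seed)
  N <- design$n_persons
  J <- length(design$d)

  cov <- data.frame(row.names = seq_len(N))
  for (nm in names(design$covariates)) {
    cv <- design$covariates[[nm]]
    cov[[nm]] <- if (cv$kind == "continuous") {
      switch(cv$dist %||% "uniform",
             uniform = stats::runif(N),
             normal = stats::rnorm(N),
             stop("unknown covariate distribution '", cv$dist, "'"))
    } else {
      pr <- cv$probs %||% rep(1 / length(cv$levels), length(cv$levels))
      factor(sample(cv$levels, N, replace = TRUE, prob = pr),
             levels = cv$levels, ordered = isTRUE(cv$ordered))
    }
  }

  if (is.null(design$impact)) {
    theta <- stats::rnorm(N, 0, design$theta_sd)
  } else {
    g <- as.integer(factor(cov[[design$impact$covariate]],
                           levels = design$covariates[[design$impact$covariate]]$levels))
    theta <- stats::rnorm(N, design$impact$mu[g], sqrt(design$impact$sigma2[g]))
  }

  # per-person parameter shifts from the DIF specification
  shifts <- lapply(design$dif, function(df_) {
    x <- cov[[df_$covariate]]
    amt <- if ((df_$form %||% "group") == "group") {
      affected <- if (is.numeric(x)) x > stats::median(x)
                  else x %in% (df_$levels %||% levels(x)[-1L])
      df_$delta * as.numeric(affected)
    } else {
      if (!is.numeric(x)) stop("linear DIF requires a continuous covariate")
      df_$delta * as.numeric(scale(x))
    }
    c(df_[c("item", "par", "covariate", "form", "delta")], list(shift = amt))
  })

  pp <- person_params_impl(design, shifts, N)
  resp <- matrix(0L, N, J,
                 dimnames = list(NULL, paste0("item", seq_len(J))))
  for (j in seq_len(J)) {
    if (is.null(pp$varying[[j]])) {
      resp[, j] <- draw_categories(gpcm_probs(pp$a[1L, j],
                                              pp$d[[j]][1L, ], theta))
    } else {
      # item parameters differ across persons: evaluate probabilities rowwise
      P <- t(vapply(seq_len(N), function(i)
        gpcm_probs(pp$a[i, j], pp$d[[j]][i, ], theta[i])[1L, ],
        numeric(length(design$d[[j]]) + 1L)))
      resp[, j] <- draw_categories(P)
    }
  }
  list(resp = resp, covariates = cov,
       truth = list(design = design, theta = theta, shifts = shifts,
                    dif_free = !length(shifts) ||
                      all(vapply(shifts, function(s) all(s$shift == 0), TRUE))))
}

# expand baseline parameters + shifts into per-person arrays
person_params_impl <- function(design, shifts, N) {
  J <- length(design$d)
  a <- matrix(design$a, N, J, byrow = TRUE)
  d <- lapply(design$d, function(dj) matrix(dj, N, length(dj), byrow = TRUE))
  varying <- vector("list", J)
  for (s in shifts) {
    if (all(s$shift == 0)) next
    j <- s$item
    if (identical(s$par, "a")) a[, j] <- a[, j] + s$shift
    else if (identical(s$par, "d")) d[[j]][, 1L] <- d[[j]][, 1L] + s$shift
    else d[[j]][, as.integer(s$par)] <- d[[j]][, as.integer(s$par)] + s$shift
    varying[[j]] <- TRUE
  }
  list(a = a, d = d, varying = varying)
}

#' Reconstruct per-person item parameters from a truth record
#'
#' @param truth the `truth` component of a [simulate_responses()] result.
#' @return list with `a` (N x J slope matrix) and `d` (list of N x K
#'   threshold matrices).
#' @export
person_params <- function(truth) {
  pp <- person_params_impl(truth$design, truth$shifts,
                           truth$design$n_persons)
  pp[c("a", "d")]
}

#' Monte Carlo rejection-rate study
#'
#' Repeatedly generates data from a design, fits the model, runs an
#' invariance test, and tabulates the rejection rate at level `alpha`,
#' with a binomial Monte Carlo standard error. Per-replication seeds are
#' derived from the design seed so the study is reproducible (and the same
#' seed sequence can be reused across DIF sizes for paired comparisons).
#' Replications whose fit or test fails are recorded and excluded.
#'
#' @param design a [sim_design()].
#' @param fit_spec list: `model` (passed to [irt_fit()]) and optional
#'   further arguments such as `impact` (a covariate name), `nodes`, `tol`.
#' @param test_spec list: `covariate` (name), `kind`, `functional`, and
#'   optional `pars`, `trim`, `reps`, `null_sample`.
#' @param n_reps number of Monte Carlo replications (at least 2).
#' @param alpha nominal level.
#' @return data frame with the rejection rate, its standard error, the
#'   number of failed replications, and the vector of p-values as an
#'   attribute `"p_values"`.
#' @export
rejection_rate_study <- function(design, fit_spec, test_spec, n_reps = 500L,
                                 alpha = 0.05) {
  stopifnot(inherits(design, "sim_design"), n_reps >= 2L)
  pvals <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    des_r <- design
    des_r$seed <- (design$seed + 104729L * r) %% 2147483629L
    pvals[r] <- tryCatch({
      dat <- simulate_responses(des_r)
      fargs <- c(list(resp = dat$resp, model = fit_spec$model),
                 fit_spec[setdiff(names(fit_spec), c("model", "impact"))])
      if (!is.null(fit_spec$impact))
        fargs$impact <- dat$covariates[[fit_spec$impact]]
      fit <- suppressWarnings(do.call(irt_fit, fargs))
      targs <- c(list(fit = fit,
                      covariate = dat$covariates[[test_spec$covariate]]),
                 test_spec[setdiff(names(test_spec), "covariate")])
      do.call(invariance_test, targs)$p_value
    }, error = function(e) NA_real_)
  }
  ok <- !is.na(pvals)
  if (!any(ok)) stop("every replication failed")
  rate <- mean(pvals[ok] <= alpha)
  out <- data.frame(functional = test_spec$functional,
                    alpha = alpha,
                    n_reps = sum(ok),
                    n_failed = sum(!ok),
                    rejection_rate = rate,
                    mc_se = sqrt(rate * (1 - rate) / sum(ok)))
  attr(out, "p_values") <- pvals
  out
}
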