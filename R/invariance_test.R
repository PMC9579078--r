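#' Score-based tests of measurement invariance
#'
#' `invariance_test()` is the front end for testing whether the item
#' parameters of a fitted IRT model are invariant along a person covariate
#' (i.e., for detecting differential item functioning). It computes the
#' case-wise score contributions of the fit, orders them by the covariate,
#' and summarizes the fluctuation of their cumulative sums with one of four
#' statistics, matched to the covariate's scale of measurement:
#'
#' * `"LMuo"` (unordered covariate): sum over levels of the squared
#'   standardized within-level score sums,
#'   \eqn{\sum_l \|\Delta B_l\|^2 / (n_l / N)}; p-value from the
#'   \eqn{\chi^2} distribution with \eqn{P(m - 1)} degrees of freedom.
#' * `"maxLMo"` (ordered covariate): maximum of
#'   \eqn{\|B(t_l)\|^2 / (t_l (1 - t_l))} over the \eqn{m - 1} level cut
#'   points; Monte Carlo p-value.
#' * `"maxLM"` (continuous covariate): the same functional maximized over
#'   all tie boundaries inside the trimming window; Monte Carlo p-value.
#' * `"DM"` (continuous covariate): double maximum
#'   \eqn{\max_{i, p} |B(i/N)_p|}; analytic p-value from the
#'   Brownian-bridge boundary-crossing series, combined across components
#'   under asymptotic independence.
#'
#' An ordered covariate may deliberately be treated as continuous (`maxLM`,
#' `DM` accept `kind = "ordered"`), in which case rank scores define the
#' ordering; the converse pairings are usage errors.
#'
#' By default the tested parameter set consists of all item parameters; for
#' multiple-group (impact) fits the group distribution parameters
#' \eqn{\mu_g, \sigma^2_g} are excluded unless `include_impact_pars = TRUE`
#' or `pars` selects them explicitly. `pars` indexes the columns of
#' [scores()], i.e. item-major slope-then-intercept order.
#'
#' @param fit an [irtfit] object.
#' @param covariate person covariate vector of length \eqn{N}.
#' @param kind covariate scale: `"continuous"`, `"ordered"`, `"unordered"`.
#' @param functional `"maxLM"`, `"LMuo"`, `"maxLMo"`, or `"DM"`.
#' @param pars optional parameter subset (indices or names into the score
#'   matrix columns).
#' @param trim trimming window for `"maxLM"`, default `c(0.1, 0.9)`.
#' @param reps Monte Carlo replications for sup-type p-values.
#' @param seed optional seed for the Monte Carlo p-value.
#' @param include_impact_pars include the group distribution parameters in
#'   the default tested set.
#' @param null_sample optional pre-simulated null sample, see
#'   [bridge_lm_null()].
#' @param process a `"score_process"` from [cumulative_process()] (for the
#'   low-level statistic functions).
#' @param S a score matrix (for the low-level statistic functions).
#' @param ordering a [build_ordering()] result.
#' @return an object of class `"invtest"`: functional, statistic, p-value,
#'   tested parameters, p-value method, and the location of the maximum for
#'   sup-type statistics.
#' @examples
#' des <- sim_design("rasch", d = seq(-1, 1, length.out = 4), n_persons = 150,
#'                   covariates = list(age = list(kind = "continuous")),
#'                   seed = 7)
#' dat <- simulate_responses(des)
#' fit <- irt_fit(dat$resp, model = "rasch")
#' invariance_test(fit, dat$covariates$age, kind = "continuous",
#'                 functional = "maxLM", reps = 2000, seed = 1)
#' @export
invariance_test <- function(fit, covariate,
                            kind = c("continuous", "ordered", "unordered"),
                            functional = c("maxLM", "LMuo", "maxLMo", "DM"),
                            pars = NULL, trim = c(0.1, 0.9), reps = 50000L,
                            seed = NULL, include_impact_pars = FALSE,
                            null_sample = NULL,
                            pvalue_grid = c("boundaries", "continuous")) {
  stopifnot(inherits(fit, "irtfit"))
  kind <- match.arg(kind)
  functional <- match.arg(functional)
  if (length(covariate) != fit$n_obs)
    stop("'covariate' must have length N = ", fit$n_obs)
  ok <- switch(functional,
               LMuo = kind == "unordered",
               maxLMo = kind == "ordered",
               maxLM = , DM = kind %in% c("continuous", "ordered"))
  if (!ok)
    stop("functional '", functional, "' is not defined for a ", kind,
         " covariate; pair LMuo with unordered, maxLMo with ordered, and ",
         "maxLM/DM with continuous (or ordered-as-continuous) covariates")

  S <- scores(fit)
  if (is.null(pars)) {
    pars <- if (!is.null(fit$par_index) && !include_impact_pars)
      fit$par_index$item else seq_len(ncol(S))
  }
  okind <- if (functional %in% c("maxLM", "DM") && kind == "ordered")
    "ordered" else kind
  ordering <- build_ordering(covariate, okind)

  res <- switch(functional,
    LMuo = stat_lmuo(S, ordering, pars = pars),
    maxLMo = stat_maxlmo(S, ordering, pars = pars, reps = reps, seed = seed,
                         null_sample = null_sample),
    maxLM = {
      pr <- cumulative_process(S, ordering, pars = pars, trim = trim)
      stat_maxlm(pr, reps = reps, seed = seed, null_sample = null_sample,
                 pvalue_grid = match.arg(pvalue_grid))
    },
    DM = stat_dm(cumulative_process(S, ordering, pars = pars, trim = trim))
  )
  res$model <- fit$model
  res$trim <- if (functional %in% c("maxLM", "DM")) trim
  res
}
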