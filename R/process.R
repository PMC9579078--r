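#' Order respondents by a person covariate
#'
#' Prepares the covariate ordering along which score contributions are
#' cumulated. For continuous and ordered covariates a stable sort is used
#' and the process is later evaluated only at boundaries between distinct
#' sorted values (within ties the ordering is arbitrary, so the process
#' there is not meaningful). For unordered covariates no sort is meaningful
#' and only the level structure is kept.
#'
#' @param covariate vector of length \eqn{N}: numeric for
#'   `kind = "continuous"`, factor or vector coercible to one for the
#'   categorical kinds (factor level order defines the ordering for
#'   `kind = "ordered"`).
#' @param kind `"continuous"`, `"ordered"`, or `"unordered"`.
#' @return an object of class `"covariate_ordering"` with elements `kind`,
#'   `sort_index` (permutation of `1:N`), `boundaries` (indices `i` such
#'   that the sorted covariate changes between positions `i` and `i + 1`),
#'   and for categorical kinds `levels` and `level_sizes`.
#' @export
build_ordering <- function(covariate, kind = c("continuous", "ordered", "unordered")) {
  kind <- match.arg(kind)
  if (any(is.na(covariate)))
    stop("missing covariate values are not supported")
  N <- length(covariate)
  if (kind == "continuous") {
    if (!is.numeric(covariate))
      stop("a continuous covariate must be numeric")
    x <- covariate
  } else {
    covariate <- as.factor(covariate)
    covariate <- droplevels(covariate)
    if (nlevels(covariate) < 2L)
      stop("the covariate is constant; there is no invariance hypothesis to test")
    x <- as.integer(covariate)
  }
  if (length(unique(x)) < 2L)
    stop("the covariate is constant; there is no invariance hypothesis to test")
  idx <- order(x)                       # stable sort, ties keep input order
  xs <- x[idx]
  structure(list(
    kind = kind,
    sort_index = idx,
    boundaries = which(diff(xs) != 0),
    sorted_values = if (kind == "continuous") covariate[idx] else
      levels(covariate)[xs],
    levels = if (kind != "continuous") levels(covariate),
    level_sizes = if (kind != "continuous")
      as.integer(table(covariate)),
    group = if (kind != "continuous") as.integer(covariate),
    n = N
  ), class = "covariate_ordering")
}

#' Standardized cumulative score process
#'
#' Builds the empirical fluctuation process
#' \deqn{B(t, \hat\Psi) = \hat I^{-1/2} N^{-1/2}
#'   \sum_{i = 1}^{\lfloor Nt \rfloor} s(\hat\Psi; u_{(i)}),}
#' the decorrelated cumulative sum of the covariate-ordered case-wise score
#' contributions. Under the null hypothesis of parameter invariance each of
#' its \eqn{P} components converges to an independent Brownian bridge, which
#' is what all test statistic distributions are derived from. When a
#' parameter subset `pars` is given, columns are selected *before*
#' standardization, i.e. \eqn{\hat I} is the covariance of the selected
#' columns only.
#'
#' @param S score matrix from [scores()].
#' @param ordering a [build_ordering()] result (continuous or ordered).
#' @param pars optional column indices (or names) selecting the tested
#'   parameters; default all columns.
#' @param trim numeric length-2 fractions `(from, to)` bounding the window
#'   in which sup-type statistics are maximized; default `c(0.1, 0.9)`.
#' @return an object of class `"score_process"`: `cumsum` is the
#'   \eqn{(N + 1) \times P} matrix of standardized partial sums (row 1 is
#'   \eqn{t = 0}), `times` the grid \eqn{i/N}, `boundaries` the admissible
#'   tie boundaries, plus `trim` and bookkeeping.
#' @export
cumulative_process <- function(S, ordering, pars = NULL, trim = c(0.1, 0.9)) {
  stopifnot(inherits(ordering, "covariate_ordering"))
  if (ordering$kind == "unordered")
    stop("a cumulative process is not meaningful for an unordered covariate")
  S <- as.matrix(S)
  if (nrow(S) != ordering$n)
    stop("score matrix and ordering disagree on N")
  S <- select_pars(S, pars)
  N <- nrow(S)
  cr <- covariance_root(S)
  B <- apply(S[ordering$sort_index, , drop = FALSE] %*% cr$root, 2L, cumsum) /
    sqrt(N)
  B <- rbind(0, B)
  colnames(B) <- colnames(S)
  structure(list(
    cumsum = B,
    times = seq_len(N) / N,
    boundaries = ordering$boundaries,
    trim = trim,
    ordering = ordering,
    pars = colnames(S),
    n_obs = N,
    n_pars = ncol(S)
  ), class = "score_process")
}

select_pars <- function(S, pars) {
  if (is.null(pars)) return(S)
  if (is.character(pars)) {
    bad <- setdiff(pars, colnames(S))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  } else if (any(pars < 1L) || any(pars > ncol(S))) {
    stop("'pars' indices must lie in 1..", ncol(S))
  }
  S[, pars, drop = FALSE]
}
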