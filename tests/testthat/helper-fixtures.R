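# shared fixtures: everything is generated in code at test time

# dichotomous Rasch data plus a continuous and a two-level covariate
sim_rasch_fixture <- function(n = 200, J = 5, seed = 42, delta = 0,
                              dif_item = 2) {
  des <- sim_design(
    "rasch",
    d = seq(-1.2, 1.2, length.out = J),
    n_persons = n,
    covariates = list(x = list(kind = "continuous"),
                      g = list(kind = "categorical", levels = c("A", "B"))),
    dif = if (delta != 0)
      list(list(item = dif_item, par = "d", covariate = "g",
                form = "group", delta = delta, levels = "B")),
    seed = seed)
  simulate_responses(des)
}

# central finite differences of caselik() w.r.t. the free parameter vector
fd_scores <- function(fit, h = 1e-5) {
  p0 <- fit$params
  out <- matrix(0, fit$n_obs, length(p0))
  for (j in seq_along(p0)) {
    pp <- p0; pm <- p0
    pp[j] <- pp[j] + h
    pm[j] <- pm[j] - h
    out[, j] <- (caselik(fit, params = pp) - caselik(fit, params = pm)) / (2 * h)
  }
  colnames(out) <- names(p0)
  out
}

# Verbal Aggression data as distributed with lme4 (identical to the original
# source): 316 persons x 24 dichotomized items plus anger and gender.
# Items are selected by name because lme4 orders the 24 items differently
# from the original distribution, whose first six columns are the six
# situation-1 items (want + do modes).
va_data <- function() {
  e <- new.env()
  utils::data("VerbAgg", package = "lme4", envir = e)
  va <- e$VerbAgg
  w <- stats::reshape(va[, c("id", "item", "r2")], idvar = "id",
                      timevar = "item", direction = "wide")
  resp <- as.matrix(w[, -1]) == "Y"
  storage.mode(resp) <- "integer"
  colnames(resp) <- sub("^r2\\.", "", colnames(resp))
  first6 <- c("S1WantCurse", "S1WantScold", "S1WantShout",
              "S1DoCurse", "S1DoScold", "S1DoShout")
  list(resp6 = resp[, first6],
       anger = va$Anger[match(w$id, va$id)],
       gender = va$Gender[match(w$id, va$id)])
}

# exhaustive-enumeration oracle for the LM-type functionals: recompute the
# standardization and every candidate quadratic form from first principles
brute_max_lm <- function(S, ord_values, trim = c(0.1, 0.9)) {
  N <- nrow(S)
  idx <- order(ord_values)
  Ss <- S[idx, , drop = FALSE]
  I <- crossprod(S) / N
  Iinv <- solve(I)
  xs <- ord_values[idx]
  best <- -Inf
  for (i in seq_len(N - 1)) {
    if (xs[i] == xs[i + 1]) next
    t <- i / N
    if (i < floor(N * trim[1]) || i > ceiling(N * trim[2])) next
    cs <- colSums(Ss[seq_len(i), , drop = FALSE])
    q <- drop(t(cs) %*% Iinv %*% cs) / N / (t * (1 - t))
    best <- max(best, q)
  }
  best
}

brute_lmuo <- function(S, groups) {
  N <- nrow(S)
  Iinv <- solve(crossprod(S) / N)
  stat <- 0
  for (l in unique(groups)) {
    W <- colSums(S[groups == l, , drop = FALSE])
    stat <- stat + drop(t(W) %*% Iinv %*% W) / sum(groups == l)
  }
  stat
}

brute_dm <- function(S, ord_values) {
  N <- nrow(S)
  idx <- order(ord_values)
  e <- eigen(crossprod(S) / N, symmetric = TRUE)
  root <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  B <- apply(S[idx, , drop = FALSE] %*% root, 2, cumsum) / sqrt(N)
  max(abs(B))
}
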