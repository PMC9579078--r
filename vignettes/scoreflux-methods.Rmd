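---
title: "Score-based measurement invariance tests: models, statistics, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Score-based measurement invariance tests: models, statistics, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The testing problem

A test is measurement invariant when respondents of equal latent trait have
the same response probabilities regardless of other characteristics.
Violations — differential item functioning (DIF) — are classically tested by
comparing pre-defined groups, which breaks down for continuous covariates
such as age or a co-administered trait score. Score-based (M-fluctuation)
tests avoid pre-grouping: they ask whether the case-wise likelihood score
contributions, which sum to zero at the MLE, drift systematically when
respondents are ordered by a covariate.

Writing $\ell(\Psi; u_i)$ for person $i$'s log-likelihood contribution and
$s(\hat\Psi; u_i) = \partial \ell / \partial \Psi |_{\hat\Psi}$ for the
case-wise score, the standardized cumulative score process is
$$B(t, \hat\Psi) = \hat I^{-1/2} N^{-1/2}
  \sum_{i=1}^{\lfloor Nt \rfloor} s(\hat\Psi; u_{(i)}),$$
where $u_{(i)}$ are the covariate-ordered responses and $\hat I$ estimates
the score covariance. Under correct model specification and parameter
invariance, each of the $P$ components of $B$ converges to an independent
Brownian bridge (functional CLT), which yields null distributions for any
reasonable functional of the process. `scoreflux` implements four:

* **maxLM** (continuous covariates): $\max_t \|B(t)\|^2/(t(1-t))$ over
  admissible split points;
* **maxLMo** (ordered covariates): the same functional over the $m-1$
  level cut points;
* **LMuo** (unordered covariates): $\sum_l \|\Delta B_l\|^2/(n_l/N)$ over
  level-wise increments, asymptotically $\chi^2_{P(m-1)}$;
* **DM** (continuous covariates): $\max_{i,p} |B(i/N)_p|$, with an
  analytic boundary-crossing p-value.

Any parameter subset can be tested (argument `pars`), which turns the
same machinery into item-wise DIF tests; the subset is selected *before*
standardization so $\hat I$ refers to the tested parameters only.

# Models and estimation

**Rasch / CML.** The dichotomous Rasch model is estimated by conditional
maximum likelihood: conditioning on the raw scores removes the person
parameters, at the price of working with elementary symmetric functions
(ESFs) $\gamma_r$ of the item easiness parameters. ESFs and their first two
derivative families are computed by the stable summation recursion (and,
for derivatives, recursions on leave-one-out and leave-two-out parameter
sets), never by subset enumeration, which overflows and cancels
catastrophically beyond toy sizes. Newton iterations use the analytic
conditional gradient and Hessian (minus the conditional covariance of the
responses given the raw score) with step halving, stopping at gradient
sup-norm $10^{-8}$. Identification fixes the first item's difficulty at 0.
CML makes no assumption on the trait distribution — the reason to prefer it
for Rasch-type models. Persons with raw score 0 or $J$ carry no conditional
information; they contribute zero log-likelihood and zero score rows but
are *retained in $N$*, keeping score rows aligned with the covariate vector
(dropping them would silently reorder the process).

**1PL / 2PL / GPCM / MML.** Marginal ML integrates the trait out against a
normal distribution, approximated by Gauss–Hermite quadrature with 61 nodes
(default; configurable). 61 nodes makes posterior moments stable far into
the tails while keeping E-steps cheap; the rule is computed by Golub–Welsch
eigendecomposition of the Hermite Jacobi matrix. The 2PL uses the
slope/intercept form $P_{ij} = \mathrm{logit}^{-1}(a_j \theta_i + d_j)$;
the GPCM is the adjacent-categories logistic model with cumulative
intercepts, so a two-category item *is* a 2PL item — the dichotomous case
collapses exactly, which fixes the threshold sign convention. The 1PL
shares one slope across items.

The EM algorithm alternates posterior trait weights on the quadrature grid
(E-step) with per-item Newton maximization of the expected complete-data
log-likelihood (M-step). With an `impact` grouping, the reference group's
trait distribution is fixed at $N(0,1)$ and the other groups'
$(\mu_g, \sigma^2_g)$ are free parameters, updated by direct quasi-Newton
ascent of the marginal log-likelihood on the group's rescaled grid
$\theta = \mu_g + \sigma_g x$; both step types are ascent steps, so the
marginal log-likelihood is non-decreasing across iterations (asserted in
the tests). Iteration stops when the largest parameter change falls below
`tol` ($10^{-5}$) *and* the score column sums are numerically zero — the
second condition matters because the fluctuation tests build on the
zero-sum identity, and a parameter-change criterion alone does not
guarantee it. If `maxit` (500) is reached first, the fit is returned with a
warning and `converged = FALSE`.

Missing responses are rejected at input: supporting them would change the
score formulas per pattern, and silent row dropping would misalign the
covariate ordering.

# Scores

All scores are analytic. For CML-Rasch, entry $(i, j)$ is the expected
response of a person with raw score $r_i$ on item $j$ (an ESF ratio) minus
the observed response. For MML fits, the score of a slope is
$\sum_k f_{ik} (u_{ij} - P_j(\theta_k)) \theta_k$ with $f_{ik}$ the
posterior node weights; intercepts drop the $\theta_k$ factor, and GPCM
intercepts use step indicators minus step probabilities. Group means and
variances get score columns too (the grid-substitution derivatives), so
the case-wise gradient is exact for the quadrature-defined likelihood —
which is why the finite-difference validation (central differences of
`caselik()`, step $10^{-5}$) agrees to $10^{-5}$ rather than only up to
quadrature error.

By default the group distribution parameters are *excluded* from the tested
set (the invariance hypothesis concerns the item parameters; impact is the
modeled alternative to DIF in the trait distribution), but
`include_impact_pars = TRUE`, or listing their indices in `pars`, includes
them; $\hat I$ then refers to whatever is tested.

$\hat I$ is the outer product of gradients $S^\top S / N$. OPG requires no
second derivatives and matches the standardization under which the
component bridges are asymptotically independent. Its inverse square root
is taken by symmetric eigendecomposition, and eigenvalues below
$10^{-10}$ of the largest are a hard error rather than a ridged
pseudo-inverse: a singular score covariance means the tested parameters are
not jointly identified, and the user should see that instead of a silently
altered statistic.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `nodes` | 61 | Gauss–Hermite nodes (MML); stability of posterior moments |
| `tol` | 1e-5 | EM stopping tolerance on parameter change |
| `maxit` | 500 | EM iteration cap; warning (not error) when hit |
| `trim` | (0.1, 0.9) | maxLM window, as fractions of $N$ |
| `reps` | 50000 | Monte Carlo replications for sup-type p-values |
| `pars` | all item parameters | tested parameter subset |
| `pvalue_grid` | "boundaries" | null grid for the maxLM p-value (see below) |

# Numerical choices

**Ties.** The process is evaluated only at boundaries between distinct
sorted covariate values. Within a tie block the ordering is arbitrary, so
any value of the process there depends on an arbitrary permutation; a
statistic that includes such points is not a function of the data.

**Trimming.** maxLM divides by $t(1-t)$, which explodes at the edges; the
default window $(0.1, 0.9)$ is conventional and exposed because published
values do not always state their window. (The Verbal Aggression
reproduction is insensitive to it: the maximum is attained in the
interior.)

**Monte Carlo p-values.** maxLM and maxLMo p-values are simulated (50,000
bridge replications by default, seed recorded in the result) rather than
interpolated from published critical-value tables: exact for the evaluated
functional, reproducible, and dependency-free. By default the simulation
runs on exactly the observed admissible boundary proportions. With heavily
tied covariates this grid is coarse, and its supremum is stochastically
smaller than the continuous-time supremum that classical table-based
p-values refer to — the p-values are then genuinely smaller (the test
correctly pays for maximizing over fewer candidate points).
`pvalue_grid = "continuous"` instead simulates the continuous-time
supremum on a dense grid when comparability with table-based output is
wanted; on the Verbal Aggression anger test (29 distinct covariate values)
the two conventions give visibly different p-values for the same statistic
of 14.019, exactly as this analysis predicts.

**DM p-value.** The analytic series
$2\sum_{k \ge 1} (-1)^{k+1} e^{-2k^2c^2}$ (100 terms) is the
continuous-time crossing probability of one bridge component; components
are combined as $1 - (1 - p_1)^P$, using the asymptotic independence
created by the $\hat I^{-1/2}$ standardization. A finite grid's supremum
undershoots the continuous supremum by the classical Siegmund overshoot
($\approx 0.5826\sqrt{\Delta t}$ on the statistic scale), so the
test-suite validation simulates on a 1000-point grid and compares at the
continuity-corrected level; the reported p-value itself stays the plain
series.

**maxLMo.** The limiting process is evaluated at the observed cumulative
level proportions; with two levels the statistic reduces to the single-cut
LM value and its Monte Carlo p-value agrees with the $\chi^2_P$ tail, a
reduction the tests check.

**Ordered covariates as continuous.** maxLMo (level cut points) is the
default pairing for ordered covariates; passing an ordered covariate to
maxLM/DM deliberately treats its ranks as a continuous ordering, which is
occasionally wanted for many-level ordinal scales.

# The synthetic-data generator

`sim_design()`/`simulate_responses()` generate responses with known
structure: Rasch/2PL/GPCM item parameters, continuous (uniform or normal)
and categorical covariates, group impact on the trait distribution, and
DIF in two effect forms — a group shift of a parameter (for continuous
covariates, applied to the upper half at the median split: DIF between the
first and second half of the ordered sample) and a shift linear in the
standardized covariate, the minimal smooth extension. A truth record
reconstructs every per-person parameter, and `rejection_rate_study()`
loops design → fit → test with per-replication seeds derived from the
design seed, so size/power studies are reproducible and pairable across
effect sizes.

The generator emulates the *shape* of the empirical datasets used in the
field (binary and 5-category Likert responses, numeric and categorical
person covariates, group impact). It does not emulate real-data features
such as local dependence between items, missing responses, guessing,
multidimensionality, or covariate measurement error — so passing
calibration tests on generated data shows correctness of the statistics
under the model, not robustness to model misspecification.

# Problem sizes in the test suite

The suite validates score gradients at $N = 200$, $J = 5$ per model;
calibrates LMuo and maxLM size on DIF-free Rasch data at $N = 500$,
$J = 10$ over 500 replications (sharing one simulated null sample across
replications, valid because a continuous covariate gives the same
admissible boundary grid almost surely); and traces power over DIF sizes
$\{0, 0.4, 0.8\}$ with paired seeds, 500 replications each. These sizes
give exact-binomial 99% bands around the nominal level that are tight
enough to catch calibration errors while keeping the whole suite
reasonable to run routinely. The impact-recovery checks use 4-category
GPCM items because the group variance is weakly identified by small sets
of dichotomous items (its MLE sampling error there is several times
larger — measured against an independent direct optimizer, which the EM
matches to machine-level log-likelihood).

# Known limitations

* No 3PL/4PL asymptotes, graded/nominal response, multidimensional or
  mixture models; no CML for rating-scale/partial-credit models.
* No missing-data support (by design, see above).
* OPG is the only covariance estimator; no sandwich/observed-information
  variants.
* The DM component-combination assumes asymptotic independence after
  standardization; for very small $N$ and many parameters it is
  approximate.
* p-values for recursive partitioning, anchor selection, and effect sizes
  are out of scope.
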