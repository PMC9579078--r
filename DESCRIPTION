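Package: scoreflux
Title: Score-Based Measurement Invariance Tests for Item Response Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of differential item functioning (DIF) along continuous,
    ordered, or unordered person covariates via score-based (M-fluctuation)
    tests. Fits the dichotomous Rasch model by conditional maximum likelihood
    using elementary symmetric functions, and the 1PL, 2PL, and generalized
    partial credit models by marginal maximum likelihood (EM with
    Gauss-Hermite quadrature), optionally with multiple-group impact on the
    latent trait distribution. Computes analytic case-wise score
    contributions, the standardized cumulative score process ordered by a
    person covariate, and the double-maximum (DM), maximally selected LM
    (maxLM, maxLMo), and unordered LM (LMuo) statistics with analytic,
    chi-square, or Monte Carlo p-values, for the full parameter set or
    arbitrary subsets. Includes a synthetic response generator with
    configurable impact and DIF for calibration and power studies.
License: MIT
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, lme4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
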