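Package: lplsr
Title: Three-Block L-PLS Regression with Regularized Variable Elimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits L-shaped three-block partial least squares (L-PLS)
    regression, in which a background matrix describing the predictor
    variables (for example Gene Ontology memberships of genes) steers the
    latent-component weights through a mixing parameter alpha. Includes
    variable importance on projection (VIP) for both predictor columns and
    background rows, a two-stage stepwise regularized backward elimination
    with a significance-based rejection level, nested split/tuning schemes
    (cross-model validation), selectivity scoring over repeated data splits
    with a permutation null, and a block-covariance Monte Carlo simulator
    with a power analysis for variable selection. Designed for
    genotype-phenotype mapping where per-gene numeric features and gene
    annotations are available.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
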