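---
title: "Three-block L-PLS regression with regularized variable elimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-block L-PLS regression with regularized variable elimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lplsr)
```

## The modelling problem

Genotype–phenotype mapping with per-gene numeric features typically faces
`K` in the thousands and `N` in the tens: a phenotype vector `y` (length
`N`), a genotype feature matrix `X` (`N × K`, e.g. evolutionary-distance
scores per gene), and — crucially — *background information* about the
genes themselves: Gene Ontology memberships, essentiality, copy-number or
loss-of-function annotations. That background is an `L × K` binary matrix
`Z` whose rows describe the columns of `X`. The three blocks form an
L-shaped layout: `y` against the rows of `X`, `Z` against its columns.

Ordinary PLS compresses `X` into a few latent components chosen to covary
with `y`, but it ignores `Z`. L-PLS injects the background at the
modelling stage: each component's weight vector is a convex combination of
the X-driven direction and a Z-informed direction, governed by a mixing
weight `alpha` in `[0, 1]`. At `alpha = 0` the model *is* ordinary
univariate NIPALS PLS (the package treats this as an exact invariant, and
the test suite verifies it against an independent PLS implementation); at
`alpha = 1` the weights are steered entirely by the annotation structure.

## The fitting algorithm

`lpls()` first centers the blocks: `y` by its mean, `X` doubly (row,
column and grand means removed — every row and column of the centered
matrix sums to zero), `Z` within rows. For each component `a`:

1. the X-driven direction is `v_x2 ∝ X'y` (unit norm);
2. the Z-informed direction projects it through the row space of the
   background: `v_z1 ∝ Z'(Z v_x2)` (unit norm);
3. the mixed weight `w = alpha v_z1 + (1 - alpha) v_x2` is renormalised;
4. scores are `t = X w` for `X` while `w` itself serves as the score
   vector for `Z`; loadings are least-squares projections
   (`p_y = y't/t't`, `p_x = X't/t't`, `p_z = Z w`);
5. all three blocks are deflated by their rank-one reconstructions before
   the next component.

With a single response no inner NIPALS iteration is needed — the latent
directions have the closed form above, which degenerates correctly at
`alpha = 0`. An optional refinement loop (`refine = TRUE`) re-projects the
mixed weight through `Z` until the direction stabilises (change below
`1e-10`); in our experience it changes nothing materially for binary
membership matrices, so it is off by default. Coefficients are assembled
as `beta = W (P_x'W)^{-1} p_y`, and the fitted-value identity
`X00 beta = T p_y` together with pairwise score orthogonality is enforced
to `1e-8` in the tests.

Numerical conventions worth stating explicitly:

* **Signs.** NIPALS signs are arbitrary; we fix the first non-zero entry
  of `v_x2` to be positive before mixing, so fits are reproducible across
  platforms.
* **Zero detection.** A vector counts as numerically zero below
  `1e-12` times the Frobenius norm of the matrix that produced it. A zero
  `X'y` means no further component exists and the fit aborts, reporting
  the largest achievable component count. A zero `v_z1` marks a
  Z-uninformative component: harmless while `alpha < 1`, an error at
  `alpha = 1` (a degenerate mixed direction aborts rather than silently
  flipping).
* **Minimum problem size.** Double centering maps a single predictor
  column to the zero matrix (its row means equal the column), and a
  single background row centers to zero. Models therefore need at least
  two active variables in each eliminable block; the elimination below
  respects that floor. Similarly, at `alpha = 1` each component consumes
  one rank of the row-centered `Z`, which caps the usable components at
  `L - 1` for partition-structured backgrounds.
* **Prediction.** The centering of a new sample uses the training column
  and grand means together with the new row's own mean; predicting the
  training rows reproduces the in-sample fit exactly.

## VIP and two-stage elimination

Variable importance on projection aggregates each variable's squared
weight across components, weighted by the response variance each
component explains (`SS_a = p_ya^2 t_a't_a`):

    VIP_Xk = sqrt( K * sum_a SS_a (w_ak)^2 / sum_a SS_a )

and analogously for background rows with the per-component-normalised
Z-loadings in place of the weights. Both are normalised so the squared
scores average 1 — the conventional "VIP below 1 means below average"
reading. We use this standard form deliberately: it is dimensionally
consistent, reduces to the classic single-block VIP at `alpha = 0`, and
keeps the sum-of-squares invariant (`sum VIP^2 = number of active
variables`) that the tests assert at every elimination iteration.

Elimination proceeds in two stages (`lpls_select()`):

* **Stage 1** ranks columns of `X` by `VIP_X`. With `M` variables below
  the cutoff `u`, the `S = ceiling(f M)` worst are removed (`f` is the
  step length; ties at the boundary break by original column index).
  Removing column `k` of `X` removes column `k` of `Z` too — the blocks
  must keep describing the same variables. The stage terminates when
  `M = 0` or fewer than two variables would remain.
* **Stage 2** repeats the procedure on the rows of the reduced `Z`,
  ranked by `VIP_Z`, with `X` fixed to the stage-1 survivors. If the
  surviving columns make the row-centered `Z` identically zero (all rows
  constant across them), the background cannot be ranked and the stage
  terminates with all rows kept.

Every iteration records a cross-validated RMSE `E_g` over a fold
partition fixed once per selection run. After a stage completes,
`choose_model()` finds the minimal `E*`, then compares every sparser
iteration against it with a paired two-sided t-test on held-out squared
residuals (paired by sample — hence the fixed folds). The chosen model is
the sparsest whose p-value exceeds `1 - d`: the rejection level `d`
prices how much non-significant error increase one accepts in exchange
for fewer variables. VIP values are computed from the full-training fit
at each iteration; the RMSE comes from the cross-validation. Variables
tied exactly at the cutoff count as *not* below it.

## Tuning and cross-model validation

`make_splits()` draws repeated random 25/75 test/training partitions (10
by default; the repeats overlap partially by construction). Inside a
training set, `lpls_tune()` runs two levels:

1. `(alpha, ncomp)` by leave-one-out cross-validation of the plain L-PLS
   fit over a grid (default `alpha` step 0.01, up to 10 components);
2. `(f, d)` by 10-fold cross-validation of the *entire* two-stage
   selection at the chosen `(alpha, ncomp)`, with the cutoff fixed at its
   upper limit `u = 10` so the amount of elimination is governed by `d`
   alone.

Running the `(alpha, ncomp)` search once per training set, rather than
nested inside every `(f, d)` fold, is a deliberate simplification: the
L-PLS hyperparameters concern the fit itself and are stable across the
elimination path, while full nesting would multiply cost by the size of
the `(f, d)` grid for no change in the selection ordering. All tuning
sees only training samples, so wrapping it in the outer repeated splits
yields a complete cross-model validation — the test suite asserts that no
held-out index can reach any inner fold. Ties are resolved
parsimoniously: smaller `ncomp`, then smaller `alpha`. The level-1 splits
are drawn uniformly (no stratification), and the full `Z` is used at
every level — only `y` and `X` are split.

Stage-2 refits reuse the `(alpha, ncomp)` chosen at stage entry rather
than re-tuning per iteration; re-tuning is available by calling
`lpls_tune()` on the reduced blocks but is not the default (cost, and the
comparison across iterations should hold the model class fixed).

## Selectivity scores and the permutation null

A variable selected as one of `m` in a split earns `1/m` from that split
(`selectivity()`); summing over the repeated splits gives a stability
score — high scores mean "repeatedly selected among few". Mass is
conserved by construction: each non-empty split contributes exactly 1.
`permutation_null()` calibrates significance by re-running the entire
split + selection pipeline with the response permuted, pooling the null
scores, and reporting a quantile threshold (default 95th percentile, 100
permutations by default; neither is canonical and both are arguments).

## The simulation design and what it does (not) emulate

`sim_config()` defines a joint Gaussian model: `L` groups of predictors,
equicorrelated within groups (correlation `rho_l`, unit variances, so the
predictor block is a correlation matrix), independent across groups, and
a latent standard-normal response with covariance `c_l` to every member
of group `l`. The default design has 14 groups of sizes
`[10,10,10,100,10,10,10,10,10,10,10,100,100,100]` (500 variables),
within-group correlations `[0.5, 0.5, 0.5, 0.2, 0, ..., 0]` and response
covariances `[0.35, -0.3, 0.25, 0.2, 0, ..., 0]` — only the first four
groups (130 variables) carry signal. Validity is checked in closed form:
for equicorrelated blocks the residual variance of the latent response is

    1 - sum_l k_l c_l^2 / (1 + (k_l - 1) rho_l)

which the default design puts at 0.3077; a brute-force quadratic form on
the constructed joint matrix agrees to `1e-10` in the tests. The latent
response is binarised by sign into a -1/+1 class code (the threshold is
an argument), and `Z` encodes group membership as 0/1 indicators — the
natural encoding of "variable k belongs to group l", and the analogue of
the gene-to-GO-term membership matrix in real data. The default sample
size is 100; analyses in this package pin their own `n` explicitly.

What passing simulation tests *do* show: the estimator recovers the
generating covariance structure, background information raises selection
power when `Z` reflects the true grouping, and the pipeline's accounting
(mass conservation, nesting, determinism) is correct. What they *do not*
show: robustness to non-Gaussian features, heteroscedastic noise,
annotation errors in `Z` (real GO terms are incomplete and overlapping),
or `K >> N` ratios of genome scale — real yeast data has thousands of
genes on a few dozen strains, where tuning variance dominates.

## The power study

`power_analysis()` profiles the two-stage selection across `alpha` on
replicated simulated datasets: *power* is the fraction of truly relevant
variables selected, *FPR* the fraction of irrelevant ones. One dataset is
drawn per replicate and reused across the whole `alpha` grid, making the
comparison paired (lower Monte Carlo variance than independent draws per
`alpha`). Group-level recovery is reported alongside (any-member and
majority-member), since selecting annotated groups is often the real
goal. Defaults follow the elimination-by-`d` practice: `u = 10` so every
variable is a candidate, `d = 0.80` so the chosen model stays near the
cross-validated optimum — a power study should measure ranking quality,
not maximal sparsification. The acceptance-scale study uses a reduced
design (4 signal + 4 noise groups of 5 variables, `n = 50`, 50
replicates), which keeps the full curve under a minute on one CPU; at
that scale power rises from about 0.21 at `alpha = 0` to about 0.37 at
`alpha = 0.9` while the FPR stays near 0.06.

## Known limitations

* Only a single response is modelled; multiple phenotypes are fitted one
  at a time (the command-line wrapper loops).
* The t-test in `choose_model()` treats held-out squared residuals as
  paired and approximately normal; for very small `N` the test is
  anti-conservative and predefined parameters are preferable — the
  splitting utilities warn below 12 samples.
* Binary class responses are handled by the same least-squares machinery
  (-1/+1 coding), not by a logistic link; predicted values are scores,
  not probabilities.
* `exo`-style L-PLS variants, matrix responses and soft-thresholding PLS
  are out of scope; the no-background baseline is exactly `alpha = 0`.
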