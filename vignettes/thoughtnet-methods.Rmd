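---
title: "Methods: multi-block factor analysis and repeated-measures network statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-block factor analysis and repeated-measures network statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thoughtnet)
```

## The analysis problem

In repeated resting-state designs, each subject is scanned several
times (here 2 days x 2 runs) and reports the content of their
self-generated thought after every scan on a multi-item questionnaire.
Two questions follow: what latent dimensions structure the reported
thought content, and does whole-brain functional connectivity covary
with those dimensions *within* a person from scan to scan?  The first
is answered with multiple factor analysis (MFA) of the multi-block
questionnaire; the second with a network-based statistic (NBS) whose
permutation scheme respects the repeated-measures structure.

## Multiple factor analysis with nested normalization

Each occasion's `subjects x items` sub-table is treated as one block.
Blocks are centered column-wise and, by default, scaled to unit column
variance (`scale = TRUE`); questionnaire items are used over quite
different ranges, and unit scaling keeps an idiosyncratically
high-variance item from dominating.  Raw-covariance analysis is
available via `scale = FALSE`.

Each block `X_b` then receives the classical MFA weight
`w_b = 1 / sigma_1(X_b)^2`, where `sigma_1` is the first singular
value, so every block's leading dimension carries unit inertia.  The
crossed day/run design is additionally normalized with a *nested*
two-level scheme (`nested = TRUE`): the base-weighted blocks of each
day (occasions 1&2 and 3&4) and of each run position (occasions 1&3
and 2&4) are concatenated, and each block's weight is further divided
by the squared first singular value of its day group and of its run
group.  The arithmetic of adding the day- and run-level inertias as
normalization factors is a declared design choice of this package: the
multiplicative two-level division reduces to hierarchical multi-block
weighting and collapses to standard MFA when the groups are
degenerate; `nested = FALSE` gives plain MFA.  All three factors are
recorded in the `mfa_weights` object.

The grand decomposition is the SVD of `Z = [sqrt(w_b) X_b]`.  With
`Z = U D V'`, the package reports

* eigenvalues `lambda_l = d_l^2` and their proportions of total
  inertia (`variance_table()`; component retention is the caller's
  choice -- the default configuration keeps 3, and no automatic elbow
  detection is attempted);
* loadings `q = D * V / sqrt(w)` (variable factor scores);
* compromise factor scores `F = U D`, one per subject;
* partial factor scores per occasion,
  `F_b = K w_b X_b (V_b / sqrt(w_b))`, whose mean over the `K = 4`
  occasions equals `F` exactly (barycenter identity; asserted to
  1e-10 in the tests).

Each component's sign is fixed so its largest-magnitude loading is
positive; analyses that care about orientation should use declared
contrasts or absolute loadings.

### Contributions and the bootstrap reliability rule

The contribution of item `j` at occasion `b` to component `l` is
`ctr = w_b q^2 / lambda_l`; within a component the 48 cells sum to 1,
so with 12 items the expected per-item contribution summed over the 4
occasions is 1/12 ~ 0.083 under equal loading.  For each item the four
per-occasion contributions are resampled with replacement (4 draws per
replicate, default 10,000 replicates) and summed; the percentile
interval at level `1 - alpha/12` (Bonferroni over items, with
uncorrected bounds also reported) forms the confidence interval, and
an item is flagged as a reliable contributor when the lower bound
exceeds 1/12 -- i.e. when it is consistently influential across all
four occasions.

This resampling acts on only four values per item, and that coarseness
has a consequence worth stating plainly: at the Bonferroni-corrected
percentile level the lower bound converges to four times the smallest
per-occasion contribution, so the rule effectively asks whether *all
four* occasion contributions exceed their equal-share value.  On
exchangeable (structure-free) items the validation suite measures the
family-wise false-flag rate of this rule and finds it above a nominal
5% level.  The rule is therefore a *stability screen*, not a
calibrated hypothesis test; items flagged only marginally should be
interpreted with care.  A subject-level bootstrap (refitting the MFA
per resample) would calibrate better but tests a different null and is
out of scope here.

## Connectivity stacks

ROI time series (one column per region, >= 3 volumes, no constant
series) are correlated pairwise with Pearson R; matrices are
vectorized along the upper triangle in row-major order
((1,2), (1,3), ..., (N-1,N)), with 1-based node indices both
internally and in all files.  Raw R enters the GLM by default; a
Fisher z option (`fisher_z()`) exists but is off, matching the
convention of correlating parcel series directly.  Only subjects with
all four usable scans are retained (the within-subject permutation
scheme requires complete blocks); incomplete subjects are dropped with
a named warning.  All edges are included -- no neighbor-edge
exclusion.  Parcellation is upstream of this package: node identity
lives in a `label / hemisphere / x / y / z` (MNI mm) table.

## The repeated-measures network statistic

For a per-scan predictor `x` (a partial factor score), every edge is
regressed on `[subject indicators, x]` by OLS.  Subject-indicator
nuisance is equivalent to within-subject centering, so `t` measures
within-subject covariation of the edge with thought content; an
alternative nuisance coding (`"mean_fc"`, the subject's mean
connectivity of the edge under test as a covariate) is available
behind a flag.  Edges with `t` beyond the primary threshold (default
4.7; tails positive / negative / two-sided) form a graph whose
connected components (igraph) are the candidate networks, ordered by
extent with node-index tie-breaks.

Inference follows Freedman-Lane: the nuisance-only model is fitted per
edge, residuals are permuted *within each subject's four scans*
(exchangeability blocks; the identity permutation is allowed in
sampling, and an exhaustive mode enumerates all `prod(n_b!)`
permutations for small designs), the full model is refitted on the
reconstructed data, and the maximal supra-threshold component size is
recorded, giving the null distribution for family-wise error control.
Two implementation identities keep this exact and fast: the refit is
computed through the Frisch-Waugh-Lovell projection, and for indicator
nuisance the within-block permutation preserves block-centering, so
each permutation reduces to one matrix-vector product.  Both were
verified against a literal fit-permute-refit implementation at 1e-15
before being adopted; the permutation loop's component sizes use an
internal union-find that the tests cross-check against the
igraph-based `find_components()`.

Component p-values use `p = (1 + #(null >= observed)) / (1 + n_perm)`
(never zero; the exhaustive mode uses the exact proportion).  The
component statistic is extent (edge count) by default, with an
intensity option (`sum(|t| - threshold)`).  Across the contrast family
-- by default 3 components x 2 one-sided tails = 6 tests --
Benjamini-Hochberg FDR is applied to the per-contrast minimum
p-values.  Per-edge effect sizes use the repeated-measures convention
`d = 2 t / sqrt(df)` averaged as `|d|` over a component's edges; this
definition is a declared convention of the package and is reported
alongside mean |t|.

A threshold low enough that the supra-threshold graph spans nearly all
edges in most permutations cannot rank the observed network; the null
builder warns in that regime.

## The synthetic-data generator

The generator emulates the study conditions end to end: 19 subjects x
4 occasions (2 days x 2 runs), 12 items, three latent thought factors,
and connectivity over a configurable parcellation (default 60 nodes,
up to 470; the default keeps the full validation suite in minutes).

* **Scores.**  Each factor score is a subject-level draw plus an
  independent occasion-level draw, both zero-mean Gaussian.  The
  subject-level SDs default to (1.2, 0.9, 0.6) and the occasion-level
  SD to 0.5: thought dimensions with distinct prevalence produce a
  separated, ordered component spectrum, which is what makes factor
  recovery identifiable at all -- with exactly equal factor variances
  the leading eigenvectors are rotationally degenerate and no method
  could attach components to factors.
* **Items.**  `item = loadings %*% score + noise`, mapped affinely
  onto a 0-100 visual-analog scale (`50 + 15 * raw`, clipped) and
  continuous by default (optional rounding).  The default loading
  pattern splits the 12 items 5/4/3 across the three factors with unit
  loadings -- dimensions recruit unequal numbers of items, which also
  keeps the spectrum separated after items are standardized to unit
  variance.  Item-level marginals are conventional, not calibrated to
  any particular instrument.
* **Edges.**  Per scan, each edge is population baseline (N(0.25,
  0.08)) + a stable subject offset (SD 0.1, exactly what the subject
  nuisance absorbs) + `beta * score` on planted edges + scan noise
  (SD 0.1), clipped to (-1, 1).  The planted effect enters edge-wise;
  positive semi-definiteness of the implied matrix is *not* enforced,
  which is harmless for the edge-wise GLM.  Users needing valid
  correlation matrices should use the ROI time-series path, where
  regions share community signals and planted pairs share an extra
  signal whose coupling varies with the factor score.
* **Seeds.**  One user seed expands into fixed per-stage child seeds
  (scores, questionnaire, connectivity, time series, bootstrap, NBS),
  so adding a stage never perturbs another stage's stream, and every
  output is bit-reproducible.

`calibrate_effect(d, params)` converts a target per-edge Cohen's d
into the generator's `beta` given the design (expected within-subject
predictor sum of squares and the GLM's residual degrees of freedom).

## Validation design and problem sizes

The test suite validates three layers, with all sizes chosen as
package defaults for desk-scale runs:

* **Identities and oracles** (seconds): contribution normalization and
  the 1/12 identity at 1e-10; barycenter at 1e-10; single-block MFA
  against an independent SVD PCA at 1e-8; edge-GLM t statistics
  against a normal-equations solver at 1e-8; components against a BFS
  oracle and an example 26-edge sensorimotor network that must form a
  single 19-node component; BH against a hand step-up; sampled
  permutation p-values against the 36-permutation exhaustive null of a
  2-subject x 3-scan design.
* **Error control** (about two minutes): 200 null datasets (10
  subjects, 40 nodes, no planted effect, |t| > 3, 500 permutations)
  run through the full questionnaire -> MFA -> NBS chain; the
  empirical family-wise error is required to lie in a binomial band
  around the nominal 5%.
* **Power** (about a minute): 50 replicates of a planted dense 20-node
  module (190 edges) among 40 nodes at per-edge d = 0.6, 19 subjects x
  4 scans, threshold 1.8, positive tail.  The threshold and module
  size come from a design-stage power analysis: at per-edge d = 0.6
  the per-edge detection probability is only about two-thirds at any
  sensible threshold, so a *sparse* planted network can never overlap
  its detection at Jaccard 0.5 -- aggregating power over a dense
  module is the regime in which extent-based NBS is expected to work.
  The criterion is Jaccard >= 0.5 between the detected significant
  component and the planted edges in at least 80% of replicates, with
  the generator's true occasion scores as predictor so that the
  network stage is assessed separately from factor-estimation error.

What passing these simulations does *not* show: real questionnaire
items are bounded, skewed and often discrete; real connectivity has
heavy-tailed, spatially structured noise and global artifacts; real
effects are not edge-homogeneous cliques.  The suite establishes
algorithmic correctness and statistical calibration under the stated
generative model, not empirical sensitivity on any particular dataset.

## Numerical choices and degenerate inputs

* Zero-variance questionnaire columns: explicit error naming the
  column when scaling (column of zeros when not).
* All-zero blocks, rank-deficient GLM designs, components with (near)
  zero eigenvalue, empty stacks and empty nulls all raise named
  errors rather than propagating NaN.
* Residual variance exactly zero at an edge yields an infinite t,
  which thresholding handles naturally.
* Component ordering is deterministic (extent descending, then
  smallest node index); bootstrap, permutation and generator streams
  are all seeded.
* Tolerances in the tests reflect the arithmetic: 1e-10 to 1e-12 for
  identities, 1e-8 for decompositions reached by different numerical
  routes.

## Known limitations

No missing-data handling, no loading rotation, no mixed-effects
alternative to the permutation GLM, no spatial statistics beyond graph
components, and no voxel-level processing.  The bootstrap reliability
screen is anticonservative as a test (see above).  The nested
normalization formula is one reasonable reading of adding group
inertias as normalization factors; `nested = FALSE` is provided for
the standard analysis.
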