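---
title: "Prior-guided sparse canonical correlation for imaging genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-guided sparse canonical correlation for imaging genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snfcca)
```

# The problem

Imaging genetics asks which genetic variants drive which brain phenotypes.
With an imaging quantitative-trait matrix $X \in \mathbb{R}^{n \times p}$
(subjects $\times$ regional measures, e.g. PET uptake per cortical region)
and a genotype dosage matrix $Y \in \mathbb{R}^{n \times q}$ (subjects
$\times$ SNPs, additive 0/1/2 coding), sparse canonical correlation analysis
(SCCA) seeks sparse weight vectors $u, v$ whose composites $Xu$ and $Yv$ are
maximally correlated. Because $p + q$ is commonly of the order of $n$, plain
CCA overfits badly, and even sparse CCA benefits from side information.

This package implements a *discriminative* SCCA whose extra penalty pulls
the composites to vary smoothly over a prior graph, plus the machinery to
build that graph from the data themselves by similarity network fusion
(SNF), from diagnosis labels, or from gene co-expression.

# The model

The fitted criterion is the Lagrangian form

$$\max_{u,v}\; u^\top X^\top Y v
 - \tfrac{\gamma_1}{2}\lVert Xu\rVert_2^2
 - \tfrac{\gamma_2}{2}\lVert Yv\rVert_2^2
 - \tfrac{\beta_1}{2} P_1(u) - \tfrac{\beta_2}{2} P_2(v)
 - \lambda_1\lVert u\rVert_1 - \lambda_2\lVert v\rVert_1 ,$$

with graph penalties $P_1(u) = u^\top X^\top L X u$ and
$P_2(v) = v^\top Y^\top L Y v$ for a subject-level prior with combinatorial
Laplacian $L = D - W$ (for a feature-level prior the penalty acts on the
weights directly, $u^\top L u$). The Laplacian quadratic form equals
$\tfrac12 \sum_{ij} W_{ij}\,((Xu)_i - (Xu)_j)^2$: connected subjects are
pushed toward similar composite scores, which is exactly what a
disease-severity graph should enforce.

The problem is biconvex. `dscca()` alternates the two conditional problems,
each solved by Nesterov-accelerated proximal gradient with soft-thresholding
as the proximal map, a backtracking step size initialized at $1/\hat L$
($\hat L$ from 20 power iterations on the quadratic-term matrix), inner stop
at relative weight change $< 10^{-8}$ (cap 1000 iterations), outer stop at
absolute objective change $< 10^{-6}$ (cap 100 alternations).

## Why the iterates are renormalized

A point worth documenting explicitly: the pure Lagrangian above is
degenerate as an unconstrained problem. If every canonical correlation is
below 1, the bilinear gain $u^\top X^\top Y v$ can never outweigh the two
quadratic terms, and the global optimum is $u = v = 0$; an alternation on
the raw objective either collapses to zero (killing any sparse regime for
$\lambda$) or drifts to overfit dense directions. The original two-view
problem carries the scale constraints $u^\top X^\top X u = 1$,
$v^\top Y^\top Y v = 1$, and this implementation enforces them by
renormalizing each weight vector to unit composite variance after its
update — the standard device in this algorithm family. All moment matrices
are used in covariance scale ($X^\top Y / n$ etc.), so $\lambda$ and
$\beta$ have data-size-free meaning and a log-spaced grid over
$[10^{-3}, 10]$ brackets the useful range. The recorded
`objective_trace` is evaluated at the normalized iterates and is
nonincreasing by construction: a cycle that fails to decrease it is
rejected and the alternation stops at the previous (better) point. After
convergence the weights are rescaled once more so $\lVert Xu\rVert_2 =
\lVert Yv\rVert_2 = 1$ and signs are fixed by making the largest $|u_j|$
positive (CCA is sign-ambiguous; tests need determinism).

# Prior construction

**Fused similarity network.** Per modality, subjects get a scaled
exponential similarity kernel
$W_{ij} = \exp(-\rho_{ij}^2 / (\mu\,\varepsilon_{ij}))$ on Euclidean
distances $\rho$, with the local scale $\varepsilon_{ij}$ averaging the
mean distance of each subject to its $K$ nearest neighbours (self included,
so the self-distance 0 enters the mean) and $\rho_{ij}$ itself. Defaults
$\mu = 0.5$ (recommended range 0.3–0.8) and $K = 20$. Two derived forms
feed the fusion: the *status matrix* $P$, row-normalized with the diagonal
pinned at $1/2$, and the *KNN affinity* $S$, row-normalized over the $K$
nearest non-self neighbours and zero elsewhere (keeping the self out of $S$
is the usual convention — a self-loop would dominate the diffusion; the
neighbour rule is configurable via `include_self`). Cross-diffusion then
iterates $P^{(1)} \leftarrow S^{(1)} P^{(2)} S^{(1)\top}$ and symmetrically
for modality 2, re-applying the status normalization after every sweep so
self-similarity stays highest. We stop when the relative Frobenius change
drops below $10^{-6}$ (convergence is fast; default cap 20 sweeps), and
return the symmetrized average of the two converged status matrices,
renormalized once more. The averaging-plus-symmetrization step is our
choice: the downstream Laplacian penalty needs a single symmetric graph,
and the average of the two converged matrices is the natural single
network supported by both modalities.

**Diagnosis network.** A block-diagonal graph connecting all subjects that
share a diagnosis. With diagonal $1/2$, the printed within-group weight
$1/(2g)$ for a group of size $g$ leaves row sums at $(2g-1)/(2g)$, not the
unit row sums the normalization is meant to produce; we therefore divide by
$g - 1$ by default, which makes every row sum exactly 1, and expose the
literal $g$ divisor behind `literal = TRUE`.

**Co-expression network.** For a feature-level prior, expression samples
mapped to imaging regions yield a sample-by-sample partial-correlation
matrix (negated scaled inverse of the between-sample covariance,
ridge-regularized by $10^{-3}\,\mathrm{tr}(C)/n$ — with few genes the
covariance is singular), aggregated block-wise by the median to a
region-by-region similarity; negative aggregates are clipped to zero.
Note one practical consequence of the ridge: a duplicated expression
profile produces a partial correlation slightly below 1, so "identical
profiles give the maximal similarity" holds only up to the regularization.

**Penalty placement.** A subject-level graph is $n \times n$ and is shared
by both sides of the model (one severity graph, two views of it). A
feature-level graph must match one side's dimension and penalizes that
side's weights directly; both placements are supported and selected by the
prior's `level` field.

# Cross-validation harness

`cv_dscca()` runs stratified 5-fold nested cross-validation: outer folds
estimate held-out canonical correlation, inner folds (default also 5) pick
the $(\lambda, \beta)$ grid point maximizing mean inner-test correlation.
Every training split re-derives its own standardization statistics and its
own prior (fused networks and diagnosis networks are rebuilt from training
subjects only), so test subjects never touch training — a canary test
asserts that garbling the test rows leaves the trained fold model
bit-identical. `all_subjects_prior = TRUE` deliberately reproduces the
leaky whole-cohort construction some studies use. Fold assignment is a
deterministic function of subject ids, labels and seed (not of row order),
so competing methods share identical partitions and group proportions by
construction.

Two selection rules are provided: `"best"` (maximum mean inner-test
correlation, the default) and `"1se"` — the sparsest grid point within one
standard error of the best. The distinction matters: the
prediction-optimal $\lambda$ systematically over-selects (the familiar
lasso phenomenon), so support-recovery workflows should use `"1se"`
(`tune_dscca(select = "1se")`), while method comparisons on held-out
correlation use `"best"`.

Weights are averaged across folds after sign-aligning every fold's $u$ to
fold 1 (flipping $u$ and $v$ jointly), and `rank_features()` orders
features by mean absolute weight, excluding exact zeros, ties broken by
feature id.

# The synthetic cohort generator

`simulate_cohort()` emulates the data regime the method targets, with the
planted truth stored for scoring:

* SNP dosages are Binomial(2, MAF), MAF uniform on $[0.1, 0.5]$; columns
  that come out constant are redrawn so standardization is well defined.
  No linkage disequilibrium or population stratification is modelled.
* The planted genetic score is a signed sum of the centred dosages over the
  $v$-support. The latent severity is
  $w = r\,\tilde s + \sqrt{1-r^2}\,\eta$ with the noise orthogonalized
  in sample, so $\mathrm{cor}(w, \tilde s) = r$ (`latent_corr`) *exactly*.
  We deliberately generate genotype $\to$ severity $\to$ imaging rather
  than shifting dosage distributions along an independent severity factor:
  shifting Binomial success probabilities saturates all support SNPs to
  near-identical step functions of severity, which caps the attainable
  canonical correlation near 0.8 regardless of the requested value — the
  causal ordering used here keeps dosages exactly in $\{0,1,2\}$ while
  making the planted correlation analytically exact (at
  `latent_corr = 1` and vanishing imaging noise the first canonical
  correlation reaches 1).
* Diagnosis groups are severity quantile bins — disease stage reflects the
  axis that links the modalities, which is what gives the diagnosis and
  fused priors their signal — and group means are then separated by
  `group_effect` (default 1.5) in the full factor $z$.
* Imaging features load on $z$ over the $u$-support (alternating signs);
  non-support features carry a fixed alternating group-offset pattern of
  magnitude `group_effect`/4 (group structure visible to the priors without
  swamping the planted sparse association); Gaussian noise has
  `noise_sd = 1`.

Defaults ($n = 250$, $p = 100$, $q = 150$, supports of 5 per side,
`latent_corr = 0.7`) are the package's benchmark world. What a green test
on this world establishes: the solver recovers planted sparse structure and
the priors improve held-out correlation *when severity genuinely links
modalities and diagnosis*. What it does not establish: behaviour under LD,
spatially correlated imaging noise, or confounded covariates — none of
which the generator emulates.

# Numerical choices and edge cases

* Kernel scale $\varepsilon = 0$ (coincident subjects) is an error, with
  the advice to jitter or deduplicate.
* KNN ties at the $K$-th neighbour break by ascending subject index —
  deterministic across platforms.
* Status normalization requires positive off-diagonal row mass; an
  isolated subject is an error rather than a silent division by zero.
* An all-zero weight vector after thresholding (λ too large) returns
  `converged = FALSE` with a warning instead of failing.
* Genotype missing values are imputed by per-SNP mode — the conventional
  fallback for additive coding when no reference panel is in scope.
* `make_folds()` refuses stratification when a group is smaller than the
  fold count.

# Known limitations

* One canonical component pair only; no deflation for further pairs.
* Exactly two modalities in the fusion.
* The co-expression prior expects the caller to supply expression data and
  the sample-to-region mapping; retrieval and probe-to-gene mapping are out
  of scope.
* Covariate residualization (age, sex, ...) must happen upstream.
* On the benchmark the held-out advantage of prior-guided fits over the
  plain baseline is real but small per fold (~0.01–0.02 correlation), so
  per-cohort comparisons are noisy; the acceptance suite pairs the
  fold-level correlations across methods (identical partitions) to test
  the ordering.
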