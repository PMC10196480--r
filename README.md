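# snfcca — prior-guided sparse canonical correlation for imaging genetics

`snfcca` associates a brain-imaging quantitative-trait matrix
(subjects × regions, e.g. regional PET uptake) with a genotype dosage
matrix (subjects × SNPs, additive 0/1/2 coding) by sparse canonical
correlation analysis, optionally guided by a prior network through a
graph-Laplacian penalty ("discriminative" SCCA). It is aimed at
imaging-genetics analysts who want multivariate region–SNP associations
that respect known or data-driven subject structure, together with the
cross-validation machinery to tune and compare such models honestly.

## The model

Given column-standardized views `X` (n × p) and `Y` (n × q), the package
maximizes

    u'X'Yv − (γ₁/2)‖Xu‖² − (γ₂/2)‖Yv‖² − (β₁/2)P₁(u) − (β₂/2)P₂(v)
           − λ₁‖u‖₁ − λ₂‖v‖₁

where the discriminative penalties are Laplacian quadratic forms:
`P₁(u) = u'X'L X u` for a subject-level prior graph with Laplacian
`L = D − W` (and `u'Lu` for a feature-level graph). Since
`u'X'LXu = ½ Σᵢⱼ Wᵢⱼ((Xu)ᵢ − (Xu)ⱼ)²`, connected subjects are pushed
toward similar composite scores. The biconvex problem is solved by
alternating Nesterov-accelerated proximal gradient steps with
soft-thresholding, unit-composite-variance renormalization per update, and
an outer stop at objective change < 1e-6.

Priors supplied in the package:

* **Fused similarity network** (`fused_network()`): per-modality scaled
  exponential kernels (μ = 0.5, K = 20 by default) turned into status and
  KNN-affinity matrices and merged by iterative cross-diffusion (SNF), so
  the prior reflects subject similarity supported by *both* modalities.
* **Diagnosis network** (`diagnosis_network()`): block graph over
  diagnosis groups, row-normalized with diagonal 1/2.
* **Co-expression network** (`coexpression_network()`): region × region
  partial-correlation similarity from expression samples mapped to
  regions — a feature-level prior.

`cv_dscca()` runs stratified 5-fold nested cross-validation with
per-training-split standardization and prior construction (leak-free by
construction), and `simulate_cohort()` generates genotype/imaging cohorts
with planted sparse canonical structure so the whole pipeline is testable
without restricted clinical data.

## Worked example

```r
library(snfcca)

cohort <- simulate_cohort(simulation_config(n = 150, p = 40, q = 60, seed = 7))
cohort
#> <synthetic_cohort: n = 150, p = 40, q = 60, latent_corr = 0.7, 3 groups, seed = 7>
#>   realized corr(X u*, Y v*) = 0.634

prior <- to_laplacian(fused_network(cohort$X, cohort$Y))
fit <- dscca(standardize(cohort$X), standardize(cohort$Y),
             lambda1 = 0.15, lambda2 = 0.15, beta1 = 1, beta2 = 1,
             prior = prior)
fit
#> Sparse canonical correlation model (prior: fused, subject-level)
#>   n = 150 subjects, p = 40 x-features, q = 60 y-features
#>   lambda = (0.15, 0.15), beta = (1, 1), gamma = (1, 1)
#>   nonzero weights: |u| = 8 / 40, |v| = 7 / 60
#>   training canonical correlation: 0.6553 (converged in 3 iterations)

score_recovery(fit, cohort$truth)
#> support_f1_u support_f1_v     cosine_u     cosine_v
#>    0.7692308    0.8333333    0.6817825    0.8981931
```

The printed model says: of 40 regions and 60 SNPs, 8 and 7 carry nonzero
weights, and the two sparse composites correlate at 0.655 on the training
cohort (the planted composite correlation of this draw is 0.634).
`score_recovery()` compares against the generator's planted truth — here
the selected SNPs overlap the planted 5-SNP support at F1 = 0.83 and the
weight vector points within cos⁻¹(0.90) of the planted direction. For an
honest held-out estimate and tuned hyperparameters, use
`cv_dscca(cohort$X, cohort$Y, labels = cohort$labels, prior_type = "fused")`,
and `tune_dscca(..., select = "1se")` for feature-selection workflows.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch
on the default synthetic benchmark: it simulates the cohort for the given
seed, builds the fused and diagnosis priors, runs the nested
cross-validation comparison of both prior-guided models against the plain
SCCA baseline (identical fold partitions), prints the fold-by-method
held-out correlation table plus the planted-support recovery of a CV-tuned
fit, and writes its JSON result map to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
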