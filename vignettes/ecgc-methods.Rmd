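---
title: "Scanning environmental covariates that shape G×E: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning environmental covariates that shape G×E: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ecgc)
```

## The question the package answers

Genotype-by-environment interaction is visible as genetic correlations
between environments falling below one: the same varieties, ranked by
additive genetic merit, re-rank across locations and managements. This
package asks *which quantitative environmental stimulus, over which
growth-stage window, produces that re-ranking* — and then *which genomic
regions control sensitivity to it*.

## Model

For environment $j$, phenotypes adjusted for year and management effects
decompose as $\tilde y_j = u_j + e_j$ with
$u_j \sim N(0, G\,\sigma^2_{u_j})$ over the genotyped varieties, $G$ the
VanRaden genomic relationship matrix. After scaling by the genetic standard
deviation, the additive effect is split along an environmental covariate
$x_j$ (one number per environment):

$$u_j = \sigma_{u_j}(\beta x_j + \tilde u_j), \qquad
  \beta \sim N(0, G\,\sigma^2_\beta).$$

Taking covariances between environments $j$ and $k$ gives the genetic
correlation

$$P_{j,k} = x_j x_k \sigma^2_\beta
          + x_j \sigma_{k,\beta} + x_k \sigma_{j,\beta} + \sigma_{j,k},$$

so if $\sigma^2_\beta > 0$ and the remaining terms do not conceal it, the
similarity kernel $x_j x_k$ of a causal covariate correlates with the
off-diagonals of the genetic correlation matrix. The scan statistic is the
Pearson correlation $r$ of those two off-diagonal vectors; $r^2$ is the
share of off-diagonal variance attributable to the covariate. The
cross-covariances $\sigma_{j,\beta}$ appear in the derivation only; they are
never estimated, and the simulation module sets them to zero.

Two points shape interpretation. First, a significant $\sigma^2_\beta$
(slope variance) alone is *not* evidence that a covariate drives G×E — the
other terms can conceal its contribution; the correlation of similarity
matrices is the direct evidence. Second, everything is estimable with
mixed models even when varieties barely overlap between environments,
because $G$ links them.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `n_pre_stages`, `n_post_stages` | 10, 20 | growth stages tiling sowing→flowering and flowering→maturity; 30 stages give $30 + \binom{30}{2} = 465$ windows per factor |
| `maf_min` | 0.05 | SNPs kept only with MAF strictly above it (conservative, avoids rare-allele false positives) |
| `scan_alpha` | 0.05 | family-wise level; threshold $\alpha/(n_{\text{cov}} \times n_{\text{traits}})$ |
| `fdr_level` | 0.05 | Storey FDR level for the slope GWAS |
| `region_gap_bp` | 100,000 | significant SNPs strictly closer than this merge into one region |
| `subsample_fraction`, `subsample_reps`, `subsample_min_count` | 0.8, 10, 5 | region reliability: a hit in at least 5 of 10 GWAS reruns on 80% variety subsets |
| `reml_tol`, `reml_max_iter` | 1e-8, 200 | REML convergence (relative parameter change) |

## Estimation choices

**Single-trait GBLUP (Step 0).** One variance ratio fully parameterises the
model, so REML is solved exactly by projecting $G$ onto the complement of
the fixed-effect space, eigendecomposing once, and maximising the profiled
likelihood in the ratio by Brent search. No iterative scheme, no tuning.
Fixed effects are year (categorical) and optionally management categories;
data-specific spline modelling of management conditions is out of scope.
Additive effects are predicted for *all* genotyped varieties at every
environment (the relationship matrix carries the information), which keeps
the slope regressions balanced across environments.

**Pairwise bivariate REML (Step 3).** Each environment pair is fitted as a
two-trait model with genetic covariance $\Sigma_u \otimes G$. Records are
matched by (variety, year); a duplicate on one side is resolved uniformly at
random under a named RNG substream. The residual covariance is estimated
from rows observed in both environments and fixed at zero when there are
none (the design is mostly disconnected; the likelihood carries no
information about it then). We maximise the REML likelihood by
average-information (AI) updates with a per-parameter trust region,
step-halving, a gradient fallback, and positive-semi-definiteness enforced
by constraint at every step — warm-started from the two single-trait
spectral fits. AI-REML was preferred over EM (both satisfy the same
stationarity conditions) because it converges in 5–15 iterations where EM
needs hundreds, which is what makes $\binom{M}{2}$ pairwise fits per trait
routine. The likelihood and derivative kernels are compiled
(RcppArmadillo). A fit that stalls without reaching the tolerance is
declared converged only if it is stationary or pinned at the correlation
bound; otherwise the pair is flagged and excluded, and more than 20%
flagged pairs abort the assembly.

**Assembly.** Off-diagonals are the pairwise genetic covariances; each
diagonal is the mean of its $M-1$ per-pair variance estimates. The matrix
is repaired to positive definiteness with the Higham projection
(`Matrix::nearPD`, the standard tool) on the covariance scale and then
standardised; the unit diagonal is exact by construction.

**Clustering and pruning (Step 4).** Covariates are clustered on their
environment-value vectors standardised across environments — two covariates
whose kernels are nearly identical sit at distance near zero in that space,
which is exactly the redundancy being pruned (a constant covariate becomes
the zero vector and clusters harmlessly). Complete-linkage hierarchical
clustering on Euclidean distances; the cluster count comes from the gap
statistic with uniform reference draws over the feature bounding box and
the firstSEmax rule. The within-cluster dispersion uses unsquared distances,
matching the conventional `clusGap` default, and `clusGap` itself is the
oracle for this computation in the test suite; we compute the hierarchy
once and cut it at every candidate count, which is what makes the gap
statistic affordable at hundreds of covariates and dozens of reference
draws. Within each cluster the significant covariate with the highest
$r^2$ is selected; exact ties go to the earlier window deterministically.

**Slope GWAS (Step 5).** Scaling the additive effects uses the genetic
*standard deviation* $\sigma_{u_j}$ — the model equation dictates it, and a
variance floor of $10^{-10}$ guards the division. The slope regression
includes an intercept; the covariate is standardised, so slopes are
invariant to its units. The GWAS is P3D/EMMAX: variance components of the
polygenic slope model are estimated once without markers, each SNP is then
a generalised least squares fixed-effect test (two-sided t). No principal
components are included. The FDR threshold uses Storey q-values:
$\pi_0$ estimated on the $\lambda$ grid 0.05–0.90 with a cubic smoothing
spline extrapolated to the grid's end and clipped to $(0,1]$; with fewer
than 100 p-values the spline is skipped and the last grid estimate used
directly. Regions chain significant SNPs strictly less than 100 kb apart;
subsampling reruns the GWAS on 80% variety subsets (only region members
need re-testing — under P3D, dropping other markers changes nothing).

## Simulation module

The power study draws, per replicate, covariate values $x_j \sim N(0,1)$, an
LKJ($\eta = 4$) noise correlation matrix (onion construction, exact) whose
off-diagonals are rescaled so the planted signal explains exactly $r^2$ of
the off-diagonal variance, sets the diagonal to $\overline{x_j^2}$, and
standardises. Under strong noise the standardised entries legitimately leave
$[-1,1]$; the scan statistic is a scale-free correlation and unaffected, so
no projection is applied. Each
replicate adds 99 independent standard-normal covariates as true negatives;
$-\log_{10} p$ scores are pooled across replicates into one ROC per
$(r^2, M)$ cell (a per-replicate ROC with a single positive would be
degenerate), with AUC by the rank formula (equals the trapezoid with
average-rank ties). Desk scale is 200 replicates per cell on the grid
subset $\{0.01, 0.053, 0.15\} \times \{5, 30, 60\}$; the full grids are the
`sim_config` defaults, and 2000 replicates per cell give the full-scale
study.

## Synthetic data: what it emulates, and what it does not

The generator builds the complete study the model assumes: 300 inbred
varieties genotyped at 2000 SNPs on 5 chromosomes, 20 environments × 3
years, sensitivity $\beta$ with variance 1 from 3 planted QTLs (half the
variance) plus a polygenic remainder, residual genetic effects with
exchangeable cross-environment correlation 0.3 and variances
$1 - x_j^2\sigma^2_\beta$ (floored at 0.05), within-environment
heritability 0.5, and daily weather whose causal factor carries an additive
offset proportional to $x_j$ on the days of the planted stage window — so
the covariate machinery reconstructs $x_j$ up to an affine map from raw
weather. Genotypes are two-founder block mosaics (24 founders, 25-SNP
blocks): a narrow-base breeding panel with family relatedness and local
linkage disequilibrium, which is what makes genomic prediction of varieties
unobserved at an environment informative, as in real breeding data. Each
environment-year evaluates a random 80 of the 300 varieties (240
records/environment — the sparse, unbalanced coverage typical of large
historical trial networks, which accumulate a few hundred records per
environment across years).

Deliberate non-goals: real geography and weather marginals, linkage maps
calibrated to a genome, management-condition structure, multi-trait genetic
architecture. Passing tests on this generator demonstrate that the
machinery recovers planted structure under the model's own assumptions —
not that any particular real dataset satisfies those assumptions.

Desk-scale runs stage the growth period into 2 + 4 = 6 stages (21
covariates per factor) and a single weather factor; the full 10 + 20
staging and 14 factors are exercised by the same code paths and differ only
in width.

## Numerical conventions and degenerate inputs

- Stage boundaries floor-interpolate cumulative day counts; remainder days
  fall in later stages; the flowering day belongs to the last pre-flowering
  stage, the maturity day to the last stage.
- Span covariates are unweighted means of stage means (not of raw days);
  pre- and post-flowering stages have different day counts, so the two
  readings differ — the unweighted reading is adopted and fixed.
- Outlier masking is per environment and trait, strictly outside
  mean ± 3 SD; a value exactly on the boundary is kept.
- MAF filtering is strict (`>`), matching the printed rule; a MAF of
  exactly 0.05 is excluded.
- Constant covariates give all-zero kernels, are flagged degenerate, and
  take p = 1 in the scan by convention.
- All stochastic stages (matching, subsampling, simulation, generation)
  draw from named substreams of one master seed: any stage can be re-run
  in isolation, and inserting a stage does not shift the others.
- Variance components are floored at tiny positive values before divisions;
  genetic correlations are constrained to $[-0.999, 0.999]$ during
  estimation and the assembled matrix is clipped to $[-1, 1]$ after
  standardisation.

## Known limitations

- The pairwise (pseudo-likelihood) genetic correlation matrix is not a
  joint maximum-likelihood estimate; the positive-definite repair is a
  projection, and poorly informed pairs (few linking varieties) contribute
  noisy entries.
- The per-environment fixed-effect model is year (+ optional categorical
  management); continuous management gradients are not modelled.
- P3D holds variance components fixed across markers; for markers with
  very large effects an exact per-marker REML would differ slightly.
- The gap statistic is computed at desk scale with 50 reference draws and
  a capped cluster count (`min(50, n_covariates - 1)`); both are
  configurable.
- Slope recovery degrades gracefully with environment count and
  per-environment record depth; with very sparse coverage the shrinkage of
  predicted additive effects attenuates slopes toward zero.
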