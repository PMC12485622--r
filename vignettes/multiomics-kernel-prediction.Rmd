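---
title: "Multi-omics kernel models for genomic prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics kernel models for genomic prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kernomics)
```

# The model

`kernomics` fits, for one continuous trait at a time,

$$ y = 1\mu + \sum_{k=1}^{K} u_k + e, \qquad
   u_k \sim N(0, \sigma_k^2 K_k), \qquad e \sim N(0, \sigma_e^2 I), $$

a multi-kernel RKHS (reproducing-kernel Hilbert space) regression: each
omics layer, and each modelled interaction between layers, contributes one
random line effect whose covariance is a kernel matrix. With a single
genomic kernel this is GBLUP; with several kernels the phenotypic variance
is partitioned across layers, which is the point of the framework — the
per-term variance components $\sigma_k^2$ say where trait variance comes
from, and their sum $V_P$ gives the model heritability
$h^2 = V_P/(V_P + V_e)$.

The assumptions are those of any kernel mixed model: effects are Gaussian
with the stated covariances and independent across terms, noise is i.i.d.,
and the phenotype is modelled univariately (multi-trait covariance is out
of scope). Phenotype columns are z-scored per trait before fitting;
transcriptomic and metabolomic features are mean-imputed then z-scored
(sample sd, $n-1$ denominator) before entering kernels, while markers stay
on 0/1/2 dosage coding for the VanRaden kernel and are standardized only
when used in a generic linear or Gaussian kernel. "Normalization" of omics
features is deliberately interpreted as per-feature z-scoring — the
standard choice in genomic-selection practice, and the one that makes the
linear kernel a correlation-like similarity.

# Kernels

**Linear.** `linear_kernel()` computes $XX'/p$ on standardized features.
`vanraden_kernel()` computes the genomic relationship matrix
$ZZ'/(2\sum_j p_j(1-p_j))$ with $Z$ the dosage matrix centered by twice
the allele frequency. Both are PSD by construction.

**Gaussian.** `gaussian_kernel()` uses
$K_{ij} = \exp(-d^2_{ij}/\sigma)$ with $\sigma$ the *median of the
off-diagonal* squared Euclidean distances. The diagonal zeros are excluded
from the median: including them would bias the bandwidth downward, and the
natural reading of a median-of-$d^2$ rule is over inter-line distances.
The diagonal is set to exactly 1. Identical rows make the median
degenerate (zero) and are rejected.

**Hybrid CC/PP interaction kernels.** `hybrid_kernels()` multiplies two
base kernels, $P = K_1 K_2$, and symmetrizes the triangles:
$K^{CC} = UT + UT'$, $K^{PP} = LT + LT'$. Two numerical choices here were
genuinely open and are fixed as follows:

- *Diagonal convention.* $UT$ keeps the diagonal, $LT$ excludes it, so
  $UT + LT = P$ exactly and the identity
  $K^{CC} + K^{PP} = P + P'$ holds entrywise — the invariant the test
  suite enforces at $10^{-10}$. Assigning the diagonal to both triangles
  would double-count it; to neither, lose it. $K^{CC}$ therefore carries
  $2\,\mathrm{diag}(P)$, which the mean-diagonal scaling below absorbs.
- *PSD enforcement.* A symmetrized triangle of a kernel product is **not**
  in general PSD (it is when the factors commute with compatible spectra,
  e.g. $K_2$ a polynomial of $K_1$, but not otherwise). Since a Gibbs
  sampler needs valid covariances, every CC/PP kernel passes through
  `psd_repair()` — eigendecompose, clip negative eigenvalues to zero,
  reconstruct — and the clipped spectral mass is reported. Clipping is the
  minimal correction that preserves the dominant structure.

All kernels are scaled to mean diagonal 1 (`scale_kernel()`) before
fitting so that variance components are comparable across kernels of
different construction.

**The registry.** The 24 standard predictors are data, not code: a table
of term strings in a small grammar (`gL`, `tG`, `gLtLCC`, ...), so custom
predictors compose the same way. Hybrid bases are same-kind by
construction — linear x linear for the linear-kernel models, Gaussian x
Gaussian for the Gaussian ones — and each hybrid pair is computed once per
dataset and memoized, so every model sharing a pair sees bitwise-identical
matrices.

# The Gibbs sampler

`rkhs_fit()` samples the joint posterior. Each kernel is eigendecomposed
once ($K_k = \Gamma_k \Lambda_k \Gamma_k'$, eigenpairs below
`min_eigen_keep` = 1e-8 relative dropped) and the effect reparameterized
as $u_k = \Gamma_k \Lambda_k^{1/2} b_k$ with $b_k \sim N(0, \sigma_k^2 I)$
— full conditionals for $b_k$ are then diagonal Gaussians, which makes the
sampler exact, fast for $n$ up to a few hundred, and directly comparable
to closed-form conjugate results.

Sampler cycle: intercept (flat prior) → per-term coefficients →
per-term variances → residual variance → masked phenotypes. Variances have
scaled-inverse-chi-square priors with `prior_df = 5` and scales chosen so
the prior mode allocates `prior_R2 = 0.5` of the observed phenotypic
variance equally across kernel terms and the rest to the residual — weakly
informative, and the de-facto standard in Bayesian genomic-prediction
software. Masked entries (test lines in cross-validation) are sampled each
iteration from their Gaussian predictive conditional; their reported
prediction is the posterior mean of $\mu + \sum_k u_k$.

Two implementation details matter for accuracy and reproducibility:

- *Rao-Blackwellized summaries.* Posterior means of effects and
  predictions accumulate the Gaussian full-conditional means rather than
  the sampled values — the same limit with much smaller Monte-Carlo error,
  which is what lets the fixed-variance sampler reproduce closed-form
  BLUP to high precision in the oracle tests.
- *Seed substreams.* Every (trait, model, partition, chain) cell derives
  its own RNG substream from the master seed via a string hash, so any
  subset of a benchmark reproduces exactly the numbers of the full run.

MCMC defaults are 6000 iterations, 1000 burn-in, thinning 5 (1000 retained
draws per chain); fewer than 50 retained draws is an error.
Cross-validation fits use one chain (cost); full-data variance-component
fits use two chains and report the Gelman-Rubin statistic per variance
parameter, with the conventional R-hat < 1.1 gate. For identical chains
the statistic equals $\sqrt{(m-1)/m}$, i.e. 1 up to the finite-sample
factor.

Degenerate inputs are rejected rather than patched: constant observed
phenotypes, kernels with no positive eigenvalues, non-finite entries,
dimension or ID mismatches, fully-missing feature columns, zero observed
range in NRMSE.

# Evaluation protocol

`make_partitions()` draws 20 independent uniform-random 50/50 train/test
splits (sizes $\lfloor n/2 \rfloor$ / $\lceil n/2 \rceil$ for odd $n$).
Test lines are masked, predicted by data augmentation, and scored with:

- **APC** — Pearson correlation per partition, averaged over partitions
  within trait and then across traits (unweighted). Partitions with a
  constant observed or predicted vector record a missing value with a
  warning and are excluded from the mean, since silently recording zero
  would bias model comparisons.
- **NRMSE** — RMSE divided by the observed test-set *range*. The
  normalizer was an open choice; range normalization is scale-free and
  produces values in the magnitude range typical of this benchmark
  (roughly 0.10-0.19 on standardized traits); mean normalization is
  available via the `normalizer` argument.

Heritability aggregation across traits uses the **mean of per-trait
ratios**, not the ratio of summed components: for traits with
$(V_P, V_e) = (3,1)$ and $(1,1)$ the two rules give 0.625 vs 0.667, and
only the former matches per-trait reporting conventions for this type of
benchmark table.

# The synthetic generator

`simulate_dataset()` builds linked data so every pipeline stage is
testable without external downloads:

- genotypes: independent Binomial(2, $q$) dosages with per-marker
  frequencies uniform on `maf_range` (default 0.05-0.5); monomorphic
  markers are redrawn, then dropped;
- transcripts/metabolites: each feature is
  $\sqrt{g}\,(\text{standardized score of } \sim 50 \text{ markers}) +
  \sqrt{1-g}\,\varepsilon$ with `genetic_prop` $g$ defaulting to 0.5, so
  the layers share genetic signal as real regulatory data do;
- phenotypes: per-term effects drawn in the eigenbasis of the *same
  scaled, repaired kernels the models fit* (exact covariance sampling, no
  Cholesky failures on repaired kernels), plus Gaussian noise, then
  standardized to unit variance with effects and noise rescaled
  identically so the stored decomposition reproduces the phenotype
  exactly.

Default scale mimics the smallest population a desk-scale benchmark of
this kind uses: $n = 210$ lines, 1000 markers, 2000 transcripts, 500
metabolites, three traits, and variance fractions
$(g, t, m, \text{residual}) = (0.3, 0.2, 0.1, 0.4)$, i.e. $h^2 = 0.6$.

**What the generator does *not* emulate** — and hence what passing tests
do and do not show. Lines are unrelated (no pedigree, no LD, no population
structure), so between-line kernel similarities are small and
cross-validated APC on synthetic data is much lower than on real breeding
panels, where relatedness drives prediction. Parameter recovery
(variance-component and heritability estimation) is insensitive to this
and is the generator's core validation target; absolute APC levels are
not. There is also no marker-level epistasis beyond the kernel-defined
interaction terms, no G×E, and no trait correlation.

# Problem sizes and budgets

The test suite and the acceptance script choose sizes where each property
is informative yet quick: oracle comparisons at $n = 50$ with 5000
retained draws; hybrid-kernel algebra on 200 random pairs at $n \le 30$;
variance-fraction recovery on 5 replicates at $n = 300$ with the default
MCMC budget; convergence gating and the model-ladder benchmark on the
default $n = 210$ dataset with 20 partitions. Noiseless-recovery checks
use low-dimensional layers (kernel rank below the training-set size)
because genetic values are only fully identifiable from half the lines
when the kernels' column spans are spanned by the training set.

# Known limitations

- Univariate traits only; no G×E, no proteomic/epigenomic layers.
- The sampler is dense-eigendecomposition based: fine to $n$ of a few
  hundred (the benchmark regime), not for $n$ in the tens of thousands.
- Hybrid kernels depend on the PSD repair: when the clipped spectral mass
  is large, the repaired kernel can be far from the raw symmetrized
  triangle; the clipped mass is logged so users can judge.
- No REML/EM alternative is provided; estimates are posterior means under
  the stated priors.
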