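---
title: "Individual metabolic connectomes from FDG-PET: model, estimation and validation"
author: "metaconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual metabolic connectomes from FDG-PET: model, estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Progressive mild cognitive impairment (pMCI) — MCI that converts to
Alzheimer's disease within three years — is hard to distinguish from stable
MCI (sMCI) at baseline. FDG-PET measures regional glucose metabolism, and
most predictive models reduce each atlas region to its mean uptake. This
package implements an *individual metabolic connectome* instead: within a
single subject's image, every region of the 90-region AAL parcellation is
represented by the full probability distribution of its (globally
normalized) voxel intensities, and every pair of regions is scored by how
similar those two distributions are.

The construction (KLSE, Kullback-Leibler divergence similarity estimation)
has three steps per subject:

1. **Density estimation.** For region $r$ with voxel intensities
   $x_1, \dots, x_n$, the probability density $P_r$ is a Gaussian-kernel
   density estimate. Conceptually the empirical characteristic function
   $\hat\varphi(t) = \frac{1}{n}\sum_j e^{itx_j}$ is damped by a Gaussian
   and inverted; that inversion equals the familiar kernel sum
   $\hat P(x) = \frac{1}{nh}\sum_j \phi\!\big(\frac{x - x_j}{h}\big)$,
   which is what `estimatePdf()` evaluates. The bandwidth $h$ is chosen by
   the solve-the-equation plug-in (`selectBandwidth()`).
2. **Symmetric divergence.** For regions $r, s$ the symmetric
   Kullback-Leibler (Jeffreys) divergence
   $D(P\|Q) = \int P\log\frac{P}{Q} + Q\log\frac{Q}{P}\,dx$
   is computed by trapezoidal quadrature on a shared grid
   (`symmetricKl()`).
3. **Similarity map.** $\mathrm{KLS} = e^{-D} \in (0, 1]$: identical
   distributions score 1 (`klsSimilarity()`).

The resulting $90 \times 90$ symmetric matrix with unit diagonal is the
subject's metabolic network (`buildNetwork()`). Its
$90 \cdot 89/2 = 4005$ lower-triangle entries are the subject's feature
vector (`vectorizeLowerTriangle()`), which feeds a connectome-based
predictive-modeling (CPM) pipeline: 100 (configurable) stratified 50/50
train/test splits; within each training half, 10-fold cross-validated
LASSO selects a sparse edge subset; a linear-kernel SVM, an L1-penalized
logistic regression, or a random forest is trained on the selected edges
and evaluated on the untouched test half (`runPipeline()`). Edges selected
in more than half the iterations form the consensus feature set; summing
their incidence (weighted by selection frequency) over regions and
Z-scoring the 90 sums identifies *hub* regions at $Z > 1$
(`hubsFromResult()`), the regions carrying discriminative connectivity.

## Key assumptions

- Voxel intensities within a region are exchangeable draws from a
  subject-and-region-specific distribution; spatial autocorrelation within
  the region is ignored (it inflates the effective bandwidth slightly but
  does not bias the similarity ordering).
- Images are already realigned, spatially normalized to MNI space,
  smoothed, and resampled to the atlas grid; the package starts at
  global-mean intensity normalization (`normalizeGlobalMean()`), dividing
  by the mean over the brain mask (default: the union of nonzero atlas
  labels; an explicit mask can be supplied, since "global mean brain
  uptake" admits both readings).
- The positive class for sensitivity/specificity is the progressive group
  (pMCI), so sensitivity measures converter detection.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `gridSize` | 4096 | density/quadrature grid points (power of two for the FFT route) |
| bandwidth | solve-the-equation | per region, estimated once per subject and reused across its 89 pairs |
| grid margin | 4 bandwidths | beyond the sample range, so the truncated kernel mass (~3e-5) keeps the unit-integral contract at 1e-3 |
| density floor | 1e-12 | below it a density value counts as unsupported |
| `minVoxels` | 10 | smallest region sample admitted to KDE |
| `trainFraction` | 0.5 | split ratio of the repeated random splits |
| `nIterations` | 100 | random splits (50 in the package's own validation runs, for runtime) |
| `consensusThreshold` | 0.5 | selection frequency above which an edge is consensus |
| SVM cost grid | 0.01–100 | tuned by inner 10-fold cross-validation |
| hub threshold | Z > 1.0 | on Z-scored region incidence weights |

## Numerical choices

**Two KDE routes.** The production route bins the sample onto an
oversampled copy of the grid and convolves with the Gaussian in the
Fourier domain; the oversampling factor is chosen from the binning-error
bound $0.05\,\Delta x^2 / h^3$ so that the route agrees with the exact
direct kernel sum to about `1e-7` (the direct route is kept as the test
oracle; the suite asserts agreement within `1e-6`).

**One shared grid per subject.** The divergence of a pair is defined on a
grid spanning both samples. `buildNetwork()` evaluates all 90 densities
once on a single grid spanning *all* of the subject's samples and reuses
them across the 4005 pairs; outside a region's support its density is
unsupported and contributes nothing, so this matches pair-specific grids
up to quadrature resolution (the suite checks agreement with the
`strategy = "pairwise"` implementation) while being ~40x cheaper.

**Tails and the common-support rule.** A Gaussian-kernel KDE dies off at
the kernel scale beyond its last sample, so where one region's density has
no support the log-ratio against the floored value (or against the raw
kernel tail) reflects the floor constant, not the data — for well-separated
distributions it would dominate the integral. `symmetricKl()` therefore
zeroes the integrand wherever either density is at or below the floor.
With unit-variance Gaussian samples ($n = 10^4$) this estimator tracks the
closed form $(\Delta\mu)^2$ within 5% (0.1 absolute near zero) for
$\Delta\mu$ up to 3. The rule has a known cost: when the two distributions
have very different spreads *and* are separated, part of the true
divergence lives in the wide distribution's tail beyond the narrow
sample's support, where no nonparametric estimator has information; there
the estimate is biased low (roughly 20% at $\Delta\mu = 2$, $\sigma$-ratio
2). Real normalized-uptake distributions overlap heavily, so this regime
is far from the operating point.

**Degenerate inputs.** Zero-spread samples make the bandwidth undefined
(error, unless a floor bandwidth is supplied); the solve-the-equation
fixed point falls back to Silverman's rule with the fallback recorded;
`exp(-D)` underflow is reported as the smallest positive double so
similarities stay in $(0, 1]$; tiny negative quadrature results
($> -10^{-9}$) are clamped to zero; an empty LASSO selection falls back to
the most-regularized penalty retaining one feature, flagged in the result.

**Hosmer-Lemeshow degrees of freedom.** `hosmerLemeshow()` uses
equal-count deciles of risk and $\chi^2$ with `groups - 2` degrees of
freedom, the reference for probabilities fitted on the same data (its use
after the logistic fit here). For externally fixed probabilities the
statistic is closer to $\chi^2(\text{groups})$; the type-I-error
validation therefore fits an intercept-slope logistic model before
testing, the canonical null experiment for this statistic.

## What the synthetic cohort emulates — and what it does not

Real FDG-PET for this question is access-restricted, so validation uses
`generateCohort()`. Its defaults are the package's study conditions:
90 regions x 500 voxels; region baseline means drawn once per cohort from
$N(1.0, 0.15^2)$ (the scale of globally normalized uptake); within-region
voxel sd 0.2; per-subject region-mean jitter sd 0.05; groups of 100 + 100
(a test-scale cohort; 242/178 reproduces the clinical cohort size); 20
affected region pairs concentrated on 5 designated hub regions (labels 1,
11, 48, 67, 89 — precentral L, inferior frontal operculum L, lingual R,
precuneus L, inferior temporal L, the regions most often reported as
conversion-related); effect size $\delta = 0.4$.

Effects are planted as mean shifts because the Jeffreys divergence between
equal-variance normals has the clean closed form
$(\Delta\mu)^2/\sigma^2$, making the planted truth verifiable. In
progressive subjects the two members of each affected pair move
$\delta/2$ apart in opposite directions (hubs up, partners down, so a hub
shared by several pairs is never pulled both ways and every pair's gap
grows by exactly $\delta$). Two further choices make the *edge-level*
truth identifiable, which a naive mean-shift plant is not:

- **Partners are the regions closest to their hub in baseline mean** —
  normally metabolically coupled pairs. Overlapping distributions are
  where the KLS similarity is most sensitive, so each planted pair swings
  from KLS $\approx 1$ to KLS $\approx e^{-(\delta/\sigma)^2} \approx
  0.02$, the largest possible effect at the given $\delta$.
- **Hubs are assigned spaced quantiles of the drawn baseline means** (the
  multiset of means is untouched, only which region gets which value).
  Because hubs all move up and partners down, a pair consisting of one
  hub and *another* hub's partner also separates by $\delta$; if two hubs
  sat at the same metabolic level such cross pairs would be statistically
  indistinguishable from planted ones and consensus selection could not
  prefer the designated pairs. Spacing the hubs keeps every cross pair's
  baseline gap at the hub spacing ($\gtrsim 0.2$), where both groups'
  similarities are already small and the group contrast is an order of
  magnitude weaker than a planted pair's.

A marginal mean shift still perturbs a shifted region's similarity to
every other region by $\delta/2$ in gap terms; those single-shift edges
are genuinely informative and the classifier may use them, but they stay
below the planted pairs in selection frequency, which is what makes
consensus recovery of the designated pairs a fair target.

The generator does **not** emulate scanner physics (point-spread, partial
volume, attenuation), spatial autocorrelation between neighboring voxels,
non-Gaussian uptake distributions, or registration error. Passing the
recovery tests therefore shows that the estimator and pipeline are
*correct and leak-free*, and that the method recovers planted
distributional differences of realistic magnitude — not that the clinical
accuracy figures transfer to real ADNI data, which this package cannot
access.

## Validation summary (what the test suite computes)

- Structural contracts: 4005 features from 90 regions; networks symmetric,
  unit-diagonal, entries in (0, 1].
- Gaussian oracle: KDE-based Jeffreys vs the closed form at
  $\Delta\mu \in \{0, 1, 2, 3\}$, $n = 10^4$, within max(0.1, 5%); KLS
  strictly decreasing in $\Delta\mu$.
- Recovery at the default conditions (100 + 100 subjects, 50 iterations,
  linear SVM): mean test accuracy $\ge$ 80%, consensus-edge Jaccard
  $\ge$ 0.6 against the 20 planted pairs, $\ge$ 4 of 5 planted hubs at
  $Z > 1$.
- Null control: label permutation brings mean accuracy into
  $50\% \pm 5\%$ and hub recovery to chance.
- Metric identities: FPR/FNR complements exact; rank-based AUC equal to
  the brute-force pairwise win fraction; Hosmer-Lemeshow holds its 5%
  nominal size within $\pm 3\%$ over 500 calibrated fits.

The problem sizes above (500 voxels per region, 50 split iterations, the
100 + 100 cohort) are the package's chosen validation scale; the clinical
cohort size and 100 iterations are a configuration preset away.

## Known limitations

- KL between KDEs is only trustworthy on the common support; similarity
  between nearly disjoint distributions saturates near 0 and its exact
  value is floor-dominated (reported as the smallest positive double on
  underflow).
- With < ~10 voxels a region's density (and bandwidth) is unstable —
  such regions are dropped or rejected rather than estimated.
- The consensus rule (> 50% of iterations) and the hub threshold (Z > 1)
  are conventions, exposed as configuration; hub *identity* is stable
  under affine weight rescaling but the hub *count* depends on the
  threshold.
- P-values of the Hosmer-Lemeshow test assume reasonably large expected
  counts per decile; the implementation errors on empty risk groups and
  merges tied-probability groups with a warning.
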