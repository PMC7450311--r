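# metaconn

Individual metabolic brain networks from FDG-PET, and connectome-based
prediction of MCI-to-AD conversion.

## The problem

FDG-PET maps regional glucose metabolism, and the standard way to use it
predictively is one mean uptake value per atlas region. That discards the
shape of each region's intensity distribution and all between-region
structure. `metaconn` implements a single-subject alternative: every region
of the 90-region AAL parcellation is represented by the probability density
of its globally normalized voxel intensities, and every pair of regions by
a similarity between those two densities. The result is an *individual
metabolic connectome* — one 90 × 90 network per subject from one image —
whose edges serve as features for predicting which patients with mild
cognitive impairment will convert to Alzheimer's disease (progressive,
pMCI) and which will remain stable (sMCI), and whose selected edges point
back to the brain regions that carry the discriminative signal.

It is aimed at neuroimaging methods researchers who want a complete,
testable reference implementation of the KLSE + CPM recipe: the estimator,
the leakage-free evaluation pipeline, and a synthetic benchmark with known
ground truth (the clinical data this method is usually applied to is
access-restricted).

## The method

For one subject, with region sample `x_1 … x_n` (voxel intensities after
division by the global-mean brain uptake):

1. **Density.** Each region's density is a Gaussian-kernel KDE,
   `P(x) = (1/nh) Σ_j φ((x − x_j)/h)`, the Fourier inversion of the
   Gaussian-damped empirical characteristic function
   `φ̂(t) = (1/n) Σ_j exp(i t x_j)`. The bandwidth `h` is the
   solve-the-equation plug-in (Sheather–Jones fixed point).
2. **Divergence.** For each region pair, the symmetric Kullback–Leibler
   (Jeffreys) divergence
   `D = ∫ P log(P/Q) + Q log(Q/P) dx`
   by trapezoidal quadrature on a shared grid.
3. **Similarity.** `KLS = exp(−D) ∈ (0, 1]` — the network edge weight.

The 4005 (= 90·89/2) lower-triangle edges per subject feed the
connectome-based predictive modeling (CPM) pipeline: repeated stratified
50/50 train/test splits; 10-fold cross-validated LASSO feature selection
inside each training half; linear-kernel SVM, L1 logistic regression or
random forest on the selected edges; accuracy / sensitivity / specificity
/ ROC-AUC on the untouched test half, plus the Hosmer–Lemeshow calibration
test for the logistic model. Edges selected in more than half the
iterations are the consensus set; summing their incidence per region and
Z-scoring the 90 sums yields **hub regions** (Z > 1), the regions with the
most discriminative connectivity.

## Worked example

A three-region toy: regions 1 and 2 share a metabolic level, region 3 is
far from both.

```r
library(metaconn)
set.seed(7)
regions <- list("1" = rnorm(500, 1.00, 0.2),
                "2" = rnorm(500, 1.05, 0.2),
                "3" = rnorm(500, 1.60, 0.2))
rs  <- new("RoiSampleSet", subjectId = "demo", samples = regions, nRegions = 3L)
net <- buildNetwork(rs)
round(klsMatrix(net), 4)
#>        1      2     3
#> 1 1.0000 0.9574 0e+00
#> 2 0.9574 1.0000 1e-04
#> 3 0.0000 0.0001 1e+00
```

Regions 1–2 (means 0.05 apart, heavily overlapping densities) get
KLS ≈ 0.96; both pairs involving region 3 (≈ 3 within-region sds away) are
effectively dissimilar. `vectorizeLowerTriangle(net)` turns this into the
feature vector `(0.957, 1.5e-05, 9.8e-05)` in the canonical (2,1), (3,1),
(3,2) order.

End to end on a small synthetic cohort with two planted hub regions:

```r
spec <- syntheticCohortSpec(nSmci = 20, nPmci = 20, nRegions = 20,
                            voxelsPerRegion = 300,
                            hubRegions = c(1L, 11L), pairsPerHub = 3L,
                            seed = 42)
coh <- generateCohort(spec)
fvs <- lapply(roiSamples(coh),
              function(s) vectorizeLowerTriangle(buildNetwork(s)))
ds  <- cohortDataset(fvs, cohortLabels(coh))
res <- runPipeline(ds, nIterations = 10, kinds = "svm_linear", baseSeed = 1)
performanceTables(res)$performance
#>            classifier     accuracy  sensitivity  specificity           auc
#> svm_linear svm_linear 100.0 ± 0.00 100.0 ± 0.00 100.0 ± 0.00 1.000 ± 0.000

hubs <- hubsFromResult(res$svm_linear, featurePairs(ds),
                       lookup = aal90Lookup()[1:20, ])
hubRegions(hubs)[, c("label", "name", "weight", "z")]
#>   label               name weight        z
#> 1    11 Frontal_Inf_Oper_L    2.1 1.965255
#> 2    14  Frontal_Inf_Tri_R    2.0 1.817491
#> 3     9  Frontal_Mid_Orb_L    1.9 1.669728
#> 4     1       Precentral_L    1.7 1.374201
```

The planted effect (δ = 0.4 mean separation on 6 hub-incident pairs) is
fully classifiable, 4 of the 5 consensus edges are planted pairs, and both
planted hubs (labels 1 and 11) exceed the Z > 1 threshold — together with
two partner regions, which at this small scale carry nearly as much
incident signal as the hubs.

A command-line wrapper for the same workflow ships in `inst/cli/metaconn`
(`simulate`, `build-network`, `classify`, `hubs`, `run-all` on a YAML
config).

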