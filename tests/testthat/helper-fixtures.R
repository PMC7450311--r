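## Shared fixtures, memoized so expensive cohorts are built once per run.
.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, builder(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

## One default-scale synthetic subject (90 regions x 500 voxels) and its
## metabolic network.
phantomSubject <- function() {
  fixture("phantomSubject", function() {
    coh <- generateCohort(syntheticCohortSpec(nSmci = 1, nPmci = 1,
                                              seed = 301L))
    roiSamples(coh)[[1L]]
  })
}

phantomNetwork <- function() {
  fixture("phantomNetwork", function() buildNetwork(phantomSubject()))
}

## Small multi-subject cohort for fast modeling tests (few regions).
smallCohortFeatures <- function() {
  fixture("smallCohortFeatures", function() {
    spec <- syntheticCohortSpec(nSmci = 15, nPmci = 15, nRegions = 10,
                                voxelsPerRegion = 200,
                                hubRegions = c(1L, 2L), pairsPerHub = 2L,
                                seed = 77L)
    coh <- generateCohort(spec)
    fvs <- lapply(roiSamples(coh),
                  function(s) vectorizeLowerTriangle(buildNetwork(s)))
    list(dataset = cohortDataset(fvs, cohortLabels(coh)),
         truth = cohortTruth(coh), spec = spec)
  })
}

## The full validation cohort at the default study conditions
## (100 + 100 subjects, 90 regions, delta = 0.4, 20 planted pairs on the
## 5 designated hub regions). Built once; shared by the recovery and the
## permutation-null checks.
recoveryCohortFeatures <- function() {
  fixture("recoveryCohortFeatures", function() {
    spec <- syntheticCohortSpec(seed = 424242L)
    coh <- generateCohort(spec)
    fvs <- lapply(roiSamples(coh),
                  function(s) vectorizeLowerTriangle(buildNetwork(s)))
    list(dataset = cohortDataset(fvs, cohortLabels(coh)),
         truth = cohortTruth(coh))
  })
}

## Canonical key for a set of (i, j) pairs, orientation-insensitive.
pairKey <- function(i, j) paste(pmax(i, j), pmin(i, j), sep = "-")

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
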