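#' @import methods
#' @importFrom stats dnorm rnorm runif rbinom sd quantile IQR fft pchisq
#'   predict coef var uniroot
#' @importFrom utils head read.csv write.csv modifyList packageVersion
NULL

## Internal: trapezoidal integral on a uniform grid.
.trapz <- function(x, y) {
  dx <- (x[length(x)] - x[1]) / (length(x) - 1)
  dx * (sum(y) - (y[1] + y[length(y)]) / 2)
}

.isUniformGrid <- function(g, tol = 1e-8) {
  if (length(g) < 2L) return(FALSE)
  d <- diff(g)
  all(d > 0) && (max(d) - min(d)) <= tol * max(d)
}

#' Per-subject region-wise voxel intensity samples
#'
#' Holds, for one subject, the globally normalized voxel-intensity sample of
#' every atlas region: the raw material from which region densities and the
#' metabolic network are estimated. The `samples` slot is a named list; names
#' are the integer atlas labels as strings.
#'
#' @slot subjectId character scalar.
#' @slot samples named list of numeric vectors (one per region).
#' @slot nRegions integer, number of regions present.
#' @export
setClass("RoiSampleSet",
  representation(subjectId = "character", samples = "list",
                 nRegions = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@samples) != object@nRegions)
      msg <- c(msg, "nRegions must equal length(samples)")
    if (is.null(names(object@samples)) ||
        anyNA(suppressWarnings(as.integer(names(object@samples)))))
      msg <- c(msg, "samples must be named by integer region labels")
    else if (any(as.integer(names(object@samples)) <= 0L))
      msg <- c(msg, "region labels must be positive integers")
    for (s in object@samples) {
      if (length(s) == 0L) { msg <- c(msg, "empty region sample"); break }
      if (!all(is.finite(s))) { msg <- c(msg, "non-finite sample values"); break }
    }
    if (length(msg)) msg else TRUE
  })

#' Kernel density estimate of a region's intensity distribution
#'
#' A probability density evaluated on a uniform grid, together with the
#' kernel bandwidth and the sample size it was estimated from. The
#' trapezoidal integral over the grid must be 1 within 1e-3, so the grid has
#' to extend well past the sample range (the constructors use a 4-bandwidth
#' margin).
#'
#' @slot grid numeric, strictly increasing uniform grid.
#' @slot density numeric, nonnegative, same length as `grid`.
#' @slot bandwidth positive numeric scalar.
#' @slot nSamples integer.
#' @export
setClass("DensityEstimate",
  representation(grid = "numeric", density = "numeric",
                 bandwidth = "numeric", nSamples = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@grid) != length(object@density))
      msg <- c(msg, "grid and density lengths differ")
    if (!.isUniformGrid(object@grid))
      msg <- c(msg, "grid must be strictly increasing and uniform")
    if (any(object@density < 0))
      msg <- c(msg, "density must be nonnegative")
    if (length(object@bandwidth) != 1L || !is.finite(object@bandwidth) ||
        object@bandwidth <= 0)
      msg <- c(msg, "bandwidth must be a positive scalar")
    if (length(msg) == 0L) {
      it <- .trapz(object@grid, object@density)
      if (abs(it - 1) > 1e-3)
        msg <- c(msg, sprintf("density integrates to %.6f, not 1 (+/- 1e-3)", it))
    }
    if (length(msg)) msg else TRUE
  })

#' Individual metabolic network (KLS similarity matrix)
#'
#' The single-subject metabolic connectome: a symmetric region-by-region
#' matrix of Kullback-Leibler-based similarities KLS = exp(-D), with unit
#' diagonal and entries in (0, 1]. Under the 90-region AAL parcellation this
#' is the 90 x 90 metabolic correlation matrix.
#'
#' @slot matrix numeric R x R matrix.
#' @slot regionLabels integer vector of length R (atlas labels, row order).
#' @slot subjectId character scalar.
#' @export
setClass("MetabolicNetwork",
  representation(matrix = "matrix", regionLabels = "integer",
                 subjectId = "character"),
  validity = function(object) {
    m <- object@matrix
    msg <- character()
    if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
    if (nrow(m) != length(object@regionLabels))
      msg <- c(msg, "regionLabels length must match matrix dimension")
    if (!identical(unname(m), unname(t(m))))
      msg <- c(msg, "matrix must be exactly symmetric")
    if (any(diag(m) != 1)) msg <- c(msg, "diagonal must be 1")
    if (any(!is.finite(m)) || any(m <= 0) || any(m > 1))
      msg <- c(msg, "entries must lie in (0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Feature vector extracted from a network or from ROI uptakes
#'
#' For the connectome kind, values are the lower-triangle entries of the
#' similarity matrix in the canonical order (rows i = 2..R, within each row
#' j = 1..i-1), giving R(R-1)/2 features — 4005 for 90 regions. For the
#' roi_uptake kind, values are per-region mean uptakes and `index` carries
#' the region label in column `i` (with `j` = NA).
#'
#' @slot values numeric feature values.
#' @slot index data.frame with integer columns `i`, `j` (region labels).
#' @slot kind "connectome" or "roi_uptake".
#' @export
setClass("FeatureVector",
  representation(values = "numeric", index = "data.frame", kind = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("connectome", "roi_uptake"))
      msg <- c(msg, "kind must be 'connectome' or 'roi_uptake'")
    if (nrow(object@index) != length(object@values))
      msg <- c(msg, "index rows must match values length")
    if (object@kind == "connectome") {
      if (!all(object@index$i > object@index$j))
        msg <- c(msg, "connectome index requires i > j")
      if (anyDuplicated(object@index[c("i", "j")]))
        msg <- c(msg, "duplicate feature pairs")
    }
    if (length(msg)) msg else TRUE
  })

#' Cohort design matrix for predictive modeling
#'
#' @slot X numeric subjects x features matrix, no missing values.
#' @slot y integer 0/1 labels (1 = progressive/positive class).
#' @slot subjectIds character.
#' @slot featureIndex data.frame mapping columns of X to region pairs
#'   (or regions, for uptake features).
#' @slot kind feature kind ("connectome" or "roi_uptake").
#' @export
setClass("CohortDataset",
  representation(X = "matrix", y = "integer", subjectIds = "character",
                 featureIndex = "data.frame", kind = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@X) != length(object@y))
      msg <- c(msg, "X rows must match y length")
    if (length(object@subjectIds) != length(object@y))
      msg <- c(msg, "subjectIds must match y length")
    if (ncol(object@X) != nrow(object@featureIndex))
      msg <- c(msg, "featureIndex rows must match X columns")
    if (any(!is.finite(object@X))) msg <- c(msg, "X contains non-finite values")
    if (!all(object@y %in% c(0L, 1L))) msg <- c(msg, "y must be 0/1")
    if (length(unique(object@y)) < 2L) msg <- c(msg, "both classes must be present")
    if (length(msg)) msg else TRUE
  })

#' Result of the repeated-split predictive modeling pipeline
#'
#' One object per classifier kind. `perIteration` holds, for every random
#' split, the selected feature indices, the LASSO penalty, the test-set
#' confusion metrics and AUC. `summary` holds the mean and standard
#' deviation of each metric across iterations; `selectionFrequency` the
#' fraction of iterations in which each feature was selected, and
#' `consensusFeatures` the features above the consensus threshold.
#'
#' @slot classifier classifier kind.
#' @slot perIteration list of per-iteration records.
#' @slot summary data.frame (metric, mean, sd).
#' @slot selectionFrequency numeric, one entry per feature.
#' @slot consensusFeatures integer feature (column) indices.
#' @slot consensusThreshold numeric.
#' @export
setClass("CohortRunResult",
  representation(classifier = "character", perIteration = "list",
                 summary = "data.frame", selectionFrequency = "numeric",
                 consensusFeatures = "integer", consensusThreshold = "numeric"),
  validity = function(object) {
    if (length(object@perIteration) < 1L) "perIteration must be nonempty" else TRUE
  })

#' Hub regions carrying discriminative connectivity
#'
#' Region weights are incidence sums over selected connectome features;
#' Z-scored weights above the threshold define hubs.
#'
#' @slot regionWeights numeric, one per region.
#' @slot zScores numeric, Z-scored weights (mean 0, sd 1).
#' @slot hubs data.frame (label, name, x_mni, y_mni, z_mni, weight, z),
#'   sorted by decreasing Z.
#' @slot threshold numeric Z threshold (default +1).
#' @export
setClass("HubReport",
  representation(regionWeights = "numeric", zScores = "numeric",
                 hubs = "data.frame", threshold = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@regionWeights) != length(object@zScores))
      msg <- c(msg, "weights and zScores lengths differ")
    z <- object@zScores
    if (abs(mean(z)) > 1e-9 || abs(sd(z) - 1) > 1e-9)
      msg <- c(msg, "zScores must have mean 0 and sd 1")
    if (length(msg)) msg else TRUE
  })

#' Specification of a synthetic cohort with planted group effects
#'
#' Defines the generative model for a two-group (stable vs progressive)
#' cohort of per-region voxel-intensity samples. Region baseline means are
#' drawn once per cohort from N(baselineMeanMu, baselineMeanSd^2); every
#' voxel sample is normal with the subject's region mean and withinSd.
#' In progressive subjects, each affected (hub, partner) pair is pushed
#' apart: the partner's mean moves effectSize away from the hub's baseline
#' mean. Subject-level noise perturbs every region mean per subject.
#'
#' @slot nSmci,nPmci group sizes.
#' @slot nRegions number of atlas regions (default 90).
#' @slot voxelsPerRegion voxels sampled per region (default 500).
#' @slot baselineMeanMu,baselineMeanSd cohort-level mean model (1.0, 0.15).
#' @slot withinSd within-region voxel sd (0.2).
#' @slot hubRegions integer labels of designated hub regions.
#' @slot pairsPerHub partners per hub (default 4, giving 20 affected pairs).
#' @slot affectedPairs optional 2-column matrix of planted pairs; if empty,
#'   pairs are drawn from hubRegions at generation time.
#' @slot effectSize mean separation added to affected pairs in the
#'   progressive group (default 0.4).
#' @slot subjectNoiseSd per-subject, per-region mean jitter (0.05).
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticCohortSpec",
  representation(nSmci = "integer", nPmci = "integer", nRegions = "integer",
                 voxelsPerRegion = "integer",
                 baselineMeanMu = "numeric", baselineMeanSd = "numeric",
                 withinSd = "numeric", hubRegions = "integer",
                 pairsPerHub = "integer", affectedPairs = "matrix",
                 effectSize = "numeric", subjectNoiseSd = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nSmci < 1L || object@nPmci < 1L)
      msg <- c(msg, "both groups need at least one subject")
    if (object@nRegions < 2L) msg <- c(msg, "need at least 2 regions")
    if (object@voxelsPerRegion < 1L) msg <- c(msg, "voxelsPerRegion must be >= 1")
    if (object@effectSize < 0) msg <- c(msg, "effectSize must be >= 0")
    if (object@withinSd <= 0 || object@baselineMeanSd <= 0)
      msg <- c(msg, "sds must be > 0")
    if (object@subjectNoiseSd < 0) msg <- c(msg, "subjectNoiseSd must be >= 0")
    if (any(object@hubRegions < 1L) || any(object@hubRegions > object@nRegions) ||
        anyDuplicated(object@hubRegions))
      msg <- c(msg, "hubRegions must be distinct valid region labels")
    if (nrow(object@affectedPairs)) {
      ap <- object@affectedPairs
      if (ncol(ap) != 2L) msg <- c(msg, "affectedPairs must have 2 columns")
      else {
        if (any(ap < 1L) || any(ap > object@nRegions))
          msg <- c(msg, "affectedPairs reference invalid regions")
        if (any(ap[, 1L] == ap[, 2L]))
          msg <- c(msg, "affectedPairs must involve distinct regions")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' A generated synthetic cohort
#'
#' @slot subjects list of [RoiSampleSet-class] objects.
#' @slot labels integer 0 (stable) / 1 (progressive) per subject.
#' @slot truth list with `affectedPairs` (2-column matrix, i > j) and
#'   `hubRegions`, recorded for recovery scoring.
#' @slot spec the [SyntheticCohortSpec-class] the cohort was drawn from.
#' @export
setClass("SyntheticCohort",
  representation(subjects = "list", labels = "integer", truth = "list",
                 spec = "SyntheticCohortSpec"),
  validity = function(object) {
    msg <- character()
    if (length(object@subjects) != length(object@labels))
      msg <- c(msg, "subjects and labels lengths differ")
    if (!all(object@labels %in% c(0L, 1L))) msg <- c(msg, "labels must be 0/1")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "RoiSampleSet", function(object) {
  ns <- lengths(object@samples)
  cat("RoiSampleSet for subject", sQuote(object@subjectId), "\n",
      " ", object@nRegions, "regions;",
      "voxels per region:", paste(range(ns), collapse = "-"), "\n")
})

setMethod("show", "DensityEstimate", function(object) {
  cat("DensityEstimate on", length(object@grid), "grid points",
      sprintf("[%.4g, %.4g]", object@grid[1], object@grid[length(object@grid)]),
      "\n  bandwidth", format(object@bandwidth, digits = 4),
      "from", object@nSamples, "samples\n")
})

setMethod("show", "MetabolicNetwork", function(object) {
  off <- object@matrix[upper.tri(object@matrix)]
  cat("MetabolicNetwork (", nrow(object@matrix), "x", ncol(object@matrix),
      ") for subject ", sQuote(object@subjectId), "\n",
      "  off-diagonal KLS range: ",
      sprintf("[%.4g, %.4g]", min(off), max(off)), "\n", sep = "")
})

setMethod("show", "FeatureVector", function(object) {
  cat("FeatureVector (", object@kind, "), ", length(object@values),
      " features\n", sep = "")
})

setMethod("show", "CohortDataset", function(object) {
  cat("CohortDataset:", nrow(object@X), "subjects x", ncol(object@X),
      sprintf("%s features (%d positive / %d negative)\n", object@kind,
              sum(object@y == 1L), sum(object@y == 0L)))
})

setMethod("show", "CohortRunResult", function(object) {
  cat("CohortRunResult:", object@classifier, "over",
      length(object@perIteration), "iterations\n")
  print(object@summary, row.names = FALSE, digits = 4)
  cat(length(object@consensusFeatures), "consensus features (frequency >",
      object@consensusThreshold, ")\n")
})

setMethod("show", "HubReport", function(object) {
  cat("HubReport:", nrow(object@hubs), "hub regions at Z >",
      object@threshold, "\n")
  if (nrow(object@hubs)) print(object@hubs, row.names = FALSE, digits = 4)
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", sum(object@labels == 0L), "stable +",
      sum(object@labels == 1L), "progressive subjects,",
      object@spec@nRegions, "regions\n")
})
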