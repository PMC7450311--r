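#' Accessors for metaconn classes
#'
#' Getter generics for the package's S4 containers: `subjectId()`,
#' `roiSamples()`, `klsMatrix()`, `regionLabels()`, `featureValues()`,
#' `featurePairs()`, `cohortLabels()`, `hubRegions()`, `zScores()`.
#'
#' @param object a metaconn S4 object.
#' @return the corresponding slot value.
#' @name accessors
#' @examples
#' spec <- syntheticCohortSpec(nSmci = 2, nPmci = 2, nRegions = 4,
#'                             voxelsPerRegion = 40,
#'                             affectedPairs = cbind(1, 2), seed = 1)
#' coh <- generateCohort(spec)
#' subjectId(roiSamples(coh)[[1]])
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setMethod("subjectId", "RoiSampleSet", function(object) object@subjectId)
#' @rdname accessors
#' @export
setMethod("subjectId", "MetabolicNetwork", function(object) object@subjectId)

#' @rdname accessors
#' @export
setGeneric("roiSamples", function(object) standardGeneric("roiSamples"))
#' @rdname accessors
#' @export
setMethod("roiSamples", "RoiSampleSet", function(object) object@samples)
#' @rdname accessors
#' @export
setMethod("roiSamples", "SyntheticCohort", function(object) object@subjects)

#' @rdname accessors
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setMethod("regionLabels", "RoiSampleSet",
          function(object) as.integer(names(object@samples)))
#' @rdname accessors
#' @export
setMethod("regionLabels", "MetabolicNetwork", function(object) object@regionLabels)

#' @rdname accessors
#' @export
setGeneric("klsMatrix", function(object) standardGeneric("klsMatrix"))
#' @rdname accessors
#' @export
setMethod("klsMatrix", "MetabolicNetwork", function(object) object@matrix)

#' @rdname accessors
#' @export
setGeneric("densityGrid", function(object) standardGeneric("densityGrid"))
#' @rdname accessors
#' @export
setMethod("densityGrid", "DensityEstimate", function(object) object@grid)

#' @rdname accessors
#' @export
setGeneric("densityValues", function(object) standardGeneric("densityValues"))
#' @rdname accessors
#' @export
setMethod("densityValues", "DensityEstimate", function(object) object@density)

#' @rdname accessors
#' @export
setGeneric("bandwidth", function(object) standardGeneric("bandwidth"))
#' @rdname accessors
#' @export
setMethod("bandwidth", "DensityEstimate", function(object) object@bandwidth)

#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureVector", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("featurePairs", function(object) standardGeneric("featurePairs"))
#' @rdname accessors
#' @export
setMethod("featurePairs", "FeatureVector", function(object) object@index)
#' @rdname accessors
#' @export
setMethod("featurePairs", "CohortDataset", function(object) object@featureIndex)

#' @rdname accessors
#' @export
setGeneric("cohortLabels", function(object) standardGeneric("cohortLabels"))
#' @rdname accessors
#' @export
setMethod("cohortLabels", "SyntheticCohort", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("cohortLabels", "CohortDataset", function(object) object@y)

#' @rdname accessors
#' @export
setGeneric("cohortTruth", function(object) standardGeneric("cohortTruth"))
#' @rdname accessors
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(object) object@truth)

#' @rdname accessors
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))
#' @rdname accessors
#' @export
setMethod("designMatrix", "CohortDataset", function(object) object@X)

#' @rdname accessors
#' @export
setGeneric("iterationResults", function(object) standardGeneric("iterationResults"))
#' @rdname accessors
#' @export
setMethod("iterationResults", "CohortRunResult", function(object) object@perIteration)

#' @rdname accessors
#' @export
setGeneric("resultSummary", function(object) standardGeneric("resultSummary"))
#' @rdname accessors
#' @export
setMethod("resultSummary", "CohortRunResult", function(object) object@summary)

#' @rdname accessors
#' @export
setGeneric("consensusFeatures", function(object) standardGeneric("consensusFeatures"))
#' @rdname accessors
#' @export
setMethod("consensusFeatures", "CohortRunResult",
          function(object) object@consensusFeatures)

#' @rdname accessors
#' @export
setGeneric("selectionFrequency", function(object) standardGeneric("selectionFrequency"))
#' @rdname accessors
#' @export
setMethod("selectionFrequency", "CohortRunResult",
          function(object) object@selectionFrequency)

#' @rdname accessors
#' @export
setGeneric("hubRegions", function(object) standardGeneric("hubRegions"))
#' @rdname accessors
#' @export
setMethod("hubRegions", "HubReport", function(object) object@hubs)

#' @rdname accessors
#' @export
setGeneric("zScores", function(object) standardGeneric("zScores"))
#' @rdname accessors
#' @export
setMethod("zScores", "HubReport", function(object) object@zScores)

#' @rdname accessors
#' @export
setGeneric("regionWeights", function(object) standardGeneric("regionWeights"))
#' @rdname accessors
#' @export
setMethod("regionWeights", "HubReport", function(object) object@regionWeights)
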