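#' Region weights from selected connectome features
#'
#' Builds the region-by-region incidence matrix containing only the
#' selected connectome features — entry `w` (default 1, or the supplied
#' per-pair weight such as a selection frequency) at both (i, j) and
#' (j, i) — and column-sums it. A region's weight is therefore the number
#' (or weighted sum) of selected discriminative edges incident on it; by
#' the handshake lemma the weights sum to twice the total pair weight.
#'
#' @param selectedPairs 2-column matrix or data.frame of region labels
#'   (i, j), i != j.
#' @param weightsPerPair optional numeric weights, one per pair (default 1).
#' @param nRegions number of regions (default 90); labels must lie in
#'   1..nRegions.
#' @return numeric weight vector of length `nRegions`.
#' @export
#' @examples
#' regionWeightsFromSelection(rbind(c(2, 1), c(3, 1)), nRegions = 5)
regionWeightsFromSelection <- function(selectedPairs, weightsPerPair = NULL,
                                       nRegions = 90L) {
  sp <- as.matrix(selectedPairs)
  if (length(sp) == 0L) return(numeric(nRegions))
  if (ncol(sp) != 2L) stop("selectedPairs must have two columns")
  sp <- matrix(as.integer(sp), ncol = 2L)
  if (any(sp[, 1L] == sp[, 2L])) stop("self-pairs are not allowed")
  if (any(sp < 1L) || any(sp > nRegions))
    stop("pair labels must lie in 1..", nRegions)
  if (is.null(weightsPerPair)) weightsPerPair <- rep(1, nrow(sp))
  if (length(weightsPerPair) != nrow(sp))
    stop("weightsPerPair must match the number of pairs")
  m <- matrix(0, nRegions, nRegions)
  ## accumulate through linear indices so duplicated pairs add up
  li <- c((sp[, 2L] - 1L) * nRegions + sp[, 1L],
          (sp[, 1L] - 1L) * nRegions + sp[, 2L])
  acc <- rowsum(rep(weightsPerPair, 2L), group = li)
  m[as.integer(rownames(acc))] <- acc[, 1L]
  colSums(m)
}

#' Identify hub regions by Z-scored weight
#'
#' Z-scores the region weights ((w - mean) / sd over regions) and reports
#' as hubs every region whose Z exceeds the threshold (default +1.0),
#' sorted by decreasing Z and annotated from the lookup table. Hub
#' membership is invariant to affine rescaling of the raw weights.
#'
#' @param weights numeric region weight vector (one per region, in lookup
#'   label order); must have positive spread.
#' @param lookup region lookup (default [aal90Lookup()]); must have one row
#'   per weight.
#' @param threshold Z threshold (default 1.0).
#' @return a [HubReport-class].
#' @export
identifyHubs <- function(weights, lookup = aal90Lookup(), threshold = 1.0) {
  weights <- as.numeric(weights)
  if (nrow(lookup) != length(weights))
    stop("lookup must have one row per region weight")
  s <- sd(weights)
  if (!is.finite(s) || s == 0)
    stop("region weights have zero spread: Z-scores undefined ",
         "(no discriminative structure to rank)")
  z <- (weights - mean(weights)) / s
  sel <- which(z > threshold)
  ord <- sel[order(z[sel], decreasing = TRUE)]
  hubs <- data.frame(label = lookup$label[ord], name = lookup$name[ord],
                     x_mni = lookup$x_mni[ord], y_mni = lookup$y_mni[ord],
                     z_mni = lookup$z_mni[ord],
                     weight = weights[ord], z = z[ord],
                     stringsAsFactors = FALSE)
  new("HubReport", regionWeights = weights, zScores = z, hubs = hubs,
      threshold = threshold)
}

#' Hub report from a pipeline result
#'
#' Convenience composition: weights each feature pair by its selection
#' frequency across iterations (set `binary = TRUE` to count consensus
#' membership instead), column-sums the selected-feature incidence matrix
#' and thresholds the Z-scored weights.
#'
#' @param result a [CohortRunResult-class].
#' @param featureIndex data.frame (i, j) mapping feature columns to region
#'   pairs.
#' @param lookup region lookup (default [aal90Lookup()]).
#' @param threshold Z threshold (default 1.0).
#' @param binary use consensus membership (0/1) instead of selection
#'   frequency as pair weight.
#' @return a [HubReport-class].
#' @export
hubsFromResult <- function(result, featureIndex, lookup = aal90Lookup(),
                           threshold = 1.0, binary = FALSE) {
  stopifnot(is(result, "CohortRunResult"))
  if (binary) {
    keep <- result@consensusFeatures
    w <- rep(1, length(keep))
  } else {
    keep <- which(result@selectionFrequency > 0)
    w <- result@selectionFrequency[keep]
  }
  if (!length(keep)) stop("no features were ever selected")
  pairs <- cbind(featureIndex$i[keep], featureIndex$j[keep])
  weights <- regionWeightsFromSelection(pairs, w, nRegions = nrow(lookup))
  identifyHubs(weights, lookup = lookup, threshold = threshold)
}

#' Write a hub report
#'
#' Emits the hub table as delimited text (label, name, MNI coordinates,
#' weight, Z) and, optionally, the full report as JSON.
#'
#' @param report a [HubReport-class].
#' @param path output `.csv` path.
#' @param jsonPath optional `.json` path for the full report.
#' @export
writeHubReport <- function(report, path, jsonPath = NULL) {
  write.csv(report@hubs, path, row.names = FALSE)
  if (!is.null(jsonPath)) {
    jsonlite::write_json(
      list(threshold = report@threshold,
           region_weights = report@regionWeights,
           z_scores = report@zScores, hubs = report@hubs),
      jsonPath, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(path)
}
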