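#' Canonical lower-triangle feature order
#'
#' The fixed feature ordering used everywhere in the package: rows
#' i = 2..R, within each row j = 1..i-1 (row-major lower triangle). For 90
#' regions this yields 4005 = 90*89/2 (i, j) pairs.
#'
#' @param labels integer region labels in matrix row order.
#' @return data.frame with integer columns `i`, `j` (region labels, i > j).
#' @export
#' @examples
#' lowerTriangleIndex(1:3)  # (2,1), (3,1), (3,2)
lowerTriangleIndex <- function(labels) {
  labels <- as.integer(labels)
  R <- length(labels)
  ii <- rep(2:R, times = 1:(R - 1))
  jj <- unlist(lapply(2:R, function(i) 1:(i - 1)))
  data.frame(i = labels[ii], j = labels[jj])
}

#' Vectorize a metabolic network's lower triangle
#'
#' Extracts the R(R-1)/2 off-diagonal similarities in the canonical order
#' of [lowerTriangleIndex()] — each participant's 4005 connectome features
#' under the 90-region atlas.
#'
#' @param network a [MetabolicNetwork-class] (or a symmetric numeric
#'   matrix).
#' @return a [FeatureVector-class] of kind "connectome".
#' @export
vectorizeLowerTriangle <- function(network) {
  if (is(network, "MetabolicNetwork")) {
    m <- network@matrix
    labels <- network@regionLabels
  } else {
    m <- as.matrix(network)
    if (!identical(unname(m), unname(t(m)))) stop("matrix must be symmetric")
    labels <- seq_len(nrow(m))
  }
  idx <- lowerTriangleIndex(labels)
  pos <- cbind(match(idx$i, labels), match(idx$j, labels))
  new("FeatureVector", values = m[pos], index = idx, kind = "connectome")
}

#' Rebuild a similarity matrix from a connectome feature vector
#'
#' Exact inverse of [vectorizeLowerTriangle()] (diagonal restored to 1).
#'
#' @param fv a connectome [FeatureVector-class].
#' @param labels region labels (row order); defaults to those in `fv`.
#' @return symmetric numeric matrix.
#' @export
matrixFromFeatures <- function(fv, labels = NULL) {
  stopifnot(is(fv, "FeatureVector"), fv@kind == "connectome")
  if (is.null(labels)) labels <- sort(unique(c(fv@index$i, fv@index$j)))
  R <- length(labels)
  m <- diag(1, R)
  pos <- cbind(match(fv@index$i, labels), match(fv@index$j, labels))
  m[pos] <- fv@values
  m[pos[, c(2, 1)]] <- fv@values
  dimnames(m) <- list(labels, labels)
  m
}

#' Per-region mean uptake features
#'
#' The conventional baseline feature set: one mean metabolic uptake per
#' region (length 90 under AAL-90).
#'
#' @param samples a [RoiSampleSet-class]; all expected regions must be
#'   present.
#' @param expectedLabels labels that must all be present (default: those in
#'   `samples`).
#' @return a [FeatureVector-class] of kind "roi_uptake".
#' @export
roiMeanUptake <- function(samples, expectedLabels = NULL) {
  stopifnot(is(samples, "RoiSampleSet"))
  labels <- as.integer(names(samples@samples))
  if (!is.null(expectedLabels)) {
    missing <- setdiff(as.integer(expectedLabels), labels)
    if (length(missing))
      stop("missing regions: ", paste(missing, collapse = ", "))
    keep <- match(as.integer(expectedLabels), labels)
    labels <- labels[keep]
    vals <- vapply(samples@samples[keep], mean, numeric(1))
  } else {
    vals <- vapply(samples@samples, mean, numeric(1))
  }
  new("FeatureVector", values = unname(vals),
      index = data.frame(i = labels, j = NA_integer_), kind = "roi_uptake")
}

#' Assemble a cohort dataset from per-subject feature vectors
#'
#' @param featureList list of [FeatureVector-class] objects sharing one
#'   feature index.
#' @param labels integer 0/1 outcome per subject (1 = progressive).
#' @param subjectIds character ids (default "S1", "S2", ...).
#' @return a [CohortDataset-class].
#' @export
cohortDataset <- function(featureList, labels, subjectIds = NULL) {
  stopifnot(length(featureList) == length(labels))
  if (is.null(subjectIds)) subjectIds <- paste0("S", seq_along(featureList))
  ref <- featureList[[1]]
  for (fv in featureList)
    if (!identical(fv@index, ref@index))
      stop("feature vectors have inconsistent feature indices")
  X <- do.call(rbind, lapply(featureList, function(f) f@values))
  rownames(X) <- subjectIds
  new("CohortDataset", X = X, y = as.integer(labels),
      subjectIds = subjectIds, featureIndex = ref@index, kind = ref@kind)
}

#' Write / read a cohort feature table
#'
#' One row per subject: `subject_id`, `group` (sMCI/pMCI), then feature
#' columns named `R{i}_R{j}` (connectome) or `ROI{r}` (uptake).
#'
#' @param dataset a [CohortDataset-class].
#' @param path output file.
#' @export
writeFeatureTable <- function(dataset, path) {
  idx <- dataset@featureIndex
  nm <- if (dataset@kind == "connectome")
    paste0("R", idx$i, "_R", idx$j) else paste0("ROI", idx$i)
  df <- as.data.frame(dataset@X)
  names(df) <- nm
  out <- cbind(data.frame(subject_id = dataset@subjectIds,
                          group = ifelse(dataset@y == 1L, "pMCI", "sMCI")),
               df)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  stopifnot(all(c("subject_id", "group") %in% names(df)))
  featNames <- setdiff(names(df), c("subject_id", "group"))
  conn <- grepl("^R\\d+_R\\d+$", featNames)
  if (all(conn)) {
    ij <- do.call(rbind, lapply(strsplit(sub("^R", "", featNames), "_R"),
                                as.integer))
    idx <- data.frame(i = ij[, 1], j = ij[, 2])
    kind <- "connectome"
  } else {
    idx <- data.frame(i = as.integer(sub("^ROI", "", featNames)),
                      j = NA_integer_)
    kind <- "roi_uptake"
  }
  X <- as.matrix(df[featNames])
  dimnames(X) <- list(df$subject_id, NULL)
  new("CohortDataset", X = X, y = as.integer(df$group == "pMCI"),
      subjectIds = df$subject_id, featureIndex = idx, kind = kind)
}
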