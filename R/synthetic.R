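#' Specify a synthetic two-group cohort
#'
#' Constructor with the study-scale defaults used throughout the package's
#' validation: 90 regions of 500 voxels each; region baseline means drawn
#' once per cohort from N(1.0, 0.15^2) (globally normalized uptake scale);
#' within-region voxel sd 0.2; 5 designated hub regions each paired with 4
#' distinct partner regions (20 affected pairs); effect size 0.4 pushing
#' affected pairs apart in the progressive group; per-subject, per-region
#' mean jitter of sd 0.05. The default hubs are the five conversion-
#' associated regions of the built-in lookup (labels 1, 11, 48, 67, 89).
#'
#' @param nSmci,nPmci group sizes (default 100 each, a test-scale cohort;
#'   use 242/178 for the clinical-study-sized preset).
#' @param nRegions,voxelsPerRegion parcellation size (90, 500).
#' @param baselineMeanMu,baselineMeanSd,withinSd distribution parameters.
#' @param hubRegions integer hub labels (default c(1, 11, 48, 67, 89),
#'   truncated/remapped if `nRegions` < 90).
#' @param pairsPerHub partners per hub (default 4).
#' @param affectedPairs optional explicit 2-column pair matrix; overrides
#'   hub-based pair construction.
#' @param effectSize planted mean separation (default 0.4).
#' @param subjectNoiseSd per-subject region-mean jitter (default 0.05).
#' @param seed RNG seed.
#' @return a [SyntheticCohortSpec-class].
#' @export
syntheticCohortSpec <- function(nSmci = 100L, nPmci = 100L, nRegions = 90L,
                                voxelsPerRegion = 500L,
                                baselineMeanMu = 1.0, baselineMeanSd = 0.15,
                                withinSd = 0.2, hubRegions = NULL,
                                pairsPerHub = 4L, affectedPairs = NULL,
                                effectSize = 0.4, subjectNoiseSd = 0.05,
                                seed = 1L) {
  if (is.null(hubRegions)) {
    hubRegions <- c(1L, 11L, 48L, 67L, 89L)
    hubRegions <- hubRegions[hubRegions <= nRegions]
    if (!length(hubRegions)) hubRegions <- 1L
  }
  if (is.null(affectedPairs))
    affectedPairs <- matrix(integer(0), ncol = 2L)
  new("SyntheticCohortSpec",
      nSmci = as.integer(nSmci), nPmci = as.integer(nPmci),
      nRegions = as.integer(nRegions),
      voxelsPerRegion = as.integer(voxelsPerRegion),
      baselineMeanMu = baselineMeanMu, baselineMeanSd = baselineMeanSd,
      withinSd = withinSd, hubRegions = as.integer(hubRegions),
      pairsPerHub = as.integer(pairsPerHub),
      affectedPairs = matrix(as.integer(affectedPairs), ncol = 2L),
      effectSize = effectSize, subjectNoiseSd = subjectNoiseSd,
      seed = as.integer(seed))
}

#' Generate a synthetic cohort with planted group differences
#'
#' Draws region baseline means once, plants the affected pairs, then
#' simulates every subject's per-region voxel samples. Each hub's partners
#' are the regions closest to it in baseline mean — normally
#' metabolically coupled pairs, whose intensity distributions overlap and
#' whose similarity is therefore maximally sensitive to a separation. In
#' progressive subjects the members of each affected pair move
#' `effectSize/2` apart in opposite directions (hubs up, partners down, so
#' several pairs sharing a hub never pull it in conflicting directions and
#' every pair's mean gap grows by `effectSize`). Voxel draws are normal
#' with the subject's per-region mean (baseline + planted shift + subject
#' jitter) and the common within-region sd. Subject order is shuffled;
#' everything is a deterministic function of the spec's seed.
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @return a [SyntheticCohort-class]; `cohortTruth()` records the planted
#'   pairs (as i > j) and hub regions.
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "SyntheticCohortSpec"))
  validObject(spec)
  set.seed(spec@seed)
  R <- spec@nRegions
  V <- spec@voxelsPerRegion
  baseline <- rnorm(R, spec@baselineMeanMu, spec@baselineMeanSd)
  ## Planted shifts: each affected pair's members move effectSize/2 apart,
  ## hub away from its partners and partners the opposite way. A hub's
  ## travel direction is fixed once (toward the side of the cohort mean it
  ## already sits on) and its partners are drawn from regions on the other
  ## side of it, so every pair's mean gap grows by exactly effectSize and
  ## shifts sharing a hub never conflict.
  half <- spec@effectSize / 2
  shift <- numeric(R)
  if (nrow(spec@affectedPairs)) {
    pairs <- spec@affectedPairs
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1L]
      b <- pairs[k, 2L]
      if (shift[a] == 0 && shift[b] == 0) {
        d <- sign(baseline[a] - baseline[b])
        if (d == 0) d <- 1
        shift[a] <- d * half
        shift[b] <- -d * half
      } else if (shift[b] == 0) {
        shift[b] <- -half * sign2(baseline[a] + shift[a] - baseline[b])
      } else if (shift[a] == 0) {
        shift[a] <- half * sign2(baseline[a] - baseline[b] - shift[b])
      }  # both already shifted: keep existing directions
    }
  } else {
    hubs <- spec@hubRegions
    pool <- setdiff(seq_len(R), hubs)
    need <- length(hubs) * spec@pairsPerHub
    if (need > length(pool))
      stop("not enough non-hub regions for ", need, " partners")
    ## Hubs are assigned spaced quantiles of the drawn baseline means (the
    ## multiset of means is unchanged): each planted subnetwork occupies
    ## its own metabolic level, so a shifted member of one subnetwork is
    ## never a baseline look-alike of another subnetwork's hub — the
    ## planted pairs stay the dominant group signal.
    srt <- sort(baseline)
    hubRanks <- unique(round(seq(0.06, 0.94,
                                 length.out = length(hubs)) * (R - 1)) + 1L)
    while (length(hubRanks) < length(hubs))  # tiny-R tie fallback
      hubRanks <- union(hubRanks, sample.int(R, 1L))
    reassigned <- numeric(R)
    reassigned[hubs] <- srt[hubRanks]
    rest <- srt[-hubRanks]
    reassigned[-hubs] <- rest[sample.int(length(rest))]
    baseline <- reassigned
    pairs <- matrix(0L, nrow = 0L, ncol = 2L)
    for (h in hubs) {
      ## partners = the regions metabolically closest to the hub at
      ## baseline: normally-coupled pairs whose decoupling is detectable
      take <- pool[order(abs(baseline[pool] - baseline[h]))][
        seq_len(spec@pairsPerHub)]
      pool <- setdiff(pool, take)
      pairs <- rbind(pairs, cbind(h, take))
      shift[h] <- half
      shift[take] <- -half
    }
  }
  nTot <- spec@nSmci + spec@nPmci
  labels <- c(rep(0L, spec@nSmci), rep(1L, spec@nPmci))
  ord <- sample(nTot)
  labels <- labels[ord]
  subjects <- vector("list", nTot)
  for (s in seq_len(nTot)) {
    mu <- baseline + rnorm(R, 0, spec@subjectNoiseSd)
    if (labels[s] == 1L) mu <- mu + shift
    draws <- matrix(rnorm(R * V, mean = rep(mu, each = V),
                          sd = spec@withinSd), nrow = V)
    samples <- lapply(seq_len(R), function(r) draws[, r])
    names(samples) <- seq_len(R)
    subjects[[s]] <- new("RoiSampleSet",
                         subjectId = sprintf("SYN%03d", s),
                         samples = samples, nRegions = R)
  }
  ## canonical i > j orientation for truth pairs
  tp <- cbind(pmax(pairs[, 1L], pairs[, 2L]),
              pmin(pairs[, 1L], pairs[, 2L]))
  colnames(tp) <- c("i", "j")
  new("SyntheticCohort", subjects = subjects, labels = labels,
      truth = list(affectedPairs = tp, hubRegions = spec@hubRegions,
                   baselineMeans = baseline, plantedShift = shift),
      spec = spec)
}

## sign() that never returns 0 (ties break positive).
sign2 <- function(x) if (x >= 0) 1 else -1

## Near-cubic factorization of n into three positive integers a*b*c = n.
.factor3 <- function(n) {
  best <- NULL
  for (a in seq_len(floor(n^(1 / 3)) + 1L)) {
    if (n %% a) next
    m <- n %/% a
    for (b in a:floor(sqrt(m) + 1L)) {
      if (m %% b) next
      cc <- m %/% b
      cand <- sort(c(a, b, cc))
      if (is.null(best) || cand[3] / cand[1] < best[3] / best[1]) best <- cand
    }
  }
  if (is.null(best)) c(1L, 1L, n) else as.integer(best)
}

#' Build a phantom image/atlas pair for one synthetic subject
#'
#' Lays the cohort's regions out as cuboid parcels in a compact 3D block
#' grid (with the 90 x 500-voxel default: 10 x 10 x 5 parcels tiled on a
#' 50 x 30 x 30 voxel grid) and fills each parcel with that subject's
#' region draws. The pair round-trips exactly through
#' [extractRoiSamples()]: the extracted multiset per region equals the
#' generated sample. This is a geometric phantom, not a PET simulation.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param subjectIndex which subject to lay out.
#' @return list with `volume` (numeric 3D array) and `atlas` (integer 3D
#'   array of labels; 0 outside parcels).
#' @export
generatePhantomVolume <- function(cohort, subjectIndex = 1L) {
  stopifnot(is(cohort, "SyntheticCohort"))
  subj <- cohort@subjects[[subjectIndex]]
  R <- subj@nRegions
  V <- length(subj@samples[[1L]])
  pd <- .factor3(V)                       # parcel dims
  gd <- .factor3(R)                       # parcel-grid dims
  dims <- gd * pd
  atlas <- array(0L, dims)
  vol <- array(0, dims)
  lab <- 0L
  for (kz in seq_len(gd[3])) for (ky in seq_len(gd[2]))
    for (kx in seq_len(gd[1])) {
      lab <- lab + 1L
      if (lab > R) break
      xs <- ((kx - 1L) * pd[1] + 1L):(kx * pd[1])
      ys <- ((ky - 1L) * pd[2] + 1L):(ky * pd[2])
      zs <- ((kz - 1L) * pd[3] + 1L):(kz * pd[3])
      atlas[xs, ys, zs] <- lab
      vol[xs, ys, zs] <- subj@samples[[as.character(lab)]]
    }
  list(volume = vol, atlas = atlas)
}

#' Write a synthetic cohort to disk
#'
#' Per-subject sample files as delimited text (columns = regions) plus a
#' manifest, or phantom NIfTI volume/atlas pairs when `format = "nifti"`.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @param format "csv" (default) or "nifti".
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir, format = c("csv", "nifti")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(cohort@subjects)
  paths <- character(n)
  for (s in seq_len(n)) {
    id <- cohort@subjects[[s]]@subjectId
    if (format == "csv") {
      p <- file.path(dir, paste0(id, ".csv"))
      write.csv(as.data.frame(cohort@subjects[[s]]@samples,
                              col.names = names(cohort@subjects[[s]]@samples),
                              check.names = FALSE),
                p, row.names = FALSE)
    } else {
      ph <- generatePhantomVolume(cohort, s)
      p <- file.path(dir, paste0(id, ".nii.gz"))
      RNifti::writeNifti(ph$volume, p)
      ap <- file.path(dir, "atlas.nii.gz")
      if (!file.exists(ap)) RNifti::writeNifti(ph$atlas, ap)
    }
    paths[s] <- p
  }
  mf <- data.frame(subject_id = vapply(cohort@subjects, slot, character(1),
                                       "subjectId"),
                   image_path = paths,
                   group = ifelse(cohort@labels == 1L, "pMCI", "sMCI"))
  mpath <- file.path(dir, "manifest.csv")
  write.csv(mf, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a csv-format synthetic subject written by [writeCohort()]
#'
#' @param path per-subject csv (columns = region labels).
#' @param subjectId id to attach.
#' @return a [RoiSampleSet-class].
#' @export
readSubjectSamples <- function(path, subjectId = NULL) {
  df <- read.csv(path, check.names = FALSE)
  if (is.null(subjectId)) subjectId <- sub("[.]csv$", "", basename(path))
  samples <- as.list(df)
  names(samples) <- names(df)
  new("RoiSampleSet", subjectId = subjectId, samples = samples,
      nRegions = length(samples))
}
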