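## Density floor below which a KDE value is treated as unsupported: the
## Jeffreys integrand is undefined where P or Q vanishes, and beyond a
## Gaussian kernel's sample support the log-density is an artifact of
## whatever floor constant is used. The integrand is therefore zeroed
## wherever either density falls below the floor (common-support
## quadrature); where both are supported the floored values enter the
## logarithms.
.DENSITY_FLOOR <- 1e-12

## Jeffreys integrand sum on a uniform grid, restricted to the common
## support of the two (already floored) densities.
.jeffreysTrapz <- function(p, q, dx, floor = .DENSITY_FLOOR) {
  integrand <- (p - q) * (log(p) - log(q))
  integrand[p <= floor | q <= floor] <- 0
  dx * (sum(integrand) - (integrand[1] + integrand[length(integrand)]) / 2)
}

#' Symmetric Kullback-Leibler (Jeffreys) divergence of two densities
#'
#' Computes `D = integral of P log(P/Q) + Q log(Q/P)` by trapezoidal
#' quadrature on the common grid of the two density estimates. Densities
#' are floored at 1e-12 before the logarithms, and the integrand is zeroed
#' wherever either density sits at or below the floor: outside a kernel
#' estimate's sample support the log-density reflects only the floor
#' constant, so the integral is restricted to the region where both
#' densities are genuinely estimated (see the methods vignette for the
#' bias this trades away). Tiny negative quadrature results (> -1e-9, pure
#' round-off) are clamped to 0; anything more negative signals a broken
#' density and raises an error. The operation is exactly symmetric in its
#' arguments.
#'
#' @param p,q [DensityEstimate-class] objects on the identical grid, or
#'   plain numeric density vectors (then `grid` must be given).
#' @param grid shared uniform grid (required for plain vectors).
#' @return nonnegative divergence `D`.
#' @export
#' @examples
#' g <- seq(-8, 9, length.out = 4096)
#' p <- dnorm(g); q <- dnorm(g, mean = 1)
#' symmetricKl(p, q, grid = g)  # ~1 for unit-variance normals 1 apart
symmetricKl <- function(p, q, grid = NULL) {
  if (is(p, "DensityEstimate") && is(q, "DensityEstimate")) {
    if (!isTRUE(all.equal(p@grid, q@grid, tolerance = 1e-12)) ||
        length(p@grid) != length(q@grid))
      stop("densities must share an identical grid")
    grid <- p@grid
    pv <- p@density
    qv <- q@density
  } else {
    if (is.null(grid)) stop("grid required for plain density vectors")
    pv <- as.numeric(p)
    qv <- as.numeric(q)
    if (length(pv) != length(qv) || length(pv) != length(grid))
      stop("p, q and grid lengths differ")
  }
  dx <- (grid[length(grid)] - grid[1]) / (length(grid) - 1)
  pv <- pmax(pv, .DENSITY_FLOOR)
  qv <- pmax(qv, .DENSITY_FLOOR)
  d <- .jeffreysTrapz(pv, qv, dx)
  if (d < 0) {
    if (d > -1e-9) d <- 0
    else stop(sprintf("Jeffreys quadrature returned %.3g: broken density", d))
  }
  d
}

#' KLS similarity from a divergence
#'
#' Maps a nonnegative symmetric KL divergence to the similarity
#' `KLS = exp(-D)` in (0, 1]: identical distributions score 1, divergent
#' ones approach 0. For very large divergences `exp(-D)` underflows; by
#' default the result is then reported as the smallest positive normalized
#' double so that similarities remain strictly positive
#' (`underflow = "zero"` returns 0 instead).
#'
#' @param dKl nonnegative divergence (vectorized).
#' @param underflow "tiny" (default) or "zero".
#' @return similarity value(s) in (0, 1] (or [0, 1] with "zero").
#' @export
#' @examples
#' klsSimilarity(c(0, 1))  # 1, exp(-1)
klsSimilarity <- function(dKl, underflow = c("tiny", "zero")) {
  underflow <- match.arg(underflow)
  if (any(!is.finite(dKl)) || any(dKl < 0))
    stop("divergence must be finite and >= 0")
  s <- exp(-dKl)
  if (underflow == "tiny") s[s == 0] <- .Machine$double.xmin
  s
}

## Estimate one subject's region densities on a single shared grid spanning
## all samples, returning the floored density matrix (regions x grid).
.densitiesOnSharedGrid <- function(samples, gridSize, binTarget) {
  bws <- vapply(seq_along(samples), function(r) {
    tryCatch(selectBandwidth(samples[[r]])$bandwidth,
             error = function(e) stop("bandwidth failed for region ",
                                      names(samples)[r], ": ",
                                      conditionMessage(e), call. = FALSE))
  }, numeric(1))
  hmax <- max(bws)
  lo <- min(vapply(samples, min, numeric(1))) - 4 * hmax
  hi <- max(vapply(samples, max, numeric(1))) + 4 * hmax
  grid <- seq(lo, hi, length.out = gridSize)
  dens <- matrix(0, nrow = length(samples), ncol = gridSize)
  for (r in seq_along(samples)) {
    de <- estimatePdf(samples[[r]], grid, bws[r], method = "fft",
                      binTarget = binTarget)
    dens[r, ] <- pmax(de@density, .DENSITY_FLOOR)
  }
  list(grid = grid, dens = dens, bandwidths = bws)
}

#' Build a subject's metabolic network from region samples
#'
#' Runs the KLSE recipe: one kernel density per region (solve-the-equation
#' bandwidth, estimated once and reused for all of the region's pairs),
#' symmetric KL divergence for every region pair by trapezoidal quadrature,
#' similarity `KLS = exp(-D)`, assembled into a symmetric matrix with unit
#' diagonal — the individual metabolic connectome (90 x 90 under AAL-90).
#'
#' Two grid strategies are offered. `"shared"` (default) evaluates all
#' region densities on one uniform grid spanning every sample, so each
#' density is estimated once and reused across its 89 pairs; outside a
#' region's support the floored densities contribute nothing to the
#' integrand, which makes this equivalent to pair-specific domains up to
#' quadrature resolution. `"pairwise"` rebuilds both densities of every
#' pair on a grid spanning exactly that pair (slower, used as a
#' cross-check).
#'
#' @param samples a [RoiSampleSet-class].
#' @param gridSize density grid length (default 2^12).
#' @param minVoxels minimum sample size per region.
#' @param strategy "shared" or "pairwise".
#' @param binTarget FFT binning accuracy passed to [estimatePdf()].
#' @param underflow underflow policy of [klsSimilarity()].
#' @return a [MetabolicNetwork-class].
#' @export
buildNetwork <- function(samples, gridSize = 2^12, minVoxels = 10L,
                         strategy = c("shared", "pairwise"),
                         binTarget = 1e-5, underflow = "tiny") {
  strategy <- match.arg(strategy)
  stopifnot(is(samples, "RoiSampleSet"))
  sm <- samples@samples
  labels <- as.integer(names(sm))
  R <- length(sm)
  if (R < 2L) stop("need at least 2 regions to build a network")
  short <- names(sm)[lengths(sm) < minVoxels]
  if (length(short))
    stop("regions below minVoxels = ", minVoxels, ": ",
         paste(short, collapse = ", "))
  M <- diag(1, R)
  if (strategy == "shared") {
    sh <- .densitiesOnSharedGrid(sm, gridSize, binTarget)
    grid <- sh$grid
    dx <- (grid[gridSize] - grid[1]) / (gridSize - 1)
    dens <- sh$dens
    logd <- log(dens)
    supp <- dens > .DENSITY_FLOOR
    for (i in seq_len(R - 1L)) {
      jj <- (i + 1L):R
      dif <- sweep(dens[jj, , drop = FALSE], 2L, dens[i, ])
      ldf <- sweep(logd[jj, , drop = FALSE], 2L, logd[i, ])
      integ <- dif * ldf *
        (supp[jj, , drop = FALSE] &
           matrix(supp[i, ], nrow = length(jj), ncol = gridSize,
                  byrow = TRUE))
      d <- dx * (rowSums(integ) - (integ[, 1L] + integ[, gridSize]) / 2)
      d[d < 0 & d > -1e-9] <- 0
      if (any(d < 0))
        stop("negative Jeffreys quadrature for region ", labels[i])
      M[i, jj] <- klsSimilarity(d, underflow = underflow)
      M[jj, i] <- M[i, jj]
    }
  } else {
    bws <- lapply(sm, function(s) {
      tryCatch(selectBandwidth(s),
               error = function(e) stop("bandwidth failed for a region: ",
                                        conditionMessage(e)))
    })
    for (i in seq_len(R - 1L)) {
      for (j in (i + 1L):R) {
        hi <- bws[[i]]$bandwidth
        hj <- bws[[j]]$bandwidth
        hmax <- max(hi, hj)
        lo <- min(min(sm[[i]]), min(sm[[j]])) - 4 * hmax
        up <- max(max(sm[[i]]), max(sm[[j]])) + 4 * hmax
        grid <- seq(lo, up, length.out = gridSize)
        pi. <- estimatePdf(sm[[i]], grid, hi, binTarget = binTarget)
        qj <- estimatePdf(sm[[j]], grid, hj, binTarget = binTarget)
        d <- tryCatch(symmetricKl(pi., qj),
                      error = function(e)
                        stop("KL failed for regions ", labels[i], "-",
                             labels[j], ": ", conditionMessage(e)))
        M[i, j] <- M[j, i] <- klsSimilarity(d, underflow = underflow)
      }
    }
  }
  dimnames(M) <- list(labels, labels)
  new("MetabolicNetwork", matrix = M, regionLabels = labels,
      subjectId = samples@subjectId)
}

#' Write / read a metabolic network as delimited text
#'
#' The matrix is stored with region labels as header; `readNetwork()`
#' restores the [MetabolicNetwork-class].
#'
#' @param network a [MetabolicNetwork-class].
#' @param path output file.
#' @export
writeNetwork <- function(network, path) {
  m <- network@matrix
  df <- as.data.frame(m)
  names(df) <- network@regionLabels
  write.csv(cbind(label = network@regionLabels, df), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeNetwork
#' @param subjectId subject id to attach on read.
#' @export
readNetwork <- function(path, subjectId = "subject") {
  df <- read.csv(path, check.names = FALSE)
  labels <- as.integer(df$label)
  m <- as.matrix(df[, -1, drop = FALSE])
  m <- (m + t(m)) / 2  # text round-trip can break exact symmetry
  dimnames(m) <- list(labels, labels)
  new("MetabolicNetwork", matrix = m, regionLabels = labels,
      subjectId = subjectId)
}
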