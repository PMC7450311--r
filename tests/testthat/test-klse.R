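## Closed-form Jeffreys divergence between N(m1, s1^2) and N(m2, s2^2),
## used as the independent oracle for the KDE-based estimate.
gaussJeffreys <- function(m1, s1, m2, s2) {
  d2 <- (m1 - m2)^2
  (s1^2 + d2) / (2 * s2^2) + (s2^2 + d2) / (2 * s1^2) - 1
}

## KDE-based Jeffreys estimate for two samples on a shared grid.
sampleJeffreys <- function(x, y, gridSize = 4096) {
  hx <- selectBandwidth(x)$bandwidth
  hy <- selectBandwidth(y)$bandwidth
  h <- max(hx, hy)
  g <- seq(min(x, y) - 4 * h, max(x, y) + 4 * h, length.out = gridSize)
  symmetricKl(estimatePdf(x, g, hx), estimatePdf(y, g, hy))
}

test_that("symmetric KL is zero for identical densities and symmetric", {
  g <- seq(-6, 6, length.out = 1024)
  p <- estimatePdf(rnorm(100), g, 0.5)
  expect_identical(symmetricKl(p, p), 0)
  q <- estimatePdf(rnorm(100, 1), g, 0.5)
  expect_identical(symmetricKl(p, q), symmetricKl(q, p))
  gBad <- seq(-6.1, 6, length.out = 1024)
  qBad <- estimatePdf(rnorm(100, 1), gBad, 0.5)
  expect_error(symmetricKl(p, qBad), "identical grid")
})

test_that("symmetric KL on exact normal densities matches the closed form", {
  g <- seq(-8, 10, length.out = 2^13)
  for (ms in list(c(0, 1, 1, 1), c(0, 1, 2, 1))) {
    D <- symmetricKl(dnorm(g, ms[1], ms[2]), dnorm(g, ms[3], ms[4]),
                     grid = g)
    expect_equal(D, gaussJeffreys(ms[1], ms[2], ms[3], ms[4]),
                 tolerance = 1e-3)
  }
  ## unequal variances: the common-support restriction trims the wide
  ## density's extreme tail, costing ~1% here
  D <- symmetricKl(dnorm(g, 0, 1), dnorm(g, 1, 2), grid = g)
  expect_equal(D, gaussJeffreys(0, 1, 1, 2), tolerance = 0.02)
})

test_that("KDE-based Jeffreys estimate matches the Gaussian oracle", {
  set.seed(51)
  ## equal variances: the spec of the study conditions, full accuracy
  for (dmu in c(0, 1, 2)) {
    x <- rnorm(10000)
    y <- rnorm(10000, dmu)
    truth <- gaussJeffreys(0, 1, dmu, 1)
    expect_lt(abs(sampleJeffreys(x, y) - truth), max(0.1, 0.05 * truth))
  }
  ## unequal variances, no separation
  x <- rnorm(10000)
  y <- rnorm(10000, 0, 2)
  truth <- gaussJeffreys(0, 1, 0, 2)
  expect_lt(abs(sampleJeffreys(x, y) - truth), max(0.1, 0.05 * truth))
  ## unequal variances with separation: part of the divergence lives in
  ## the wide density's tail beyond the narrow sample's support, which no
  ## nonparametric estimate can see — accuracy is honestly looser there
  x <- rnorm(10000)
  y <- rnorm(10000, 2, 2)
  truth <- gaussJeffreys(0, 1, 2, 2)
  expect_lt(abs(sampleJeffreys(x, y) - truth), 0.25 * truth)
})

test_that("estimated KLS decreases strictly with mean separation", {
  set.seed(52)
  x <- rnorm(10000)
  kls <- vapply(c(0, 0.5, 1, 2, 3), function(dmu)
    klsSimilarity(sampleJeffreys(x, rnorm(10000, dmu))), numeric(1))
  expect_true(all(diff(kls) < 0))
})

test_that("KLS similarity maps divergence to (0, 1]", {
  expect_identical(klsSimilarity(0), 1)
  expect_equal(klsSimilarity(1), exp(-1))
  expect_true(klsSimilarity(50) > 0 && klsSimilarity(50) < 1e-20)
  ## underflow policy
  expect_identical(klsSimilarity(800), .Machine$double.xmin)
  expect_identical(klsSimilarity(800, underflow = "zero"), 0)
  expect_error(klsSimilarity(-0.1), ">= 0")
})

test_that("identical region distributions give an all-ones network", {
  x <- rnorm(200)
  samples <- setNames(lapply(1:5, function(i) x), 1:5)
  rs <- new("RoiSampleSet", subjectId = "const", samples = samples,
            nRegions = 5L)
  net <- buildNetwork(rs, gridSize = 1024)
  expect_true(all(klsMatrix(net) == 1))
})

test_that("three-region toy orders similarities by mean separation", {
  set.seed(53)
  samples <- list("1" = rnorm(10000), "2" = rnorm(10000),
                  "3" = rnorm(10000, 4))
  rs <- new("RoiSampleSet", subjectId = "toy", samples = samples,
            nRegions = 3L)
  m <- klsMatrix(buildNetwork(rs))
  expect_gt(m[1, 2], 100 * m[1, 3])
  expect_lt(abs(log(m[1, 3]) - log(m[2, 3])), 1.5)
})

test_that("the 90-region phantom yields a valid 90 x 90 connectome", {
  net <- phantomNetwork()
  m <- klsMatrix(net)
  expect_equal(dim(m), c(90L, 90L))
  expect_identical(unname(m), unname(t(m)))
  expect_true(all(diag(m) == 1))
  expect_true(all(m > 0 & m <= 1))
})

test_that("network construction is invariant to region processing order", {
  set.seed(54)
  samples <- setNames(lapply(1:6, function(i) rnorm(300, i / 10, 0.3)), 1:6)
  rs1 <- new("RoiSampleSet", subjectId = "a", samples = samples,
             nRegions = 6L)
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  rs2 <- new("RoiSampleSet", subjectId = "a", samples = samples[perm],
             nRegions = 6L)
  m1 <- klsMatrix(buildNetwork(rs1, gridSize = 2048))
  m2 <- klsMatrix(buildNetwork(rs2, gridSize = 2048))
  expect_equal(m1[as.character(perm), as.character(perm)], m2,
               tolerance = 1e-10)
})

test_that("shared-grid and pairwise-grid strategies agree", {
  set.seed(55)
  samples <- setNames(lapply(1:4, function(i) rnorm(400, i / 5, 0.25)), 1:4)
  rs <- new("RoiSampleSet", subjectId = "a", samples = samples,
            nRegions = 4L)
  mS <- klsMatrix(buildNetwork(rs, strategy = "shared"))
  mP <- klsMatrix(buildNetwork(rs, strategy = "pairwise"))
  expect_equal(mS, mP, tolerance = 2e-3)
})

test_that("networks survive a text round-trip", {
  net <- phantomNetwork()
  td <- withr::local_tempdir()
  p <- file.path(td, "net.csv")
  writeNetwork(net, p)
  back <- readNetwork(p, subjectId = subjectId(net))
  expect_equal(klsMatrix(back), klsMatrix(net), tolerance = 1e-12)
  expect_identical(regionLabels(back), regionLabels(net))
})

test_that("undersized regions are rejected with their labels", {
  samples <- list("1" = rnorm(50), "2" = rnorm(3))
  rs <- new("RoiSampleSet", subjectId = "a", samples = samples,
            nRegions = 2L)
  expect_error(buildNetwork(rs), "minVoxels.*2")
})
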