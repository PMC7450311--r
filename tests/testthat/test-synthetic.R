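test_that("cohort generation is deterministic and matches its spec", {
  spec <- syntheticCohortSpec(nSmci = 4, nPmci = 3, nRegions = 12,
                              voxelsPerRegion = 50,
                              hubRegions = c(1L, 2L), pairsPerHub = 2L,
                              seed = 11)
  c1 <- generateCohort(spec)
  c2 <- generateCohort(spec)
  expect_identical(roiSamples(roiSamples(c1)[[1]]),
                   roiSamples(roiSamples(c2)[[1]]))
  expect_identical(cohortLabels(c1), cohortLabels(c2))
  expect_equal(sum(cohortLabels(c1) == 0L), 4L)
  expect_equal(sum(cohortLabels(c1) == 1L), 3L)
  expect_equal(length(roiSamples(c1)), 7L)
  expect_equal(lengths(roiSamples(roiSamples(c1)[[1]])),
               setNames(rep(50L, 12), 1:12))
  tr <- cohortTruth(c1)
  expect_equal(nrow(tr$affectedPairs), 4L)
  expect_true(all(tr$affectedPairs[, "i"] > tr$affectedPairs[, "j"]))
  expect_identical(tr$hubRegions, c(1L, 2L))
})

test_that("default study conditions plant 20 pairs on 5 hub regions", {
  spec <- syntheticCohortSpec(seed = 1)
  expect_equal(spec@nRegions, 90L)
  expect_equal(spec@voxelsPerRegion, 500L)
  expect_equal(spec@effectSize, 0.4)
  expect_identical(spec@hubRegions, c(1L, 11L, 48L, 67L, 89L))
  coh <- generateCohort(syntheticCohortSpec(nSmci = 1, nPmci = 1, seed = 1))
  tr <- cohortTruth(coh)
  expect_equal(nrow(tr$affectedPairs), 20L)
  hubTouch <- vapply(seq_len(20), function(k)
    any(tr$affectedPairs[k, ] %in% tr$hubRegions), logical(1))
  expect_true(all(hubTouch))
  ## partners are distinct and non-hub
  partners <- setdiff(as.vector(tr$affectedPairs), tr$hubRegions)
  expect_equal(length(partners), 20L)
})

test_that("a zero effect size plants no group difference", {
  spec <- syntheticCohortSpec(nSmci = 3, nPmci = 3, nRegions = 10,
                              voxelsPerRegion = 30,
                              hubRegions = 1L, pairsPerHub = 2L,
                              effectSize = 0, seed = 13)
  coh <- generateCohort(spec)
  expect_equal(cohortTruth(coh)$plantedShift, rep(0, 10))
})

test_that("planted pairs separate the groups in KLS space", {
  spec <- syntheticCohortSpec(nSmci = 12, nPmci = 12, nRegions = 15,
                              voxelsPerRegion = 300,
                              hubRegions = c(1L, 2L), pairsPerHub = 3L,
                              seed = 15)
  coh <- generateCohort(spec)
  tr <- cohortTruth(coh)
  meanKls <- vapply(roiSamples(coh), function(s) {
    m <- klsMatrix(buildNetwork(s, gridSize = 2048))
    mean(m[tr$affectedPairs])
  }, numeric(1))
  y <- cohortLabels(coh)
  tt <- t.test(meanKls[y == 0], meanKls[y == 1], alternative = "greater")
  expect_lt(tt$p.value, 1e-3)  # affected-pair KLS is lower in progressives
})

test_that("phantom layout round-trips the generated samples exactly", {
  coh <- generateCohort(syntheticCohortSpec(nSmci = 1, nPmci = 1,
                                            nRegions = 90,
                                            voxelsPerRegion = 500,
                                            seed = 17))
  ph <- generatePhantomVolume(coh, 2L)
  expect_equal(sort(unique(as.integer(ph$atlas[ph$atlas > 0]))), 1:90)
  rs <- extractRoiSamples(ph$volume, ph$atlas, minVoxels = 1L,
                          subjectId = "p")
  orig <- roiSamples(roiSamples(coh)[[2]])
  for (lab in c("1", "45", "90"))
    expect_identical(sort(roiSamples(rs)[[lab]]), sort(orig[[lab]]))
})

test_that("cohorts round-trip through per-subject csv files", {
  coh <- generateCohort(syntheticCohortSpec(nSmci = 2, nPmci = 1,
                                            nRegions = 6,
                                            voxelsPerRegion = 25, seed = 19))
  td <- withr::local_tempdir()
  mp <- writeCohort(coh, td)
  mf <- read.csv(mp)
  expect_equal(nrow(mf), 3L)
  rs <- readSubjectSamples(mf$image_path[1], mf$subject_id[1])
  expect_equal(roiSamples(rs),
               roiSamples(roiSamples(coh)[[1]]), tolerance = 1e-12)
})

test_that("invalid specs are rejected with informative messages", {
  expect_error(syntheticCohortSpec(effectSize = -1), "effectSize")
  expect_error(syntheticCohortSpec(nRegions = 10, hubRegions = 11L),
               "hubRegions")
  expect_error(syntheticCohortSpec(withinSd = 0), "sds must be > 0")
  expect_error(
    syntheticCohortSpec(nRegions = 6, hubRegions = c(1L, 2L),
                        affectedPairs = cbind(3L, 3L)),
    "distinct regions")
  ## not enough partners for the requested pair count
  expect_error(generateCohort(
    syntheticCohortSpec(nSmci = 1, nPmci = 1, nRegions = 6,
                        voxelsPerRegion = 10,
                        hubRegions = c(1L, 2L), pairsPerHub = 4L,
                        seed = 1)),
    "not enough")
})
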