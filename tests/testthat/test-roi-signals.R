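test_that("global-mean normalization rescales to unit masked mean", {
  v <- array(5, c(2, 2, 2))
  m <- array(TRUE, c(2, 2, 2))
  expect_equal(normalizeGlobalMean(v, m), array(1, c(2, 2, 2)))

  ## 3 masked voxels {2, 4, 6}; the unmasked voxel must not enter the mean
  v <- array(c(2, 4, 6, 100), c(4, 1, 1))
  m <- array(c(TRUE, TRUE, TRUE, FALSE), c(4, 1, 1))
  out <- normalizeGlobalMean(v, m)
  expect_equal(as.numeric(out[1:3, 1, 1]), c(0.5, 1.0, 1.5))
  expect_equal(out[4, 1, 1], 25)  # scaled by the same masked mean

  expect_equal(mean(out[m]), 1, tolerance = 1e-12)
  ## idempotence
  expect_equal(normalizeGlobalMean(out, m), out, tolerance = 1e-12)
})

test_that("normalization rejects degenerate masks", {
  v <- array(1, c(2, 2, 2))
  expect_error(normalizeGlobalMean(v, array(FALSE, c(2, 2, 2))), "empty")
  expect_error(normalizeGlobalMean(array(0, c(2, 2, 2)),
                                   array(TRUE, c(2, 2, 2))), "must be > 0")
  expect_error(normalizeGlobalMean(v, array(TRUE, c(2, 2, 1))),
               "dimensions differ")
})

test_that("ROI extraction returns exactly the voxels of each label", {
  atlas <- array(0L, c(2, 2, 2))
  atlas[c(1, 3, 5)] <- 1L
  atlas[c(2, 8)] <- 2L
  vol <- array(as.numeric(1:8), c(2, 2, 2))
  rs <- extractRoiSamples(vol, atlas, minVoxels = 1L)
  expect_s4_class(rs, "RoiSampleSet")
  expect_equal(sort(roiSamples(rs)[["1"]]), c(1, 3, 5))
  expect_equal(sort(roiSamples(rs)[["2"]]), c(2, 8))
  ## partition property: all nonzero voxels accounted for
  expect_equal(sum(lengths(roiSamples(rs))), sum(atlas > 0))
})

test_that("ROI extraction errors and warnings", {
  atlas <- array(1L, c(2, 2, 2))
  vol <- array(1, c(2, 2, 2))
  expect_error(extractRoiSamples(vol, array(1L, c(2, 2, 1))), "grids differ")
  expect_error(extractRoiSamples(vol, array(0L, c(2, 2, 2))),
               "no nonzero labels")
  expect_error(extractRoiSamples(vol, atlas, minVoxels = 100L,
                                 onSmall = "error"), "minVoxels")
  expect_warning(
    extractRoiSamples(vol, atlas, minVoxels = 1L,
                      lookup = data.frame(label = c(1L, 7L))),
    "absent from atlas")
  atlas2 <- atlas
  atlas2[1:2] <- 2L
  expect_warning(extractRoiSamples(vol, atlas2, minVoxels = 5L), "dropping")
})

test_that("downstream statistics are invariant to voxel order in a region", {
  set.seed(11)
  vals <- rnorm(24)
  atlas <- array(1L, c(4, 3, 2))
  v1 <- array(vals, c(4, 3, 2))
  v2 <- array(vals[sample(24)], c(4, 3, 2))
  s1 <- roiSamples(extractRoiSamples(v1, atlas, minVoxels = 1L))[["1"]]
  s2 <- roiSamples(extractRoiSamples(v2, atlas, minVoxels = 1L))[["1"]]
  expect_equal(sort(s1), sort(s2))
  expect_equal(selectBandwidth(s1)$bandwidth, selectBandwidth(s2)$bandwidth)
})

test_that("phantom volumes round-trip through NIfTI files", {
  coh <- generateCohort(syntheticCohortSpec(
    nSmci = 1, nPmci = 1, nRegions = 8, voxelsPerRegion = 64, seed = 5))
  ph <- generatePhantomVolume(coh, 1L)
  td <- withr::local_tempdir()
  vp <- file.path(td, "vol.nii.gz")
  ap <- file.path(td, "atlas.nii.gz")
  RNifti::writeNifti(ph$volume, vp)
  RNifti::writeNifti(ph$atlas, ap)
  vol <- readBrainVolume(vp)
  atl <- readAtlasVolume(ap)
  expect_equal(dim(vol), dim(ph$volume))
  expect_equal(sort(unique(as.integer(atl[atl > 0]))), 1:8)
  rs <- extractRoiSamples(vol, atl, minVoxels = 1L)
  orig <- roiSamples(roiSamples(coh)[[1L]])
  for (lab in names(orig))
    expect_equal(sort(roiSamples(rs)[[lab]]), sort(orig[[lab]]),
                 tolerance = 1e-6)  # NIfTI stores float32
})

test_that("lookup and manifest readers validate their schemas", {
  td <- withr::local_tempdir()
  lp <- file.path(td, "lookup.csv")
  write.csv(aal90Lookup(), lp, row.names = FALSE)
  lk <- readRoiLookup(lp)
  expect_equal(nrow(lk), 90)
  expect_equal(lk$name[lk$label == 67], "Precuneus_L")

  mp <- file.path(td, "manifest.csv")
  write.csv(data.frame(subject_id = c("a", "b"),
                       image_path = c("a.nii", "b.nii"),
                       group = c("sMCI", "pMCI")), mp, row.names = FALSE)
  mf <- readManifest(mp)
  expect_equal(mf$group, c("sMCI", "pMCI"))
  write.csv(data.frame(subject_id = "a", image_path = "a.nii",
                       group = "AD"), mp, row.names = FALSE)
  expect_error(readManifest(mp), "sMCI")
})
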