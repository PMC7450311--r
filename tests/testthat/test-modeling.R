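test_that("stratified splits preserve class balance within one subject", {
  y <- c(rep(0L, 242), rep(1L, 178))
  sp <- makeSplits(y, nIterations = 10, baseSeed = 3)
  for (s in sp) {
    expect_equal(sort(c(s$train, s$test)), seq_along(y))  # disjoint partition
    expect_equal(length(s$train), 210)
    expect_lte(abs(sum(y[s$train] == 0L) - 121), 1)
    expect_lte(abs(sum(y[s$train] == 1L) - 89), 1)
  }
  ## forced stratification at n = 4
  sp4 <- makeSplits(c(0L, 0L, 1L, 1L), nIterations = 20, baseSeed = 1)
  for (s in sp4) {
    expect_equal(sum(c(0L, 0L, 1L, 1L)[s$train]), 1L)
    expect_equal(length(s$train), 2L)
  }
})

test_that("splits are reproducible and reject degenerate cohorts", {
  y <- rep(c(0L, 1L), 30)
  expect_identical(makeSplits(y, 5, baseSeed = 99),
                   makeSplits(y, 5, baseSeed = 99))
  expect_false(identical(makeSplits(y, 5, baseSeed = 99),
                         makeSplits(y, 5, baseSeed = 100)))
  expect_error(makeSplits(c(0L, 0L, 0L, 1L), 2), "at least 2")
  expect_error(makeSplits(y, 5, trainFraction = 1), "trainFraction")
})

test_that("LASSO recovers a planted informative feature", {
  set.seed(61)
  hits <- 0L
  nRep <- 30L
  for (r in seq_len(nRep)) {
    n <- 200
    y <- rep(c(0L, 1L), n / 2)
    X <- cbind(rnorm(n, mean = 2 * y), matrix(rnorm(n * 50), n, 50))
    sel <- selectFeaturesLasso(X, y, seed = r)
    if (1L %in% sel$selected) hits <- hits + 1L
  }
  expect_gte(hits, round(0.95 * nRep) - 1L)
})

test_that("LASSO tolerates pure noise and duplicated columns", {
  set.seed(62)
  n <- 80
  y <- rep(c(0L, 1L), n / 2)
  X <- matrix(rnorm(n * 40), n, 40)
  sel <- suppressWarnings(selectFeaturesLasso(X, y, seed = 1))
  expect_true(length(sel$selected) >= 1L)  # fallback guarantees nonempty
  ## duplicated columns: no crash, selection still valid indices
  X2 <- cbind(X[, 1], X[, 1], X)
  sel2 <- suppressWarnings(selectFeaturesLasso(X2, y, seed = 1))
  expect_true(all(sel2$selected %in% seq_len(ncol(X2))))
})

test_that("classifiers separate Gaussian blobs and are deterministic", {
  set.seed(63)
  n <- 100
  y <- rep(c(0L, 1L), n / 2)
  X <- matrix(rnorm(n * 2), n, 2) + 5 * cbind(y, y)
  Xte <- matrix(rnorm(n * 2), n, 2) + 5 * cbind(y, y)
  svm <- trainClassifier(X, y, "svm_linear", seed = 1)
  expect_equal(predictScores(svm, X)$class, y)  # separable: 100% train
  for (kind in c("svm_linear", "logistic_l1", "random_forest")) {
    m <- trainClassifier(X, y, kind, seed = 1)
    acc <- mean(predictScores(m, Xte)$class == y)
    expect_gt(acc, 0.9)
  }
  rf1 <- predictScores(trainClassifier(X, y, "random_forest", seed = 5), Xte)
  rf2 <- predictScores(trainClassifier(X, y, "random_forest", seed = 5), Xte)
  expect_identical(rf1$score, rf2$score)
  expect_error(trainClassifier(X, rep(1L, n), "svm_linear"), "both classes")
})

test_that("test subjects never influence selection or training", {
  set.seed(64)
  n <- 60
  y <- rep(c(0L, 1L), n / 2)
  X <- cbind(rnorm(n, 1.5 * y), matrix(rnorm(n * 20), n, 20))
  tr <- 1:40
  te <- 41:60
  fitOnce <- function(yFull) {
    sel <- suppressWarnings(selectFeaturesLasso(X[tr, ], yFull[tr],
                                                seed = 2))
    m <- trainClassifier(X[tr, sel$selected, drop = FALSE], yFull[tr],
                         "svm_linear", seed = 2)
    list(sel = sel$selected, scores = predictScores(
      m, X[te, sel$selected, drop = FALSE])$score)
  }
  yCorrupt <- y
  yCorrupt[te] <- 1L - yCorrupt[te]
  a <- fitOnce(y)
  b <- fitOnce(yCorrupt)
  expect_identical(a$sel, b$sel)
  expect_identical(a$scores, b$scores)
})

test_that("pipeline summaries equal the mean of per-iteration metrics", {
  sc <- smallCohortFeatures()
  res <- suppressWarnings(
    runPipeline(sc$dataset, nIterations = 4, kinds = "svm_linear",
                baseSeed = 17))[[1]]
  acc <- vapply(iterationResults(res),
                function(r) r$metrics$accuracy, numeric(1))
  s <- resultSummary(res)
  expect_equal(s$mean[s$metric == "accuracy"], mean(acc), tolerance = 1e-12)
  expect_equal(s$sd[s$metric == "accuracy"], sd(acc), tolerance = 1e-12)
})

test_that("the pipeline is reproducible from its base seed", {
  sc <- smallCohortFeatures()
  r1 <- suppressWarnings(
    runPipeline(sc$dataset, nIterations = 3, kinds = "svm_linear",
                baseSeed = 23))[[1]]
  r2 <- suppressWarnings(
    runPipeline(sc$dataset, nIterations = 3, kinds = "svm_linear",
                baseSeed = 23))[[1]]
  expect_identical(resultSummary(r1), resultSummary(r2))
  expect_identical(lapply(iterationResults(r1), `[[`, "selected"),
                   lapply(iterationResults(r2), `[[`, "selected"))
})

test_that("a single-iteration run reports zero spread without crashing", {
  sc <- smallCohortFeatures()
  res <- suppressWarnings(
    runPipeline(sc$dataset, nIterations = 1, kinds = "svm_linear",
                baseSeed = 31))[[1]]
  expect_equal(resultSummary(res)$sd, rep(0, 6))
  expect_equal(length(iterationResults(res)), 1L)
})

test_that("label-permuted features classify at chance", {
  sc <- smallCohortFeatures()
  set.seed(65)
  yPerm <- sample(cohortLabels(sc$dataset))
  dsPerm <- new("CohortDataset", X = designMatrix(sc$dataset),
                y = yPerm, subjectIds = sc$dataset@subjectIds,
                featureIndex = featurePairs(sc$dataset),
                kind = "connectome")
  res <- suppressWarnings(
    runPipeline(dsPerm, nIterations = 10, kinds = "svm_linear",
                baseSeed = 41))[[1]]
  acc <- resultSummary(res)$mean[resultSummary(res)$metric == "accuracy"]
  expect_gt(acc, 20)  # chance on a 30-subject cohort, wide MC band
  expect_lt(acc, 80)
})
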