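## Deterministic per-iteration seed derived from a base seed (kept within
## 32-bit integer range).
.iterSeed <- function(baseSeed, iter, salt = 0L) {
  as.integer((as.numeric(baseSeed) + 7919 * iter + 104729 * salt) %%
               .Machine$integer.max)
}

## Stratified fold assignment (for inner cross-validation).
.makeFolds <- function(y, nFolds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}

#' Repeated stratified train/test splits
#'
#' Generates `nIterations` random partitions of the cohort into a training
#' and a test half (default 50/50). With `stratified = TRUE` each side's
#' class proportions match the cohort's to within one subject per class.
#' Splits are a deterministic function of `baseSeed`.
#'
#' @param y integer 0/1 labels.
#' @param nIterations number of random splits (default 100).
#' @param trainFraction fraction assigned to training (default 0.5).
#' @param stratified preserve class proportions (default TRUE).
#' @param baseSeed integer seed.
#' @return list of `list(train=, test=)` index vectors.
#' @export
makeSplits <- function(y, nIterations = 100L, trainFraction = 0.5,
                       stratified = TRUE, baseSeed = 1L) {
  y <- as.integer(y)
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0, 1)")
  if (nIterations < 1L) stop("nIterations must be >= 1")
  if (any(table(y) < 2L)) stop("each class needs at least 2 subjects")
  lapply(seq_len(nIterations), function(it) {
    set.seed(.iterSeed(baseSeed, it))
    if (stratified) {
      train <- unlist(lapply(unique(y), function(cl) {
        idx <- which(y == cl)
        sample(idx, round(length(idx) * trainFraction))
      }))
    } else {
      train <- sample(seq_along(y), round(length(y) * trainFraction))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(y), train))
  })
}

## Feature standardization learned on training data only.
.fitScaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(center = mu, scale = sdv)
}

.applyScaler <- function(X, scaler) {
  scale(X, center = scaler$center, scale = scaler$scale)[, , drop = FALSE]
}

#' Cross-validated LASSO feature selection
#'
#' Fits an L1-penalized logistic regression path (100 log-spaced penalties
#' down to 1e-4 of the null penalty) on internally z-scored training
#' features and picks the penalty minimizing 10-fold cross-validated
#' binomial deviance. Selected features are those with nonzero
#' coefficients at the chosen penalty. If that set is empty (e.g. pure
#' noise), the fit falls back to the most-regularized penalty on the path
#' retaining at least one feature, and flags the fallback.
#'
#' @param X numeric training matrix (subjects x features).
#' @param y 0/1 training labels.
#' @param nFolds inner cross-validation folds (default 10).
#' @param seed integer seed for fold assignment.
#' @return list with `selected` (column indices), `lambda`, and `fallback`
#'   (logical).
#' @export
selectFeaturesLasso <- function(X, y, nFolds = 10L, seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes required")
  scaler <- .fitScaler(X)
  Xs <- .applyScaler(X, scaler)
  set.seed(seed)
  foldid <- .makeFolds(y, nFolds)
  cv <- glmnet::cv.glmnet(Xs, y, family = "binomial", alpha = 1,
                          foldid = foldid, nlambda = 100,
                          lambda.min.ratio = 1e-4, standardize = FALSE,
                          type.measure = "deviance")
  lam <- cv$lambda.min
  beta <- as.numeric(coef(cv$glmnet.fit, s = lam))[-1L]
  selected <- which(beta != 0)
  fallback <- FALSE
  if (length(selected) == 0L) {
    nz <- cv$glmnet.fit$df
    k <- which(nz >= 1L)[1L]
    if (is.na(k)) stop("LASSO path never retains a feature")
    lam <- cv$glmnet.fit$lambda[k]
    beta <- as.numeric(coef(cv$glmnet.fit, s = lam))[-1L]
    selected <- which(beta != 0)
    fallback <- TRUE
  }
  list(selected = selected, lambda = lam, fallback = fallback)
}

#' Train a classifier on selected features
#'
#' Fits one of the three classifier kinds on (already standardized)
#' selected features: linear-kernel SVM with the cost parameter tuned by
#' inner stratified cross-validation over `costGrid`, L1-penalized
#' logistic regression with its penalty tuned by inner cross-validation,
#' or a 500-tree random forest with sqrt(F) candidate features per split.
#' The returned model exposes a continuous decision score and a binary
#' prediction via [predictScores()].
#'
#' @param X numeric training matrix restricted to selected, standardized
#'   features.
#' @param y 0/1 labels (1 = positive / progressive class).
#' @param kind "svm_linear", "logistic_l1" or "random_forest".
#' @param seed integer seed.
#' @param costGrid SVM cost grid (default 0.01, 0.1, 1, 10, 100).
#' @param nFolds inner folds for hyperparameter tuning (default 10).
#' @return an object of class `cpmModel`.
#' @export
trainClassifier <- function(X, y,
                            kind = c("svm_linear", "logistic_l1",
                                     "random_forest"),
                            seed = 1L, costGrid = c(0.01, 0.1, 1, 10, 100),
                            nFolds = 10L) {
  kind <- match.arg(kind)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes required for training")
  X <- as.matrix(X)
  set.seed(seed)
  fit <- switch(kind,
    svm_linear = {
      yf <- factor(y, levels = c(0L, 1L))
      nf <- min(nFolds, min(table(y)))
      foldid <- .makeFolds(y, nf)
      cvAcc <- vapply(costGrid, function(C) {
        correct <- 0L
        for (f in seq_len(nf)) {
          tr <- foldid != f
          if (length(unique(y[tr])) < 2L) next
          m <- e1071::svm(X[tr, , drop = FALSE], yf[tr], kernel = "linear",
                          cost = C, scale = FALSE)
          correct <- correct +
            sum(predict(m, X[!tr, , drop = FALSE]) == yf[!tr])
        }
        correct / length(y)
      }, numeric(1))
      bestC <- costGrid[which.max(cvAcc)]
      m <- e1071::svm(X, yf, kernel = "linear", cost = bestC, scale = FALSE)
      list(model = m, cost = bestC)
    },
    logistic_l1 = {
      nf <- min(nFolds, min(table(y)))
      foldid <- .makeFolds(y, nf)
      cv <- glmnet::cv.glmnet(cbind(X, 0), y, family = "binomial",
                              alpha = 1, foldid = foldid,
                              standardize = FALSE,
                              type.measure = "deviance")
      list(model = cv, ncol = ncol(X))
    },
    random_forest = {
      yf <- factor(y, levels = c(0L, 1L))
      m <- randomForest::randomForest(
        X, yf, ntree = 500L, mtry = max(1L, floor(sqrt(ncol(X)))))
      list(model = m)
    })
  structure(list(kind = kind, fit = fit, p = ncol(X)), class = "cpmModel")
}

#' Decision scores and class predictions from a trained model
#'
#' @param model a `cpmModel` from [trainClassifier()].
#' @param X new-subject feature matrix (same standardization and feature
#'   subset as training).
#' @return list with `score` (continuous, higher = more positive) and
#'   `class` (0/1 prediction).
#' @export
predictScores <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$p) stop("feature count mismatch")
  switch(model$kind,
    svm_linear = {
      p <- predict(model$fit$model, X, decision.values = TRUE)
      dv <- attr(p, "decision.values")
      sc <- as.numeric(dv[, 1L])
      if (!startsWith(colnames(dv)[1L], "1"))
        sc <- -sc  # orient so that higher score favors the positive class
      list(score = sc, class = as.integer(as.character(p)))
    },
    logistic_l1 = {
      pr <- as.numeric(predict(model$fit$model, cbind(X, 0),
                               s = "lambda.min", type = "response"))
      list(score = pr, class = as.integer(pr >= 0.5))
    },
    random_forest = {
      pr <- predict(model$fit$model, X, type = "prob")[, "1"]
      list(score = as.numeric(pr), class = as.integer(pr >= 0.5))
    })
}

## Confusion metrics + AUC for one evaluated test set.
.evaluateTest <- function(pred, yTest) {
  tp <- sum(pred$class == 1L & yTest == 1L)
  fp <- sum(pred$class == 1L & yTest == 0L)
  tn <- sum(pred$class == 0L & yTest == 0L)
  fn <- sum(pred$class == 0L & yTest == 1L)
  cm <- confusionMetrics(tp, fp, tn, fn)
  cm$auc <- rocAuc(pred$score, yTest)$auc
  cm
}

#' Repeated-split connectome-based predictive modeling pipeline
#'
#' The full evaluation loop: for each of `nIterations` stratified 50/50
#' splits, features are z-scored with training statistics only, the LASSO
#' (inner 10-fold cross-validation) selects a sparse feature subset on the
#' training half, each requested classifier is trained on those features,
#' and performance is measured on the untouched test half. Nothing from
#' the test half enters selection, standardization or hyperparameter
#' tuning. Selection frequencies across iterations define the consensus
#' feature set (frequency strictly greater than `consensusThreshold`).
#'
#' @param dataset a [CohortDataset-class].
#' @param nIterations random splits (default 100).
#' @param trainFraction training fraction (default 0.5).
#' @param kinds classifier kinds to evaluate (default linear SVM).
#' @param baseSeed integer seed controlling every random element.
#' @param consensusThreshold consensus selection frequency (default 0.5).
#' @param nFolds inner cross-validation folds (default 10).
#' @param verbose print per-iteration progress.
#' @return named list of [CohortRunResult-class], one per classifier kind.
#' @export
runPipeline <- function(dataset, nIterations = 100L, trainFraction = 0.5,
                        kinds = "svm_linear", baseSeed = 1L,
                        consensusThreshold = 0.5, nFolds = 10L,
                        verbose = FALSE) {
  stopifnot(is(dataset, "CohortDataset"))
  X <- dataset@X
  y <- dataset@y
  splits <- makeSplits(y, nIterations = nIterations,
                       trainFraction = trainFraction, baseSeed = baseSeed)
  perIter <- replicate(length(kinds), vector("list", nIterations),
                       simplify = FALSE)
  names(perIter) <- kinds
  selFreq <- numeric(ncol(X))
  for (it in seq_len(nIterations)) {
    sp <- splits[[it]]
    Xtr <- X[sp$train, , drop = FALSE]
    ytr <- y[sp$train]
    scaler <- .fitScaler(Xtr)
    XtrS <- .applyScaler(Xtr, scaler)
    XteS <- .applyScaler(X[sp$test, , drop = FALSE], scaler)
    sel <- selectFeaturesLasso(Xtr, ytr, nFolds = nFolds,
                               seed = .iterSeed(baseSeed, it, 1L))
    selFreq[sel$selected] <- selFreq[sel$selected] + 1
    for (k in kinds) {
      model <- trainClassifier(XtrS[, sel$selected, drop = FALSE], ytr,
                               kind = k,
                               seed = .iterSeed(baseSeed, it, 2L),
                               nFolds = nFolds)
      pred <- predictScores(model, XteS[, sel$selected, drop = FALSE])
      ev <- .evaluateTest(pred, y[sp$test])
      perIter[[k]][[it]] <- list(
        iteration = it, selected = sel$selected, lambda = sel$lambda,
        lassoFallback = sel$fallback, classifier = k, metrics = ev)
    }
    if (verbose) message("iteration ", it, ": ",
                         length(sel$selected), " features selected")
  }
  selFreq <- selFreq / nIterations
  consensus <- which(selFreq > consensusThreshold)
  metricNames <- c("accuracy", "sensitivity", "specificity", "fpr", "fnr",
                   "auc")
  out <- lapply(kinds, function(k) {
    vals <- sapply(metricNames, function(mn)
      vapply(perIter[[k]], function(r) r$metrics[[mn]], numeric(1)))
    vals <- matrix(vals, nrow = nIterations,
                   dimnames = list(NULL, metricNames))
    smry <- data.frame(
      metric = metricNames,
      mean = colMeans(vals),
      sd = if (nIterations > 1L) apply(vals, 2L, sd) else
        rep(0, length(metricNames)),
      row.names = NULL)
    new("CohortRunResult", classifier = k, perIteration = perIter[[k]],
        summary = smry, selectionFrequency = selFreq,
        consensusFeatures = as.integer(consensus),
        consensusThreshold = consensusThreshold)
  })
  names(out) <- kinds
  out
}
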