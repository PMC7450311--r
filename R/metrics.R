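#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity, specificity and the complementary false-positive
#' and false-negative rates, all in percent. The positive class is the
#' progressive (pMCI) group, so sensitivity tracks converter detection.
#' By construction `fpr = 100 - specificity` and `fnr = 100 - sensitivity`.
#'
#' @param tp,fp,tn,fn nonnegative confusion counts; both classes must be
#'   represented (`tp + fn > 0`, `tn + fp > 0`).
#' @return named list with counts and percentage metrics.
#' @export
#' @examples
#' confusionMetrics(tp = 37, fp = 6, tn = 26, fn = 5)$sensitivity  # 88.1
confusionMetrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be >= 0")
  if (tp + fn == 0) stop("no positive-class subjects (tp + fn = 0)")
  if (tn + fp == 0) stop("no negative-class subjects (tn + fp = 0)")
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = 100 * (tp + tn) / sum(counts),
       sensitivity = sens, specificity = spec,
       fpr = 100 - spec, fnr = 100 - sens)
}

#' ROC curve and area under the curve
#'
#' AUC is the probability that a randomly chosen positive outscores a
#' randomly chosen negative, with ties credited 1/2 (the Mann-Whitney
#' convention), computed through average ranks; this equals the trapezoidal
#' area under the empirical ROC curve.
#'
#' @param scores numeric decision scores (higher = more positive).
#' @param labels 0/1 labels, both classes present.
#' @return list with `auc` and `curve` (data.frame of fpr, tpr stepping
#'   through decreasing score thresholds).
#' @export
#' @examples
#' rocAuc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$auc  # 0.75
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(scores, decreasing = TRUE)
  ls <- labels[ord]
  ss <- scores[ord]
  keep <- c(ss[-length(ss)] != ss[-1], TRUE)  # one point per threshold
  tpr <- cumsum(ls == 1L)[keep] / np
  fpr <- cumsum(ls == 0L)[keep] / nn
  list(auc = auc,
       curve = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Calibration test for predicted probabilities: subjects are grouped into
#' equal-count "deciles of risk" by predicted probability; the statistic
#' sums `(O - E)^2 / E` over observed/expected events and non-events in
#' each group and is referred to a chi-square with `groups - 2` degrees of
#' freedom — the reference distribution for probabilities fitted on the
#' same data, the test's standard logistic-regression use (for externally
#' supplied probabilities the statistic is closer to chi-square with
#' `groups` degrees of freedom and this p-value is conservative in
#' neither direction). When there are fewer distinct probabilities than groups,
#' adjacent groups are merged with a warning and the degrees of freedom
#' shrink accordingly.
#'
#' @param probs predicted event probabilities in (0, 1).
#' @param labels 0/1 observed outcomes.
#' @param nGroups number of risk groups (default 10).
#' @return list with `chi2`, `p_value`, `dof`, `n_groups_used` and the
#'   per-group `table` (observed/expected events and sizes).
#' @export
hosmerLemeshow <- function(probs, labels, nGroups = 10L) {
  labels <- as.integer(labels)
  n <- length(probs)
  if (length(labels) != n) stop("probs/labels length mismatch")
  if (n < 2L * nGroups) stop("need at least 2 subjects per group")
  if (any(probs <= 0 | probs >= 1)) stop("probs must lie strictly in (0, 1)")
  brk <- quantile(probs, seq(0, 1, length.out = nGroups + 1L), names = FALSE)
  ubrk <- unique(brk)
  if (length(ubrk) < nGroups + 1L)
    warning("fewer distinct probabilities than groups: merging to ",
            length(ubrk) - 1L, " groups")
  g <- cut(probs, ubrk, include.lowest = TRUE, labels = FALSE)
  ng <- length(ubrk) - 1L
  O <- tapply(labels, g, sum)
  E <- tapply(probs, g, sum)
  sz <- tapply(labels, g, length)
  if (any(E <= 0) || any(sz - E <= 0))
    stop("a risk group has expected count 0")
  chi2 <- sum((O - E)^2 / E + ((sz - O) - (sz - E))^2 / (sz - E))
  dof <- ng - 2L
  list(chi2 = unname(chi2),
       p_value = pchisq(chi2, df = dof, lower.tail = FALSE),
       dof = dof, n_groups_used = ng,
       table = data.frame(group = seq_len(ng), n = as.vector(sz),
                          observed = as.vector(O), expected = as.vector(E)))
}

#' Summarize repeated-split results as performance tables
#'
#' Formats one or more [CohortRunResult-class] objects into the field's
#' usual reporting shape: a wide table of `mean +/- sd` percentages per
#' classifier for accuracy/sensitivity/specificity/AUC, and the
#' complementary error-rate table (FPR/FNR).
#'
#' @param results named list of [CohortRunResult-class] objects (one per
#'   classifier) or a single result.
#' @return list of two data.frames: `performance` and `error_rates`.
#' @export
performanceTables <- function(results) {
  if (is(results, "CohortRunResult")) results <- list(results)
  fmt <- function(m, s) sprintf("%.1f ± %.2f", m, s)
  perf <- do.call(rbind, lapply(results, function(r) {
    s <- r@summary
    g <- function(metric, col) s[s$metric == metric, col]
    data.frame(classifier = r@classifier,
               accuracy = fmt(g("accuracy", "mean"), g("accuracy", "sd")),
               sensitivity = fmt(g("sensitivity", "mean"), g("sensitivity", "sd")),
               specificity = fmt(g("specificity", "mean"), g("specificity", "sd")),
               auc = sprintf("%.3f ± %.3f", g("auc", "mean") ,
                             g("auc", "sd")))
  }))
  errs <- do.call(rbind, lapply(results, function(r) {
    s <- r@summary
    g <- function(metric, col) s[s$metric == metric, col]
    data.frame(classifier = r@classifier,
               fpr = fmt(g("fpr", "mean"), g("fpr", "sd")),
               fnr = fmt(g("fnr", "mean"), g("fnr", "sd")))
  }))
  list(performance = perf, error_rates = errs)
}
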