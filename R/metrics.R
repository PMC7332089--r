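#' Site-centric confusion counts for one replica
#'
#' Every proline in the replica is an independent example: true positives
#' are correctly predicted hydroxylation sites, false positives prolines
#' called modified against the annotation, and so on. Sites outside the
#' replica are ignored.
#'
#' @param predictions Prediction data.frame (with `key` and `call` columns),
#'   or a named 0/1 vector of calls indexed by site key.
#' @param positives,negatives Character vectors of replica site keys.
#' @param missingPolicy What to do when a replica site has no prediction:
#'   `"error"` (default) or `"negative"` (count as a negative call; the
#'   number of such sites is attached as attribute `nMissing`).
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusionCounts <- function(predictions, positives, negatives,
                            missingPolicy = c("error", "negative")) {
  missingPolicy <- match.arg(missingPolicy)
  calls <- if (is.data.frame(predictions)) {
    setNames(predictions$call, predictions$key)
  } else predictions
  keys <- c(positives, negatives)
  got <- calls[keys]
  nMissing <- sum(is.na(got))
  if (nMissing) {
    if (missingPolicy == "error")
      stop(nMissing, " replica site(s) have no prediction, e.g. '",
           keys[which(is.na(got))[1]], "'")
    got[is.na(got)] <- 0L
  }
  truth <- rep(c(1L, 0L), c(length(positives), length(negatives)))
  out <- c(TP = sum(got == 1L & truth == 1L),
           FP = sum(got == 1L & truth == 0L),
           TN = sum(got == 0L & truth == 0L),
           FN = sum(got == 0L & truth == 1L))
  attr(out, "nMissing") <- nMissing
  out
}

#' The six evaluation metrics from confusion counts
#'
#' Sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, balanced
#' accuracy `WACC = (Sn+Sp)/2`, precision `PREC = TP/(TP+FP)`, F-measure
#' `F1 = 2TP/(2TP+FP+FN)` and Matthews correlation
#' `MCC = (TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Any undefined 0/0 ratio (e.g. precision with no positive calls, MCC with
#' a zero denominator) is reported as 0 so that replica aggregation stays
#' total; this keeps worse-than-random predictors visibly below zero on MCC.
#'
#' @param counts Named vector with `TP`, `FP`, `TN`, `FN` entries.
#' @return Named numeric vector `c(Sn, Sp, WACC, F1, PREC, MCC)`.
#' @export
computeMetrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
  if (any(c(tp, fp, tn, fn) < 0)) stop("negative confusion counts")
  if (tp + fp + tn + fn == 0) stop("empty confusion table")
  safe <- function(num, den) if (den == 0) 0 else num / den
  sn <- safe(tp, tp + fn)
  sp <- safe(tn, tn + fp)
  prec <- safe(tp, tp + fp)
  f1 <- safe(2 * tp, 2 * tp + fp + fn)
  mccDen <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mccDen == 0) 0 else (tp * tn - fp * fn) / sqrt(mccDen)
  c(Sn = sn, Sp = sp, WACC = (sn + sp) / 2, F1 = f1, PREC = prec, MCC = mcc)
}

#' Aggregate per-replica metrics as mean and standard deviation
#'
#' Error bars across replicas use the sample (n-1) standard deviation, as
#' replicas are draws from a resampling distribution.
#'
#' @param metricMatrix Numeric matrix, one row per replica, columns named by
#'   metric.
#' @return A data.frame with columns `metric`, `mean`, `sd`.
#' @export
aggregateMetrics <- function(metricMatrix) {
  stopifnot(is.matrix(metricMatrix), nrow(metricMatrix) >= 2L)
  data.frame(metric = colnames(metricMatrix),
             mean = colMeans(metricMatrix),
             sd = apply(metricMatrix, 2L, stats::sd),
             row.names = NULL)
}

#' Evaluate one predictor over a replica collection
#'
#' @param predictions Prediction data.frame or named call vector (see
#'   [confusionCounts]).
#' @param replicas A [ReplicaCollection-class].
#' @param missingPolicy Passed to [confusionCounts].
#' @return A list with `perReplica` (replicas x metrics matrix) and
#'   `summary` (from [aggregateMetrics]).
#' @export
evaluatePredictor <- function(predictions, replicas,
                              missingPolicy = c("error", "negative")) {
  stopifnot(is(replicas, "ReplicaCollection"))
  missingPolicy <- match.arg(missingPolicy)
  calls <- if (is.data.frame(predictions)) {
    setNames(predictions$call, predictions$key)
  } else predictions
  n <- nReplicas(replicas)
  per <- matrix(NA_real_, n, 6L,
                dimnames = list(NULL, c("Sn", "Sp", "WACC", "F1", "PREC",
                                        "MCC")))
  for (r in seq_len(n)) {
    cc <- confusionCounts(calls, replicaPositives(replicas, r),
                          replicaNegatives(replicas, r), missingPolicy)
    per[r, ] <- computeMetrics(cc)
  }
  list(perReplica = per, summary = aggregateMetrics(per))
}

#' Precision-recall and ROC curves for score-bearing predictions
#'
#' Thresholds are swept over the unique scores (ties grouped); a site is
#' called positive when its score is greater than or equal to the threshold.
#' The ROC area is computed by the trapezoid rule.
#'
#' @param scores Named numeric vector of prediction scores by site key.
#' @param positives,negatives Character vectors of evaluated site keys.
#' @return A list with `points` (data.frame of threshold, TPR, FPR,
#'   precision, recall) and `auc`.
#' @export
predictionCurves <- function(scores, positives, negatives) {
  keys <- c(positives, negatives)
  if (anyNA(scores[keys]))
    stop("scores missing for some evaluated sites")
  s <- scores[keys]
  truth <- rep(c(1L, 0L), c(length(positives), length(negatives)))
  thr <- sort(unique(s), decreasing = TRUE)
  if (length(thr) == 1L) {
    warning("all scores identical: degenerate single-point curve, AUC 0.5")
    return(list(points = data.frame(threshold = thr, TPR = 1, FPR = 1,
                                    precision = mean(truth), recall = 1),
                auc = 0.5))
  }
  P <- sum(truth == 1L); N <- sum(truth == 0L)
  pts <- t(vapply(thr, function(t0) {
    call <- as.integer(s >= t0)
    tp <- sum(call & truth); fp <- sum(call & !truth)
    c(threshold = t0, TPR = tp / P, FPR = fp / N,
      precision = if (tp + fp == 0) 1 else tp / (tp + fp),
      recall = tp / P)
  }, numeric(5)))
  pts <- as.data.frame(pts)
  fpr <- c(0, pts$FPR, 1)
  tpr <- c(0, pts$TPR, 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(points = pts, auc = auc)
}

#' Random Bernoulli baseline predictor
#'
#' Calls each site hydroxylated independently with probability `p`
#' (default 0.5). A useful predictor must clearly beat this baseline to be
#' of practical value for experimental design.
#'
#' @param keys Character vector of site keys to predict.
#' @param p Probability of a positive call.
#' @param seed RNG seed.
#' @return Prediction data.frame with `key`, `call`, `score`, `method`.
#' @export
randomBaseline <- function(keys, p = 0.5, seed = 1L) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  set.seed(seed)
  score <- runif(length(keys))
  data.frame(key = keys, call = as.integer(score < p), score = score,
             method = "random", level = NA_character_,
             stringsAsFactors = FALSE)
}

#' Majority-vote consensus baseline
#'
#' Calls a site positive when strictly more than half of the input methods
#' call it positive; ties are resolved to a negative call, consistent with
#' using the consensus to reduce false positives.
#'
#' @param predictionList List of prediction data.frames (one per method),
#'   each covering the same sites.
#' @return Prediction data.frame with method `"consensus"`.
#' @export
consensusBaseline <- function(predictionList) {
  stopifnot(length(predictionList) >= 1L)
  keys <- sort(unique(predictionList[[1]]$key))
  votes <- vapply(predictionList, function(pr) {
    calls <- setNames(pr$call, pr$key)[keys]
    if (anyNA(calls))
      stop("method '", pr$method[1], "' does not cover every site")
    calls
  }, numeric(length(keys)))
  votes <- matrix(votes, nrow = length(keys))
  frac <- rowMeans(votes)
  data.frame(key = keys, call = as.integer(frac > 0.5), score = frac,
             method = "consensus", level = NA_character_,
             stringsAsFactors = FALSE)
}
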