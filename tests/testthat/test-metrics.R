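test_that("confusion counting is site-centric over replica members only", {
  pos <- sprintf("p%d:1", 1:7); neg <- sprintf("n%d:1", 1:7)
  perfect <- setNames(rep(c(1L, 0L), each = 7), c(pos, neg))
  expect_equal(unclass(confusionCounts(perfect, pos, neg))[1:4],
               c(TP = 7L, FP = 0L, TN = 7L, FN = 0L), ignore_attr = TRUE)
  allPos <- setNames(rep(1L, 14), c(pos, neg))
  expect_equal(confusionCounts(allPos, pos, neg)[["FP"]], 7L)
  expect_equal(confusionCounts(allPos, pos, neg)[["TN"]], 0L)
  inverted <- setNames(rep(c(0L, 1L), each = 7), c(pos, neg))
  cc <- confusionCounts(inverted, pos, neg)
  expect_equal(cc[["TP"]], 0L); expect_equal(cc[["FN"]], 7L)
  expect_equal(cc[["FP"]], 7L); expect_equal(cc[["TN"]], 0L)
  # predictions outside the replica are ignored
  extra <- c(perfect, setNames(1L, "other:9"))
  expect_equal(sum(confusionCounts(extra, pos, neg)), 14)
})

test_that("missing predictions follow the configured policy", {
  pos <- c("p1:1", "p2:1"); neg <- c("n1:1", "n2:1")
  partial <- setNames(c(1L, 1L, 0L), c("p1:1", "p2:1", "n1:1"))
  expect_error(confusionCounts(partial, pos, neg), "no prediction")
  cc <- confusionCounts(partial, pos, neg, missingPolicy = "negative")
  expect_equal(cc[["TN"]], 2L)
  expect_equal(attr(cc, "nMissing"), 1L)
})

test_that("metric formulas match closed-form cases", {
  m <- computeMetrics(c(TP = 50, FP = 0, TN = 50, FN = 0))
  expect_equal(unname(m[c("MCC", "WACC", "F1")]), c(1, 1, 1))
  m2 <- computeMetrics(c(TP = 25, FP = 25, TN = 25, FN = 25))
  expect_equal(m2[["MCC"]], 0)
  expect_equal(m2[["WACC"]], 0.5)
  m3 <- computeMetrics(c(TP = 40, FP = 10, TN = 35, FN = 15))
  expect_equal(unname(m3), unname(metricsOracle(40, 10, 35, 15)))
  expect_error(computeMetrics(c(TP = -1, FP = 0, TN = 1, FN = 0)),
               "negative")
})

test_that("undefined ratios resolve to zero by convention", {
  # no positive calls: PREC and MCC denominators collapse
  m <- computeMetrics(c(TP = 0, FP = 0, TN = 10, FN = 5))
  expect_equal(m[["PREC"]], 0)
  expect_equal(m[["MCC"]], 0)
  expect_equal(m[["Sp"]], 1)
})

test_that("metrics agree with the vector-reconstruction oracle", {
  set.seed(31)
  for (k in 1:300) {
    cc <- sample(0:40, 4, replace = TRUE)
    if (sum(cc) == 0) next
    got <- computeMetrics(c(TP = cc[1], FP = cc[2], TN = cc[3], FN = cc[4]))
    want <- metricsOracle(cc[1], cc[2], cc[3], cc[4])
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("replica aggregation uses sample standard deviation", {
  m <- matrix(rep(c(0.4, 0.6), 3), 2, 3,
              dimnames = list(NULL, c("Sn", "Sp", "MCC")))
  agg <- aggregateMetrics(m)
  expect_equal(agg$mean, rep(0.5, 3))
  expect_equal(agg$sd, rep(sd(c(0.4, 0.6)), 3))
  same <- matrix(0.7, 5, 2, dimnames = list(NULL, c("Sn", "Sp")))
  expect_equal(aggregateMetrics(same)$sd, c(0, 0))
  expect_error(aggregateMetrics(same[1, , drop = FALSE]))
})

test_that("random-baseline WACC spread matches the binomial prediction", {
  set.seed(32)
  k <- 100L   # sites per class per replica
  pos <- sprintf("p%03d:1", 1:k); neg <- sprintf("n%03d:1", 1:k)
  wacc <- vapply(1:1000, function(r) {
    pr <- randomBaseline(c(pos, neg), 0.5, seed = 5000 + r)
    computeMetrics(confusionCounts(pr, pos, neg))[["WACC"]]
  }, numeric(1))
  predicted <- sqrt(0.125 / k)   # sd of (Sn + Sp) / 2 for Bernoulli(0.5)
  expect_gt(sd(wacc), 0.7 * predicted)
  expect_lt(sd(wacc), 1.3 * predicted)
  expect_equal(mean(wacc), 0.5, tolerance = 0.01)
})

test_that("curves behave at the extremes and match pROC on random data", {
  pos <- sprintf("p%d:1", 1:20); neg <- sprintf("n%d:1", 1:20)
  truthScores <- setNames(rep(c(1, 0), each = 20), c(pos, neg))
  expect_equal(predictionCurves(truthScores, pos, neg)$auc, 1)
  set.seed(33)
  s <- setNames(runif(40), c(pos, neg))
  res <- predictionCurves(s, pos, neg)
  expect_equal(predictionCurves(setNames(1 - s, names(s)), pos, neg)$auc,
               1 - res$auc, tolerance = 1e-9)
  flat <- setNames(rep(0.5, 40), c(pos, neg))
  expect_warning(resFlat <- predictionCurves(flat, pos, neg), "identical")
  expect_equal(resFlat$auc, 0.5)
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = rep(c(1, 0), each = 20), predictor = unname(s),
    quiet = TRUE, direction = "<")))
  expect_equal(res$auc, ref, tolerance = 1e-9)
})

test_that("truth-linked scores beat their label permutations on AUC", {
  set.seed(34)
  pos <- sprintf("p%d:1", 1:40); neg <- sprintf("n%d:1", 1:40)
  s <- setNames(c(rnorm(40, 1), rnorm(40, 0)), c(pos, neg))
  aucTrue <- predictionCurves(s, pos, neg)$auc
  aucPerm <- vapply(1:20, function(i) {
    keys <- sample(c(pos, neg))
    predictionCurves(s, keys[1:40], keys[41:80])$auc
  }, numeric(1))
  expect_gt(aucTrue, median(aucPerm))
})

test_that("random baseline respects p at the extremes and in frequency", {
  keys <- sprintf("s%05d:1", 1:10000)
  expect_true(all(randomBaseline(keys, 1, seed = 1)$call == 1L))
  expect_true(all(randomBaseline(keys, 0, seed = 1)$call == 0L))
  frac <- mean(randomBaseline(keys, 0.5, seed = 2)$call)
  expect_gt(frac, 0.48); expect_lt(frac, 0.52)   # binomial 99% interval
  expect_error(randomBaseline(keys, 1.5), "\\[0, 1\\]")
})

test_that("consensus is a strict majority with ties negative", {
  mkPred <- function(calls, m) data.frame(
    key = sprintf("s%d:1", seq_along(calls)), call = calls, method = m)
  cons3 <- consensusBaseline(list(mkPred(c(1, 1), "a"), mkPred(c(1, 0), "b"),
                                  mkPred(c(0, 0), "c")))
  expect_equal(cons3$call, c(1L, 0L))
  cons2 <- consensusBaseline(list(mkPred(1, "a"), mkPred(0, "b")))
  expect_equal(cons2$call, 0L)     # 1 of 2 is a tie: negative
  single <- consensusBaseline(list(mkPred(c(1, 0, 1), "a")))
  expect_equal(single$call, c(1L, 0L, 1L))
  short <- list(mkPred(c(1, 1), "a"),
                data.frame(key = "s1:1", call = 1, method = "b"))
  expect_error(consensusBaseline(short), "cover")
})
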