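test_that("with no incompleteness, observed labels equal true labels", {
  gen <- generateProteome(syntheticConfig(nCollagen = 3L, nOther = 20L,
                                          incompleteness = 0, seed = 61L))
  expect_identical(gen$truth$observedLabel, gen$truth$trueLabel)
  expect_identical(gen$annotations$label, gen$truth$trueLabel)
})

test_that("full Y-hydroxylation marks every Y-position proline positive", {
  cfg <- syntheticConfig(nCollagen = 5L, nOther = 0L,
                         yHydroxylationProb = 1, targetPrevalence = 0.5,
                         seed = 62L)
  gen <- generateProteome(cfg)
  ys <- gen$truth[gen$truth$role == "collagen_Y", ]
  expect_gt(nrow(ys), 0L)
  expect_true(all(ys$trueLabel == "positive"))
  xs <- gen$truth[gen$truth$role == "collagen_X", ]
  expect_true(all(xs$trueLabel == "negative"))
})

test_that("realized prevalence tracks the analytic expectation", {
  gen <- defaultBenchmark()$gen
  ann <- gen$annotations
  p <- expectedPrevalence(gen$config)
  n <- nrow(ann)
  got <- mean(ann$label == "positive")
  expect_lt(abs(got - p), 3 * sqrt(p * (1 - p) / n))
  # and the default configuration targets the ~10% positive-proline rate
  expect_equal(gen$config$targetPrevalence, 0.10)
  expect_lt(abs(p - 0.10), 0.02)
})

test_that("an infeasible prevalence target fails with a diagnostic", {
  expect_error(
    generateProteome(syntheticConfig(targetPrevalence = 0.5)),
    "infeasible")
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- syntheticConfig(nCollagen = 2L, nOther = 10L,
                         targetPrevalence = 0.15, seed = 63L)
  d1 <- tempfile("gen1"); d2 <- tempfile("gen2")
  g1 <- generateProteome(cfg)
  g2 <- generateProteome(cfg)
  writeBenchmarkInputs(g1$proteome, g1$annotations, d1)
  writeBenchmarkInputs(g2$proteome, g2$annotations, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  g3 <- generateProteome(syntheticConfig(nCollagen = 2L, nOther = 10L,
                                         targetPrevalence = 0.15,
                                         seed = 64L))
  expect_false(identical(as.character(proteinSequences(g1$proteome)),
                         as.character(proteinSequences(g3$proteome))))
})

test_that("annotation incompleteness thins positives monotonically", {
  base <- list(nCollagen = 6L, nOther = 60L, seed = 65L)
  observed <- apparentFP <- numeric(0)
  for (h in c(0, 0.2, 0.5)) {
    cfg <- do.call(syntheticConfig, c(base, list(incompleteness = h)))
    gen <- generateProteome(cfg)
    observed[as.character(h)] <- sum(gen$annotations$label == "positive")
    # a truth-perfect predictor's apparent false positives are exactly the
    # unlabeled true positives
    calls <- setNames(as.integer(gen$truth$trueLabel == "positive"),
                      gen$truth$key)
    apparent <- sum(calls == 1L & gen$annotations$label == "negative")
    apparentFP[as.character(h)] <- apparent /
      sum(gen$truth$trueLabel == "positive")
    # thinning consistency: observed positives + thinned = true positives
    expect_equal(sum(gen$annotations$label == "positive") + apparent,
                 sum(gen$truth$trueLabel == "positive"))
  }
  expect_true(all(diff(observed) < 0))
  expect_true(all(diff(apparentFP) > 0))
})

test_that("a pure memorizer is perfect on seen data, blind on novel data", {
  # training = every old-motif window; evaluation = novel-motif windows
  gen <- generateProteome(syntheticConfig(nCollagen = 0L, nOther = 60L,
                                          targetPrevalence = 0.08,
                                          seed = 66L))
  sites <- splitSiteKey(gen$truth$key)
  ws <- siteWindows(gen$proteome, sites)
  keys <- siteKeys(ws)
  oldPos <- gen$truth$key[gen$truth$role == "motif_old" &
                            gen$truth$trueLabel == "positive"]
  novelPos <- gen$truth$key[gen$truth$role == "motif_novel" &
                              gen$truth$trueLabel == "positive"]
  expect_gt(length(oldPos), 5L)
  expect_gt(length(novelPos), 5L)
  pred <- simulatePredictor(ws, oldPos, lambda = 1, epsilon = 0,
                            seed = 67L)
  calls <- setNames(pred$call, pred$key)
  expect_true(all(calls[oldPos] == 1L))       # memorization of seen sites
  expect_true(all(calls[novelPos] == 0L))     # blind to the novel motif
  # with noise off and lambda 1, scores equal the similarity propensity
  expect_true(all(pred$score[match(oldPos, pred$key)] >= 0.9))
})

test_that("the generalizing component recognizes the true motif", {
  gen <- generateProteome(syntheticConfig(nCollagen = 0L, nOther = 40L,
                                          targetPrevalence = 0.08,
                                          seed = 68L))
  ws <- siteWindows(gen$proteome, splitSiteKey(gen$truth$key))
  oldPos <- gen$truth$key[gen$truth$role == "motif_old" &
                            gen$truth$trueLabel == "positive"]
  pred <- simulatePredictor(ws, oldPos[1], lambda = 0, g = 1, epsilon = 0,
                            motif = gen$config$oldMotif, seed = 69L)
  calls <- setNames(pred$call, pred$key)
  motifKeys <- gen$truth$key[gen$truth$role == "motif_old"]
  expect_true(all(calls[motifKeys] == 1L))
  expect_error(simulatePredictor(ws, oldPos[1], lambda = 0, g = 1),
               "motif")
  expect_error(simulatePredictor(ws, oldPos[1], tau = 40),
               "\\[0, 1\\]")
})
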