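# helper: a SiteClustering built directly from an id map
manualClustering <- function(ids) {
  new("SiteClustering", keys = names(ids),
      cluster = as.integer(factor(ids, levels = unique(ids))),
      merge = matrix(0L, 0L, 2L), height = numeric(0), cutHeight = 1)
}

annRows <- function(keys, labels, sources = "Literature",
                    confidence = NA_real_) {
  sk <- splitSiteKey(keys)
  data.frame(protein_id = sk$protein_id, position = sk$position,
             residue = "P", label = labels,
             source = rep_len(sources, length(keys)),
             confidence = rep_len(confidence, length(keys)),
             collagen = FALSE, evidence_code = NA_character_, key = keys,
             stringsAsFactors = FALSE)
}

test_that("negatives sharing a cluster with a positive are removed", {
  cl <- manualClustering(c("p:1" = 1, "n:1" = 1, "n:2" = 2))
  ann <- annRows(c("p:1", "n:1", "n:2"),
                 c("positive", "negative", "negative"))
  pool <- filterNegatives(cl, ann)
  expect_equal(as.character(pool), "n:2")
  expect_equal(attr(pool, "removed"), "n:1")
  expect_equal(attr(pool, "nRemoved"), 1L)
})

test_that("negative filtering degenerate cases behave as specified", {
  # no positives: pool is every negative
  cl <- manualClustering(c("n:1" = 1, "n:2" = 2))
  ann <- annRows(c("n:1", "n:2"), "negative")
  expect_equal(as.character(filterNegatives(cl, ann)), c("n:1", "n:2"))
  # everything in one positive cluster: empty pool with a warning
  cl2 <- manualClustering(c("p:1" = 1, "n:1" = 1, "n:2" = 1))
  ann2 <- annRows(c("p:1", "n:1", "n:2"),
                  c("positive", "negative", "negative"))
  expect_warning(pool2 <- filterNegatives(cl2, ann2), "empty")
  expect_equal(length(pool2), 0L)
  # unclustered site is a hard error naming it
  expect_error(filterNegatives(cl, annRows("n:9", "negative")), "n:9")
})

test_that("splits partition positives by source and collagen flag", {
  keys <- paste0(c("colA", "colA", "a", "b", "c", "d", "e", "f"), ":",
                 c(3, 6, 10, 10, 10, 10, 10, 10))
  ann <- annRows(keys,
                 c(rep("positive", 5), rep("negative", 3)),
                 sources = c("Literature", "MS-Kim", "Literature",
                             "Literature", "MS-Kim", "MS-Kim", "MS-Kim",
                             "MS-Kim"))
  cl <- manualClustering(setNames(seq_along(keys), keys))
  prot <- Proteome(setNames(rep(strrep("AP", 10), 7),
                            c("colA", "a", "b", "c", "d", "e", "f")),
                   collagen = c(colA = TRUE))
  sp <- buildSplits(ann, cl, prot)
  expect_setequal(splitPositives(sp, "Literature"),
                  c("colA:3", "a:10", "b:10"))
  expect_setequal(splitPositives(sp, "MS"), c("colA:6", "c:10"))
  expect_setequal(splitPositives(sp, "MS-Kim"), c("colA:6", "c:10"))
  expect_equal(splitPositives(sp, "MS-HeLa"), character(0))
  expect_setequal(splitPositives(sp, "Collagen"), c("colA:3", "colA:6"))
  expect_equal(splitPositives(sp, "Literature-collagen"), "colA:3")
  expect_equal(splitPositives(sp, "MS-collagen"), "colA:6")
  expect_setequal(splitPositives(sp, "Literature-noncollagen"),
                  c("a:10", "b:10"))
  expect_setequal(negativePool(sp), c("d:10", "e:10", "f:10"))
  expect_error(buildSplits(annRows("a:10", "positive", "MS-Weird"), cl,
                           prot), "unknown source")
})

test_that("sub-threshold MS-HeLa positives are excluded from every split", {
  keys <- c("a:2", "b:2", "c:2", "d:2")
  ann <- annRows(keys, c("positive", "positive", "negative", "negative"),
                 sources = c("MS-HeLa", "MS-HeLa", "MS-Kim", "MS-Kim"),
                 confidence = c(0.5, 0.95, NA, NA))
  cl <- manualClustering(setNames(seq_along(keys), keys))
  prot <- Proteome(setNames(rep("APA", 4), c("a", "b", "c", "d")))
  sp <- buildSplits(ann, cl, prot)
  expect_equal(splitPositives(sp, "MS-HeLa"), "b:2")
  expect_equal(splitPositives(sp, "MS"), "b:2")
  for (nm in splitNames(sp))
    expect_false("a:2" %in% splitPositives(sp, nm))
  expect_equal(sp@meta$nLowConfidenceDropped, 1L)
})

test_that("a site reported by both MS sources appears once in MS", {
  keys <- c("a:2", "a:2", "n:2")
  ann <- annRows(c("a:2", "n:2"), c("positive", "negative"),
                 sources = c("MS-Kim", "MS-Kim"))
  ann <- rbind(ann, annRows("a:2", "positive", "MS-HeLa", 0.99))
  cl <- manualClustering(c("a:2" = 1, "n:2" = 2))
  prot <- Proteome(setNames(rep("APA", 2), c("a", "n")))
  sp <- buildSplits(ann, cl, prot)
  expect_equal(splitPositives(sp, "MS"), "a:2")
  expect_equal(splitPositives(sp, "MS-HeLa"), "a:2")
  expect_equal(splitPositives(sp, "MS-Kim"), "a:2")
})

test_that("replica sets are balanced, without replacement, reproducible", {
  keys <- c(sprintf("p%02d:5", 1:10), sprintf("n%02d:5", 1:40))
  ann <- annRows(keys, rep(c("positive", "negative"), c(10, 40)),
                 sources = "MS-Kim")
  cl <- manualClustering(setNames(seq_along(keys), keys))
  prot <- Proteome(setNames(rep("AAAAPAA", 50), splitSiteKey(keys)$protein_id))
  sp <- buildSplits(ann, cl, prot)
  reps <- makeReplicas(sp, "MS", nReplicas = 30L, frac = 0.7, seed = 99L)
  expect_equal(nReplicas(reps), 30L)
  for (r in seq_len(30L)) {
    p <- replicaPositives(reps, r); n <- replicaNegatives(reps, r)
    expect_equal(length(p), 7L)          # floor(0.7 * 10)
    expect_equal(length(n), 7L)          # exactly balanced
    expect_false(anyDuplicated(c(p, n)) > 0)
    expect_true(all(n %in% negativePool(sp)))
    expect_true(all(p %in% splitPositives(sp, "MS")))
  }
  # same seed: identical; different seed: different with high probability
  reps2 <- makeReplicas(sp, "MS", nReplicas = 30L, frac = 0.7, seed = 99L)
  expect_identical(reps@positives, reps2@positives)
  expect_identical(reps@negatives, reps2@negatives)
  reps3 <- makeReplicas(sp, "MS", nReplicas = 30L, frac = 0.7, seed = 100L)
  expect_false(identical(reps@negatives, reps3@negatives))
  # pool too small is a clear error
  tiny <- new("BenchmarkSplits",
              positives = list(MS = sprintf("p%02d:5", 1:10)),
              negativePool = c("n01:5", "n02:5"), meta = list())
  expect_error(makeReplicas(tiny, "MS", 5L), "pool too small")
})
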