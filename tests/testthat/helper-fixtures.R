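# Shared fixtures and independent oracles for the test suite.

AA20_TEST <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# --- tiny hand-built proteome on disk -------------------------------------

writeTinyInputs <- function(dir = tempfile("tiny")) {
  dir.create(dir)
  fasta <- file.path(dir, "prot.fasta")
  writeLines(c(">PA", "MKTPAAGPLLWP", ">PB", "PGGAPPA"), fasta)
  ann <- file.path(dir, "ann.tsv")
  writeLines(c(
    "protein_id\tposition\tresidue\tlabel\tsource\tconfidence\tcollagen\tevidence_code",
    "PA\t4\tP\tpositive\tLiterature\t\t0\tECO:0000269",
    "PA\t8\tP\tnegative\tMS-Kim\t\t0\t",
    "PB\t5\tP\tpositive\tMS-HeLa\t0.95\t1\t"), ann)
  tracks <- file.path(dir, "tracks.tsv")
  writeLines(c("protein_id\tfeature\ttrack",
               "PA\tdisorder\t000111110000",
               "PB\tdisorder\t1111111"), tracks)
  list(dir = dir, fasta = fasta, ann = ann, tracks = tracks)
}

# --- random window generator ----------------------------------------------

randomWindows <- function(n, W = 7L, gapProb = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  wins <- vapply(seq_len(n), function(i) {
    chars <- sample(AA20_TEST, W, replace = TRUE)
    half <- (W - 1L) %/% 2L
    # occasionally pad one terminus, as terminal sites are
    nPad <- sample(0:half, 1L, prob = c(1 - gapProb, rep(gapProb / half, half)))
    if (nPad > 0L && runif(1) < 0.5) chars[seq_len(nPad)] <- "-"
    else if (nPad > 0L) chars[(W - nPad + 1L):W] <- "-"
    chars[half + 1L] <- sample(AA20_TEST, 1L)
    paste(chars, collapse = "")
  }, character(1))
  new("SiteWindowSet", windows = wins,
      proteinID = sprintf("RND%03d", seq_len(n)),
      position = rep(50L, n), W = as.integer(W))
}

# --- independent brute-force average-linkage oracle ------------------------
# Recomputes every inter-cluster average distance from the raw matrix at
# each step (no Lance-Williams update); merges while the minimal average
# distance is <= cutHeight, breaking ties on the lexicographically smallest
# (min representative, max representative) pair.

bruteAverageLinkage <- function(D, cutHeight, tol = 1e-9) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    bestVal <- Inf
    bestPair <- NULL
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      avg <- mean(D[clusters[[a]], clusters[[b]]])
      ra <- min(clusters[[a]]); rb <- min(clusters[[b]])
      reps <- c(min(ra, rb), max(ra, rb))
      if (avg < bestVal - tol) {
        bestVal <- avg
        bestPair <- list(a = a, b = b, reps = reps)
      } else if (avg <= bestVal + tol) {
        bestVal <- min(bestVal, avg)
        if (reps[1] < bestPair$reps[1] ||
            (reps[1] == bestPair$reps[1] && reps[2] < bestPair$reps[2]))
          bestPair <- list(a = a, b = b, reps = reps)
      }
    }
    if (bestVal > cutHeight) break
    merged <- sort(c(clusters[[bestPair$a]], clusters[[bestPair$b]]))
    clusters <- clusters[-c(bestPair$a, bestPair$b)]
    clusters[[length(clusters) + 1L]] <- merged
  }
  out <- integer(n)
  for (ci in seq_along(clusters)) out[clusters[[ci]]] <- ci
  out
}

# canonical form of a partition, for comparing clusterings up to relabelling
canonicalPartition <- function(ids) {
  as.integer(factor(ids, levels = unique(ids)))
}

samePartition <- function(a, b) {
  identical(canonicalPartition(a), canonicalPartition(b))
}

# --- independent metric oracle ---------------------------------------------
# Reconstructs the 0/1 prediction and truth vectors from the confusion
# counts and computes each metric from first principles (MCC as the Pearson
# correlation of the two binary vectors); undefined values map to 0.

metricsOracle <- function(tp, fp, tn, fn) {
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  zeroIfBad <- function(x) if (!is.finite(x)) 0 else x
  sn <- zeroIfBad(mean(pred[truth == 1]))
  sp <- zeroIfBad(mean(1 - pred[truth == 0]))
  prec <- zeroIfBad(mean(truth[pred == 1]))
  f1 <- zeroIfBad(2 * prec * sn / (prec + sn))
  mcc <- if (stats::sd(pred) == 0 || stats::sd(truth) == 0) 0 else
    stats::cor(pred, truth)
  c(Sn = sn, Sp = sp, WACC = (sn + sp) / 2, F1 = f1, PREC = prec, MCC = mcc)
}

# --- memoised default synthetic benchmark ----------------------------------
# Built once per test run at the generator's default study conditions.

.benchmarkCache <- new.env(parent = emptyenv())

defaultBenchmark <- function() {
  if (!is.null(.benchmarkCache$bm)) return(.benchmarkCache$bm)
  gen <- generateProteome(syntheticConfig())
  sites <- splitSiteKey(unique(gen$annotations$key))
  windows <- siteWindows(gen$proteome, sites)
  S <- siteScoreMatrix(windows)
  dmat <- scoreToDistance(S)
  clustering <- clusterSites(dmat)
  splits <- buildSplits(gen$annotations, clustering, gen$proteome)
  .benchmarkCache$bm <- list(gen = gen, windows = windows, dmat = dmat,
                             clustering = clustering, splits = splits)
  .benchmarkCache$bm
}

defaultReplicas <- function(split, nReplicas = 1000L, seed = 7L) {
  key <- paste0("reps_", split, "_", nReplicas, "_", seed)
  if (is.null(.benchmarkCache[[key]])) {
    .benchmarkCache[[key]] <- makeReplicas(defaultBenchmark()$splits, split,
                                           nReplicas, seed = seed)
  }
  .benchmarkCache[[key]]
}
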