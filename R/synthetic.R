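# Approximate vertebrate proteome residue composition, with the proline
# frequency set so that the default benchmark lands near the ~10% fraction
# of prolines carrying a hydroxylation annotation.
DEFAULT_BACKGROUND <- c(
  A = 0.0790, R = 0.0555, N = 0.0400, D = 0.0540, C = 0.0135,
  Q = 0.0395, E = 0.0675, G = 0.0705, H = 0.0225, I = 0.0590,
  L = 0.0960, K = 0.0580, M = 0.0240, F = 0.0385, P = 0.0650,
  S = 0.0660, T = 0.0535, W = 0.0110, Y = 0.0290, V = 0.0685)

#' Configuration of the synthetic benchmark generator
#'
#' The generator emulates the statistical structure of a hydroxylation
#' benchmark: collagen-like proteins made of (X-Y-Gly) triple-helix repeats
#' with hydroxylation concentrated on Y-position prolines, non-collagen
#' proteins carrying sparse motif-borne signalling sites inside
#' disorder-marked intervals, an overall positive-proline prevalence of
#' roughly 10%, per-site confidence scores, and configurable annotation
#' incompleteness (true positives that appear as negatives).
#'
#' Two distinct signalling motifs are planted: an "old" motif whose
#' positives are tagged `Literature` (the training-era evidence) and a
#' "novel" motif whose positives are tagged as mass-spectrometry sources,
#' so that train/test experiments can expose a memorizing predictor.
#'
#' @param nCollagen,nOther Protein counts.
#' @param collagenRepeats Number of (X-Y-G) triplets per collagen protein.
#' @param collagenFlank Residues of background sequence on each side of the
#'   repeat region.
#' @param otherLengthRange Length range (uniform) of non-collagen proteins.
#' @param pX,pY Probability that the X / Y triplet position is a proline
#'   (0.28 and 0.38: the observed rates in collagen motifs).
#' @param yHydroxylationProb Probability that a Y-position proline is a true
#'   positive.
#' @param oldMotif,novelMotif 6-residue signalling motifs, each containing
#'   exactly one proline.
#' @param motifRate Poisson mean of occurrences per non-collagen protein,
#'   for each motif.
#' @param motifPositiveProb Probability that a motif proline is a true
#'   positive.
#' @param background Named residue frequency vector for background sequence.
#' @param incompleteness Fraction `h` in `[0, 1)` of true positives left
#'   unlabeled (they appear as negatives in the annotations; the truth
#'   manifest keeps the real labels).
#' @param targetPrevalence Intended fraction of prolines that are true
#'   positives (diagnostic; generation fails if the configuration cannot
#'   come close).
#' @param seed Master seed.
#' @return A classed list of generator settings.
#' @export
syntheticConfig <- function(nCollagen = 12L, nOther = 150L,
                            collagenRepeats = 40L, collagenFlank = 20L,
                            otherLengthRange = c(200L, 320L),
                            pX = 0.28, pY = 0.38,
                            yHydroxylationProb = 0.85,
                            oldMotif = "LAPYNT", novelMotif = "WRPCFD",
                            motifRate = 0.7, motifPositiveProb = 0.75,
                            background = DEFAULT_BACKGROUND,
                            incompleteness = 0,
                            targetPrevalence = 0.10, seed = 42L) {
  stopifnot(nCollagen >= 0, nOther >= 0,
            pX >= 0, pX <= 1, pY >= 0, pY <= 1,
            yHydroxylationProb >= 0, yHydroxylationProb <= 1,
            motifPositiveProb >= 0, motifPositiveProb <= 1,
            incompleteness >= 0, incompleteness < 1)
  for (m in c(oldMotif, novelMotif)) {
    ch <- strsplit(m, "")[[1]]
    if (length(ch) != 6L || !all(ch %in% AA20) || sum(ch == "P") != 1L)
      stop("motif '", m, "' must be 6 canonical residues with exactly one ",
           "proline")
  }
  structure(list(nCollagen = nCollagen, nOther = nOther,
                 collagenRepeats = collagenRepeats,
                 collagenFlank = collagenFlank,
                 otherLengthRange = otherLengthRange, pX = pX, pY = pY,
                 yHydroxylationProb = yHydroxylationProb,
                 oldMotif = oldMotif, novelMotif = novelMotif,
                 motifRate = motifRate,
                 motifPositiveProb = motifPositiveProb,
                 background = background[AA20] / sum(background[AA20]),
                 incompleteness = incompleteness,
                 targetPrevalence = targetPrevalence, seed = seed),
            class = "SyntheticConfig")
}

#' Analytic expected positive-proline prevalence of a configuration
#'
#' @param cfg A [syntheticConfig].
#' @return Expected fraction of prolines that are true positives.
#' @export
expectedPrevalence <- function(cfg) {
  bgP <- cfg$background[["P"]]
  colP <- 2 * cfg$collagenFlank * bgP + cfg$collagenRepeats * (cfg$pX + cfg$pY)
  colPos <- cfg$collagenRepeats * cfg$pY * cfg$yHydroxylationProb
  meanLen <- mean(cfg$otherLengthRange)
  nMotif <- 2 * cfg$motifRate
  othP <- meanLen * bgP + nMotif * (1 - 6 * bgP)
  othPos <- nMotif * cfg$motifPositiveProb
  (cfg$nCollagen * colPos + cfg$nOther * othPos) /
    (cfg$nCollagen * colP + cfg$nOther * othP)
}

# Non-proline residue usage at the X and Y positions of the collagen
# triple-helix repeat: a narrow pool dominated by alanine, so that repeat
# windows from different proteins stay mutually similar (real collagen
# sites collapse into very few sequence clusters).
COLLAGEN_X_POOL <- c(A = 0.45, L = 0.15, E = 0.15, S = 0.15, V = 0.10)
COLLAGEN_Y_POOL <- c(A = 0.35, R = 0.20, K = 0.20, Q = 0.15, T = 0.10)

samplePool <- function(n, pool) {
  sample(names(pool), n, replace = TRUE, prob = pool)
}

sampleBackground <- function(n, background) {
  if (!n) return(character(0))
  sample(AA20, n, replace = TRUE, prob = background)
}

#' Generate a synthetic benchmark proteome
#'
#' Draws protein sequences, true site labels, observed annotations (true
#' labels thinned by the incompleteness fraction), source tags, confidence
#' scores and feature tracks, all reproducible from the config seed. A
#' truth manifest with the unthinned labels is returned separately and is
#' never consumed by the benchmark pipeline itself.
#'
#' @param cfg A [syntheticConfig].
#' @return A list with `proteome` ([Proteome-class]), `annotations`
#'   (observed annotation data.frame, one row per candidate proline),
#'   `truth` (manifest data.frame with `role` and `trueLabel` columns) and
#'   `config`.
#' @export
generateProteome <- function(cfg = syntheticConfig()) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  exp_ <- expectedPrevalence(cfg)
  if (abs(exp_ - cfg$targetPrevalence) > 0.05)
    stop(sprintf(paste0("configuration infeasible: expected positive-proline",
                        " prevalence %.3f is far from target %.3f"),
                 exp_, cfg$targetPrevalence))
  set.seed(deriveSeed(cfg$seed, 0L))
  seqs <- character(0)
  collagen <- logical(0)
  tracks <- list(disorder = list(), helix = list(), sheet = list(),
                 low_complexity = list())
  truthRows <- list()

  addTruth <- function(id, pos, role, true) {
    truthRows[[length(truthRows) + 1L]] <<-
      data.frame(protein_id = id, position = pos, role = role,
                 trueLabel = true, stringsAsFactors = FALSE)
  }

  for (i in seq_len(cfg$nCollagen)) {
    id <- sprintf("COL%04d", i)
    flank1 <- sampleBackground(cfg$collagenFlank, cfg$background)
    flank2 <- sampleBackground(cfg$collagenFlank, cfg$background)
    xs <- ifelse(runif(cfg$collagenRepeats) < cfg$pX, "P",
                 samplePool(cfg$collagenRepeats, COLLAGEN_X_POOL))
    ys <- ifelse(runif(cfg$collagenRepeats) < cfg$pY, "P",
                 samplePool(cfg$collagenRepeats, COLLAGEN_Y_POOL))
    triplets <- as.vector(rbind(xs, ys, "G"))
    chars <- c(flank1, triplets, flank2)
    seqs[id] <- paste(chars, collapse = "")
    collagen[id] <- TRUE
    L <- length(chars)
    repStart <- cfg$collagenFlank + 1L
    repEnd <- cfg$collagenFlank + 3L * cfg$collagenRepeats
    lc <- integer(L); lc[repStart:repEnd] <- 1L
    tracks$low_complexity[[id]] <- lc
    tracks$disorder[[id]] <- integer(L)
    tracks$helix[[id]] <- integer(L)
    tracks$sheet[[id]] <- integer(L)
    for (r in seq_len(cfg$collagenRepeats)) {
      xPos <- cfg$collagenFlank + 3L * (r - 1L) + 1L
      yPos <- xPos + 1L
      if (xs[r] == "P") addTruth(id, xPos, "collagen_X", "negative")
      if (ys[r] == "P")
        addTruth(id, yPos, "collagen_Y",
                 if (runif(1) < cfg$yHydroxylationProb) "positive"
                 else "negative")
    }
    flankP <- which(chars == "P")
    flankP <- flankP[flankP < repStart | flankP > repEnd]
    for (p in flankP) addTruth(id, p, "background", "negative")
  }

  for (i in seq_len(cfg$nOther)) {
    id <- sprintf("PRT%04d", i)
    L <- sample(cfg$otherLengthRange[1]:cfg$otherLengthRange[2], 1L)
    chars <- sampleBackground(L, cfg$background)
    disorder <- integer(L)
    motifAt <- list()
    for (motifName in c("old", "novel")) {
      motif <- if (motifName == "old") cfg$oldMotif else cfg$novelMotif
      k <- rpois(1L, cfg$motifRate)
      mlen <- nchar(motif)
      for (j in seq_len(k)) {
        # non-overlapping placement, away from the termini so the motif is
        # fully inside the sequence
        free <- setdiff(seq(10L, L - mlen - 10L),
                        unlist(lapply(motifAt, function(s)
                          (s - mlen):(s + mlen))))
        if (!length(free)) next
        start <- if (length(free) == 1L) free else sample(free, 1L)
        motifAt[[length(motifAt) + 1L]] <- start
        chars[start:(start + mlen - 1L)] <- strsplit(motif, "")[[1]]
        pPos <- start + which(strsplit(motif, "")[[1]] == "P") - 1L
        lab <- if (runif(1) < cfg$motifPositiveProb) "positive" else "negative"
        addTruth(id, pPos, paste0("motif_", motifName), lab)
        dStart <- max(1L, start - 10L)
        dEnd <- min(L, start + mlen + 9L)
        disorder[dStart:dEnd] <- 1L
      }
    }
    seqs[id] <- paste(chars, collapse = "")
    collagen[id] <- FALSE
    helix <- integer(L); sheet <- integer(L)
    # a couple of arbitrary secondary-structure segments for content stats
    hs <- sample(seq_len(max(L - 30L, 1L)), 2L)
    helix[hs[1]:(hs[1] + 14L)] <- 1L
    sheet[hs[2]:(hs[2] + 9L)] <- 1L
    helix[disorder == 1L] <- 0L; sheet[disorder == 1L] <- 0L
    tracks$disorder[[id]] <- disorder
    tracks$helix[[id]] <- helix
    tracks$sheet[[id]] <- sheet
    tracks$low_complexity[[id]] <- integer(L)
    claimed <- which(chars == "P")
    motifP <- unlist(lapply(motifAt, function(s) {
      within <- s:(s + 5L)
      within[chars[within] == "P"]
    }))
    for (p in setdiff(claimed, motifP))
      addTruth(id, p, "background", "negative")
  }

  truth <- do.call(rbind, truthRows)
  truth$key <- makeSiteKey(truth$protein_id, truth$position)

  # observed labels: thin true positives by the incompleteness fraction
  isPos <- truth$trueLabel == "positive"
  thin <- isPos & runif(nrow(truth)) < cfg$incompleteness
  truth$observedLabel <- ifelse(isPos & !thin, "positive", "negative")

  # source tags and confidence for observed positives
  truth$source <- "MS-Kim"
  truth$confidence <- NA_real_
  truth$evidence_code <- NA_character_
  obsPos <- which(truth$observedLabel == "positive")
  for (j in obsPos) {
    role <- truth$role[j]
    src <- if (role == "motif_old") {
      "Literature"
    } else if (role == "motif_novel") {
      sample(c("MS-HeLa", "MS-Kim"), 1L, prob = c(0.3, 0.7))
    } else {
      sample(c("Literature", "MS-HeLa", "MS-Kim"), 1L,
             prob = c(0.5, 0.15, 0.35))
    }
    truth$source[j] <- src
    truth$confidence[j] <- switch(src,
      "Literature" = NA_real_,
      "MS-HeLa" = rbeta(1L, 5, 1),
      "MS-Kim" = rbeta(1L, 9, 1))
    if (src == "Literature") truth$evidence_code[j] <- "ECO:0000269"
  }

  proteome <- Proteome(seqs, collagen = collagen, tracks = tracks)
  annotations <- data.frame(
    protein_id = truth$protein_id, position = truth$position,
    residue = "P", label = truth$observedLabel, source = truth$source,
    confidence = truth$confidence,
    collagen = collagen[truth$protein_id],
    evidence_code = truth$evidence_code, key = truth$key,
    stringsAsFactors = FALSE)
  rownames(annotations) <- NULL

  list(proteome = proteome, annotations = annotations, truth = truth,
       config = cfg)
}

#' Simulate a (possibly memorizing) site predictor
#'
#' Embodies the failure mode of pattern-memorizing machine-learning
#' predictors: a site is recognized with weight `lambda` when its window is
#' sufficiently similar to some training-positive window (relative
#' similarity `score / self-score >= tau`), and with weight `1 - lambda` a
#' generalizing rule fires with probability `g` when the true signalling
#' motif is present. Each call is then flipped with noise probability
#' `epsilon`. Scores expose the underlying propensity.
#'
#' @param windowSet [SiteWindowSet-class] of the sites to predict.
#' @param trainingKeys Site keys of the training positives (must be present
#'   in `windowSet` or supplied via `trainingWindows`).
#' @param trainingWindows Optional [SiteWindowSet-class] holding the
#'   training-positive windows.
#' @param lambda Memorization weight in `[0, 1]`.
#' @param tau Relative similarity threshold in `[0, 1]` (default 0.9).
#' @param g Generalization probability in `[0, 1]`.
#' @param motif Motif string the generalizing rule recognizes (required when
#'   `g > 0`).
#' @param epsilon Per-call flip noise in `[0, 1]`.
#' @param seed RNG seed.
#' @param params [ScoringParams-class] for the similarity computation.
#' @param method Method label in the output table.
#' @return Prediction data.frame with `key`, `call`, `score`, `method`.
#' @export
simulatePredictor <- function(windowSet, trainingKeys,
                              trainingWindows = NULL,
                              lambda = 1, tau = 0.9, g = 0, motif = NULL,
                              epsilon = 0.02, seed = 1L,
                              params = ScoringParams(),
                              method = "simulated") {
  stopifnot(is(windowSet, "SiteWindowSet"),
            lambda >= 0, lambda <= 1, g >= 0, g <= 1,
            epsilon >= 0, epsilon <= 1)
  if (tau < 0 || tau > 1)
    stop("tau is a relative similarity threshold and must lie in [0, 1]")
  if (g > 0 && is.null(motif))
    stop("a motif must be given when the generalization weight g is > 0")
  keys <- siteKeys(windowSet)
  if (is.null(trainingWindows)) {
    idx <- match(trainingKeys, keys)
    if (anyNA(idx))
      stop("training key '", trainingKeys[which(is.na(idx))[1]],
           "' not present in windowSet")
    trainingWindows <- windowSet[idx]
  }
  cross <- crossScoreMatrix(windowSet, trainingWindows, params)
  maxScore <- apply(cross, 1L, max)
  self <- vapply(windowSet@windows, function(w) siteScore(w, w, params),
                 numeric(1), USE.NAMES = FALSE)
  simRatio <- ifelse(self > 0, pmax(0, pmin(1, maxScore / self)),
                     as.numeric(keys %in% trainingKeys))
  memorized <- simRatio >= tau
  motifPresent <- if (is.null(motif)) rep(FALSE, length(keys)) else
    grepl(motif, windowSet@windows, fixed = TRUE)
  propensity <- lambda * as.numeric(memorized) +
    (1 - lambda) * g * as.numeric(motifPresent)
  set.seed(seed)
  call <- as.integer(runif(length(keys)) < propensity)
  flip <- runif(length(keys)) < epsilon
  call[flip] <- 1L - call[flip]
  data.frame(key = keys, call = call,
             score = lambda * simRatio +
               (1 - lambda) * g * as.numeric(motifPresent),
             method = method, level = NA_character_,
             stringsAsFactors = FALSE)
}

#' @rdname SiteWindowSet-class
#' @param i Index vector.
#' @param x A `SiteWindowSet`.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "SiteWindowSet", function(x, i, j, ..., drop = FALSE) {
  new("SiteWindowSet", windows = x@windows[i], proteinID = x@proteinID[i],
      position = x@position[i], W = x@W)
})
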