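#' Background symbol frequencies of a proteome
#'
#' Residue composition of the full proteome over the 20 canonical letters,
#' rescaled to leave a small probability mass for the gap symbol (windows at
#' sequence ends carry gaps, and the profiles treat the gap as a 21st
#' emission symbol).
#'
#' @param proteome A [Proteome-class].
#' @param gapFreq Background frequency assigned to the gap symbol
#'   (default 0.01).
#' @return Named numeric vector of 21 frequencies summing to 1.
#' @export
backgroundFrequencies <- function(proteome, gapFreq = 0.01) {
  stopifnot(is(proteome, "Proteome"), gapFreq > 0, gapFreq < 1)
  chars <- strsplit(paste(as.character(proteome@sequences), collapse = ""),
                    "", fixed = TRUE)[[1]]
  counts <- table(factor(chars[chars %in% AA20], levels = AA20))
  if (sum(counts) == 0) stop("proteome contains no canonical residues")
  freq <- as.numeric(counts) / sum(counts) * (1 - gapFreq)
  setNames(c(freq, gapFreq), ALPHABET21)
}

#' Build the cluster-seeded profile database
#'
#' One positional profile per positive cluster (any cluster containing at
#' least one positive site), built from all member windows of that cluster —
#' negative sites inside a positive cluster contribute to its profile, just
#' as they are excluded from the negative pool. Column counts over the 21
#' symbols are smoothed with `pseudocount * background` and converted to
#' log2 odds against the background.
#'
#' @param clustering A [SiteClustering-class].
#' @param windowSet A [SiteWindowSet-class] covering the clustered sites.
#' @param annotations Annotation data.frame (for positive labels).
#' @param background 21-symbol background vector from
#'   [backgroundFrequencies].
#' @param pseudocount Smoothing weight (default 0.02; a small pseudocount
#'   keeps single-seed profiles sharp so that seed members score far into
#'   the null tail).
#' @param evalueMax E-value threshold for positive calls (default 1.0; very
#'   permissive because 13-column sites are short compared to full domains).
#' @return An uncalibrated [ProfileDB-class].
#' @export
buildProfiles <- function(clustering, windowSet, annotations, background,
                          pseudocount = 0.02, evalueMax = 1.0) {
  stopifnot(is(clustering, "SiteClustering"), is(windowSet, "SiteWindowSet"))
  lab <- siteLabels(annotations)
  cid <- clusterIDs(clustering)
  posClusters <- sort(unique(cid[lab$positives]))
  if (!length(posClusters)) stop("no positive clusters: cannot seed profiles")
  W <- windowWidth(windowSet)
  wins <- windowStrings(windowSet)
  enc <- encodeWindows(as.character(wins), W)
  rownames(enc) <- names(wins)
  bg <- background[ALPHABET21]
  profiles <- list()
  seedKeys <- list()
  for (cl in posClusters) {
    members <- names(cid)[cid == cl]
    members <- members[members %in% rownames(enc)]
    if (!length(members)) stop("cluster ", cl, " has no windows")
    sub <- enc[members, , drop = FALSE]
    counts <- vapply(seq_len(W), function(cc)
      tabulate(sub[, cc], nbins = 21L), integer(21L))
    freq <- t(counts + pseudocount * bg) / (nrow(sub) + pseudocount)
    profiles[[as.character(cl)]] <- log2(freq / rep(bg, each = W))
    seedKeys[[as.character(cl)]] <- members
  }
  new("ProfileDB", profiles = profiles, seedKeys = seedKeys,
      background = bg, W = W, nullLocation = NA_real_, nullScale = NA_real_,
      evalueMax = evalueMax)
}

# n x nProfiles matrix of profile scores for encoded windows
profileScores <- function(enc, db) {
  vapply(db@profiles, function(p) {
    s <- numeric(nrow(enc))
    for (cc in seq_len(db@W)) s <- s + p[cc, enc[, cc]]
    s
  }, numeric(nrow(enc)))
}

#' Calibrate the null score distribution of a profile database
#'
#' Samples `nNull` windows i.i.d. from the background residue frequencies,
#' scores each against every profile, and fits a Gumbel (extreme-value)
#' location/scale to the pooled score distribution by method of moments.
#' E-values are then `databaseSize * P_null(score >= s)` under that fit.
#'
#' @param db A [ProfileDB-class].
#' @param nNull Number of null windows (default 10000; fewer than 1000
#'   triggers a warning).
#' @param seed RNG seed; the same seed reproduces the same parameters.
#' @return The calibrated [ProfileDB-class].
#' @export
calibrateNull <- function(db, nNull = 10000L, seed = 1L) {
  stopifnot(is(db, "ProfileDB"))
  if (nNull < 1000L)
    warning("nNull < 1000: null-model fit may be unstable")
  set.seed(seed)
  aaBg <- db@background[AA20] / sum(db@background[AA20])
  enc <- matrix(sample(seq_along(AA20), nNull * db@W, replace = TRUE,
                       prob = aaBg), nrow = nNull)
  pooled <- as.numeric(profileScores(enc, db))
  scale <- stats::sd(pooled) * sqrt(6) / pi
  loc <- mean(pooled) - 0.5772156649 * scale
  db@nullLocation <- loc
  db@nullScale <- scale
  db
}

gumbelSF <- function(s, loc, scale) {
  -expm1(-exp(-(s - loc) / scale))
}

#' Scan site windows against the profile database
#'
#' Each window is scored against every profile (columnwise sum of log-odds);
#' the best score is converted to an E-value under the calibrated null and
#' a site is called positive when its E-value is at most `evalueMax`.
#'
#' @param windowSet A [SiteWindowSet-class].
#' @param db A calibrated [ProfileDB-class] (see [calibrateNull]).
#' @param evalueMax Override of the database's E-value threshold.
#' @param databaseSize Override of the E-value scaling (defaults to the
#'   number of profiles).
#' @return Prediction data.frame with `key`, `call`, `score`
#'   (`-log10` E-value, clamped), `evalue`, `bestProfile`, `method`.
#' @export
scanSites <- function(windowSet, db, evalueMax = NULL, databaseSize = NULL) {
  stopifnot(is(windowSet, "SiteWindowSet"))
  if (!isCalibrated(db))
    stop("profile database is not calibrated; run calibrateNull() first")
  if (is.null(evalueMax)) evalueMax <- db@evalueMax
  if (evalueMax <= 0) stop("evalueMax must be > 0")
  if (is.null(databaseSize)) databaseSize <- length(db@profiles)
  enc <- encodeWindows(windowSet@windows, windowWidth(windowSet))
  sc <- profileScores(enc, db)
  bestIdx <- max.col(sc, ties.method = "first")
  best <- sc[cbind(seq_len(nrow(sc)), bestIdx)]
  evalue <- databaseSize * gumbelSF(best, db@nullLocation, db@nullScale)
  data.frame(key = siteKeys(windowSet),
             call = as.integer(evalue <= evalueMax),
             score = -log10(pmax(evalue, 1e-300)),
             evalue = evalue,
             bestProfile = names(db@profiles)[bestIdx],
             method = "naive-profile", level = NA_character_,
             stringsAsFactors = FALSE)
}

#' Serialize the profile database as TSV
#'
#' One row per (cluster, column) with the 21 symbol scores.
#'
#' @param db A [ProfileDB-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeProfilesTSV <- function(db, path) {
  rows <- do.call(rbind, lapply(names(db@profiles), function(cl) {
    p <- db@profiles[[cl]]
    colnames(p) <- ALPHABET21
    data.frame(cluster = cl, column = seq_len(nrow(p)), p,
               check.names = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
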