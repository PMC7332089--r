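#' Assembly configuration for benchmark splits
#'
#' @param confidenceMin Minimum confidence probability for MS-HeLa positive
#'   sites (default 0.8); lower-confidence positives are dropped from every
#'   split to minimize assignment errors.
#' @param filterKimToo Also apply the confidence threshold to MS-Kim
#'   positives (default `FALSE`; the threshold is documented for the HeLa
#'   experiment, and extending it is left as an option).
#' @return A classed list of assembly settings.
#' @export
assemblyConfig <- function(confidenceMin = 0.8, filterKimToo = FALSE) {
  stopifnot(confidenceMin >= 0, confidenceMin <= 1)
  structure(list(confidenceMin = confidenceMin, filterKimToo = filterKimToo),
            class = "AssemblyConfig")
}

KNOWN_SOURCES <- c("Literature", "MS-HeLa", "MS-Kim")

# A site is positive when any (retained) annotation row labels it positive;
# a site with only negative rows is a negative candidate.
siteLabels <- function(annotations) {
  posKeys <- unique(annotations$key[annotations$label == "positive"])
  negKeys <- setdiff(unique(annotations$key[annotations$label == "negative"]),
                     posKeys)
  list(positives = posKeys, negatives = negKeys)
}

#' Filter the negative pool by positive-cluster membership
#'
#' Negative examples that are too similar to positive examples leak homology
#' between evaluation positives and negatives; they are removed by dropping
#' every negative that falls inside a cluster containing at least one
#' positive site.
#'
#' @param clustering A [SiteClustering-class] covering every annotated site.
#' @param annotations Annotation data.frame (with `key` and `label` columns).
#' @return Character vector of retained negative keys, with attributes
#'   `removed` (keys dropped) and `nRemoved`.
#' @export
filterNegatives <- function(clustering, annotations) {
  stopifnot(is(clustering, "SiteClustering"))
  lab <- siteLabels(annotations)
  cid <- clusterIDs(clustering)
  missing <- setdiff(c(lab$positives, lab$negatives), names(cid))
  if (length(missing))
    stop("site '", missing[1], "' has no cluster assignment")
  positiveClusters <- unique(cid[lab$positives])
  keep <- lab$negatives[!cid[lab$negatives] %in% positiveClusters]
  removed <- setdiff(lab$negatives, keep)
  if (!length(keep))
    warning("negative pool is empty: every negative shares a cluster ",
            "with a positive site")
  structure(keep, removed = removed, nRemoved = length(removed))
}

#' Build named benchmark splits
#'
#' Partitions positive sites by evidence source (`Literature`, `MS-HeLa`,
#' `MS-Kim`; `MS` is the deduplicated union of the two mass-spectrometry
#' sources) and by collagen flag, each split sharing the single filtered
#' negative pool. MS-HeLa positives below the confidence threshold are
#' dropped before splitting and appear in no split.
#'
#' Emitted splits: `Literature`, `MS-HeLa`, `MS-Kim`, `MS`, `Collagen`,
#' `Literature-collagen`, `MS-collagen`, plus the non-collagen complements
#' `Literature-noncollagen` and `MS-noncollagen` (signalling-type sites,
#' whose motifs are not conserved, are the hard case worth isolating).
#'
#' @param annotations Annotation data.frame from [readProteome].
#' @param clustering A [SiteClustering-class] over all annotated sites.
#' @param proteome A [Proteome-class] (for collagen flags).
#' @param config An [assemblyConfig].
#' @return A [BenchmarkSplits-class].
#' @export
buildSplits <- function(annotations, clustering, proteome,
                        config = assemblyConfig()) {
  stopifnot(is(clustering, "SiteClustering"), is(proteome, "Proteome"))
  unknown <- setdiff(unique(annotations$source), KNOWN_SOURCES)
  if (length(unknown))
    stop("unknown source tag '", unknown[1], "'")

  conf <- ifelse(is.na(annotations$confidence), 1, annotations$confidence)
  lowConf <- annotations$label == "positive" & conf < config$confidenceMin &
    (annotations$source == "MS-HeLa" |
       (config$filterKimToo & annotations$source == "MS-Kim"))
  nLowConf <- length(unique(annotations$key[lowConf]))
  retained <- annotations[!lowConf, , drop = FALSE]
  droppedKeys <- setdiff(annotations$key[lowConf], retained$key)

  pool <- filterNegatives(clustering, retained)
  lab <- siteLabels(retained)

  posBySource <- function(src)
    unique(retained$key[retained$label == "positive" &
                          retained$source == src])
  lit <- posBySource("Literature")
  hela <- posBySource("MS-HeLa")
  kim <- posBySource("MS-Kim")
  ms <- union(hela, kim)
  flags <- collagenFlags(proteome)
  onCollagen <- function(keys)
    keys[flags[splitSiteKey(keys)$protein_id]]
  offCollagen <- function(keys)
    keys[!flags[splitSiteKey(keys)$protein_id]]

  positives <- list(
    "Literature" = lit,
    "MS-HeLa" = hela,
    "MS-Kim" = kim,
    "MS" = ms,
    "Collagen" = onCollagen(lab$positives),
    "Literature-collagen" = onCollagen(lit),
    "MS-collagen" = onCollagen(ms),
    "Literature-noncollagen" = offCollagen(lit),
    "MS-noncollagen" = offCollagen(ms))

  new("BenchmarkSplits", positives = positives,
      negativePool = as.character(pool),
      meta = list(cutHeight = cutHeight(clustering),
                  confidenceMin = config$confidenceMin,
                  nNegativesRemoved = attr(pool, "nRemoved"),
                  nLowConfidenceDropped = length(droppedKeys)))
}

#' Summary table of a benchmark (clusters, evaluated sites, negatives)
#'
#' @param splits A [BenchmarkSplits-class].
#' @param clustering The [SiteClustering-class] used to build the splits.
#' @return A data.frame with one row per split.
#' @export
splitSummary <- function(splits, clustering) {
  cid <- clusterIDs(clustering)
  rows <- lapply(splitNames(splits), function(nm) {
    pos <- splitPositives(splits, nm)
    data.frame(split = nm,
               clusters = length(unique(cid[pos])),
               evaluated_sites = length(pos),
               filtered_negative_sites = length(negativePool(splits)))
  })
  do.call(rbind, rows)
}

#' Build balanced replica subsamples of one split
#'
#' Each of the `nReplicas` replicas draws `floor(frac * P)` positives without
#' replacement from the split's `P` positives and the same number of
#' negatives without replacement from the shared filtered pool; negatives
#' are re-drawn independently for every replica. Every replica is
#' individually reproducible: replica `r` uses a seed derived from
#' `(seed, r)`.
#'
#' @param splits A [BenchmarkSplits-class].
#' @param split Name of the split to resample.
#' @param nReplicas Number of replicas (default 1000).
#' @param frac Fraction of positives drawn per replica (default 0.7).
#' @param seed Master seed.
#' @return A [ReplicaCollection-class].
#' @export
makeReplicas <- function(splits, split, nReplicas = 1000L, frac = 0.7,
                         seed = 1L) {
  stopifnot(is(splits, "BenchmarkSplits"), nReplicas >= 1L,
            frac > 0, frac <= 1)
  pos <- splitPositives(splits, split)
  pool <- negativePool(splits)
  k <- floor(frac * length(pos))
  if (k < 1L)
    stop("split '", split, "' has too few positives (", length(pos), ")")
  if (length(pool) < k)
    stop("negative pool too small: need ", k, ", have ", length(pool))
  pm <- matrix("", nReplicas, k)
  nm <- matrix("", nReplicas, k)
  seeds <- integer(nReplicas)
  for (r in seq_len(nReplicas)) {
    seeds[r] <- deriveSeed(seed, r)
    set.seed(seeds[r])
    pm[r, ] <- sample(pos, k)
    nm[r, ] <- sample(pool, k)
  }
  new("ReplicaCollection", splitName = split, positives = pm, negatives = nm,
      seeds = seeds, frac = frac)
}
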