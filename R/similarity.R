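#' Scoring parameters for window comparison
#'
#' Pairwise site similarity is the columnwise sum of substitution-matrix
#' scores over the two pre-aligned windows, with an affine penalty per gap
#' run. A gap run is a maximal stretch of consecutive columns in which at
#' least one of the two windows carries a gap; the run is charged
#' `gapOpen + (len - 1) * gapExtend` once, regardless of which window the
#' gaps are in, and its columns contribute nothing to the substitution sum.
#'
#' @slot matrixName Substitution matrix name (a data set of
#'   \pkg{Biostrings}); default `"BLOSUM62"`.
#' @slot gapOpen Penalty for the first gap column of a run (default -5).
#' @slot gapExtend Penalty for each further gap column of a run (default -1).
#' @export
setClass("ScoringParams",
  representation(matrixName = "character", gapOpen = "numeric",
                 gapExtend = "numeric"))

setValidity("ScoringParams", function(object) {
  if (!(object@gapOpen <= object@gapExtend && object@gapExtend <= 0))
    return("gap penalties must satisfy gapOpen <= gapExtend <= 0")
  TRUE
})

#' @rdname ScoringParams-class
#' @param matrixName,gapOpen,gapExtend See slot documentation.
#' @export
ScoringParams <- function(matrixName = "BLOSUM62", gapOpen = -5,
                          gapExtend = -1) {
  new("ScoringParams", matrixName = matrixName, gapOpen = gapOpen,
      gapExtend = gapExtend)
}

setMethod("show", "ScoringParams", function(object) {
  cat(sprintf("ScoringParams: %s, gap open %g / extend %g per run\n",
              object@matrixName, object@gapOpen, object@gapExtend))
})

#' Similarity score of two site windows
#'
#' @param w1,w2 Window strings of equal length (see [extractWindow]).
#' @param params A [ScoringParams-class].
#' @return A single numeric score; symmetric in its arguments.
#' @export
siteScore <- function(w1, w2, params = ScoringParams()) {
  if (nchar(w1) != nchar(w2))
    stop("window length mismatch: ", nchar(w1), " vs ", nchar(w2))
  W <- nchar(w1)
  B <- substitutionMatrix21(params@matrixName)
  e1 <- encodeWindows(w1, W)[1, ]
  e2 <- encodeWindows(w2, W)[1, ]
  gapIdx <- match(GAP, ALPHABET21)
  mask <- e1 == gapIdx | e2 == gapIdx
  sum(B[cbind(e1[!mask], e2[!mask])]) +
    gapRunPenalty(mask, params@gapOpen, params@gapExtend)
}

#' All pairwise similarity scores of a window set
#'
#' Computes the full symmetric score matrix. Windows are grouped by their gap
#' mask so that the per-run affine gap penalty can be added as a constant per
#' mask pair while the substitution part is accumulated columnwise; this
#' keeps the computation vectorized even for thousands of sites.
#'
#' @param windowSet A [SiteWindowSet-class].
#' @param params A [ScoringParams-class].
#' @return A symmetric numeric matrix with site keys as dimnames.
#' @export
siteScoreMatrix <- function(windowSet, params = ScoringParams()) {
  stopifnot(is(windowSet, "SiteWindowSet"))
  n <- length(windowSet)
  if (!n) stop("empty window set")
  W <- windowSet@W
  enc <- encodeWindows(windowSet@windows, W)
  B <- substitutionMatrix21(params@matrixName)
  gapIdx <- match(GAP, ALPHABET21)
  S <- matrix(0, n, n)
  for (cc in seq_len(W)) S <- S + B[enc[, cc], enc[, cc]]
  # per-pair gap-run penalty via unique gap masks
  maskStr <- apply(enc == gapIdx, 1L, function(m)
    paste(as.integer(m), collapse = ""))
  um <- unique(maskStr)
  mi <- match(maskStr, um)
  masks <- lapply(strsplit(um, ""), function(x) x == "1")
  P <- matrix(0, length(um), length(um))
  for (a in seq_along(um)) for (b in seq_len(a)) {
    P[a, b] <- P[b, a] <-
      gapRunPenalty(masks[[a]] | masks[[b]], params@gapOpen, params@gapExtend)
  }
  S <- S + P[mi, mi, drop = FALSE]
  keys <- siteKeys(windowSet)
  dimnames(S) <- list(keys, keys)
  S
}

#' Similarity scores between two window sets
#'
#' Rectangular counterpart of [siteScoreMatrix]: scores every window of
#' `windowSetA` against every window of `windowSetB`.
#'
#' @param windowSetA,windowSetB [SiteWindowSet-class] objects of equal width.
#' @param params A [ScoringParams-class].
#' @return A numeric matrix (rows = A, columns = B) with site keys as
#'   dimnames.
#' @export
crossScoreMatrix <- function(windowSetA, windowSetB,
                             params = ScoringParams()) {
  stopifnot(is(windowSetA, "SiteWindowSet"), is(windowSetB, "SiteWindowSet"))
  if (windowSetA@W != windowSetB@W)
    stop("window length mismatch between the two sets")
  W <- windowSetA@W
  encA <- encodeWindows(windowSetA@windows, W)
  encB <- encodeWindows(windowSetB@windows, W)
  B <- substitutionMatrix21(params@matrixName)
  gapIdx <- match(GAP, ALPHABET21)
  S <- matrix(0, nrow(encA), nrow(encB))
  for (cc in seq_len(W)) S <- S + B[encA[, cc], encB[, cc]]
  maskA <- apply(encA == gapIdx, 1L, function(m)
    paste(as.integer(m), collapse = ""))
  maskB <- apply(encB == gapIdx, 1L, function(m)
    paste(as.integer(m), collapse = ""))
  umA <- unique(maskA); umB <- unique(maskB)
  mA <- lapply(strsplit(umA, ""), function(x) x == "1")
  mB <- lapply(strsplit(umB, ""), function(x) x == "1")
  P <- matrix(0, length(umA), length(umB))
  for (a in seq_along(umA)) for (b in seq_along(umB))
    P[a, b] <- gapRunPenalty(mA[[a]] | mB[[b]], params@gapOpen,
                             params@gapExtend)
  S <- S + P[match(maskA, umA), match(maskB, umB), drop = FALSE]
  dimnames(S) <- list(siteKeys(windowSetA), siteKeys(windowSetB))
  S
}

#' Convert pairwise similarity scores to distances
#'
#' The distance transform inverts the ordering of similarities by affine
#' negation: `d(i, j) = Smax - s(i, j)` with `Smax` the maximum score
#' observed over all pairs including self-pairs. This keeps all distances
#' non-negative and exactly reverses the similarity ranking (BLOSUM scores
#' can be zero or negative, so a reciprocal transform would be ill-defined).
#'
#' @param scoreMatrix Full symmetric score matrix from [siteScoreMatrix].
#' @return A [SiteDistanceMatrix-class].
#' @export
scoreToDistance <- function(scoreMatrix) {
  if (!is.matrix(scoreMatrix) || nrow(scoreMatrix) == 0)
    stop("empty site set: need at least one pairwise score")
  Smax <- max(scoreMatrix)
  keys <- rownames(scoreMatrix)
  new("SiteDistanceMatrix", keys = keys,
      dist = stats::as.dist(Smax - scoreMatrix), Smax = Smax,
      selfScores = setNames(diag(scoreMatrix), keys))
}

#' Default dendrogram cut height for a distance matrix
#'
#' The published clustering protocol does not state its cut threshold, so the
#' default is calibrated such that windows sharing roughly 70% identical
#' columns fall below the cut: `Smax - identity * median(self scores)`.
#' The height actually used is always recorded in the clustering object and
#' in pipeline outputs.
#'
#' @param dmat A [SiteDistanceMatrix-class].
#' @param identity Fraction of self-similarity at which windows should still
#'   co-cluster (default 0.7).
#' @return A numeric cut height.
#' @export
defaultCutHeight <- function(dmat, identity = 0.7) {
  stopifnot(is(dmat, "SiteDistanceMatrix"))
  dmat@Smax - identity * stats::median(dmat@selfScores)
}

# UPGMA (average linkage) with a deterministic lexicographic tie-break:
# among all pairs within `tol` of the minimal inter-cluster distance, merge
# the pair whose (min representative, max representative) is smallest, where
# a cluster's representative is the smallest original site index it contains.
# Returns hclust-style merge/height.
upgmaMerge <- function(D, tol = 1e-9) {
  n <- nrow(D)
  d <- D
  diag(d) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  rep_ <- seq_len(n)        # representative original index per active slot
  node <- -seq_len(n)       # hclust node code per active slot
  merge <- matrix(0L, max(n - 1L, 0L), 2L)
  height <- numeric(max(n - 1L, 0L))
  if (n < 2L) return(list(merge = merge, height = height))
  rowMin <- apply(d, 1L, min)
  rowNN <- apply(d, 1L, which.min)

  for (step in seq_len(n - 1L)) {
    m <- min(rowMin[active])
    cand <- which(active & rowMin <= m + tol)
    best <- NULL
    for (r in cand) {
      cols <- which(d[r, ] <= m + tol)
      for (cc in cols) {
        a <- min(rep_[r], rep_[cc]); b <- max(rep_[r], rep_[cc])
        if (is.null(best) || a < best[1] || (a == best[1] && b < best[2]))
          best <- c(a, b, r, cc)
      }
    }
    i <- best[3]; j <- best[4]
    if (rep_[j] < rep_[i]) { tmp <- i; i <- j; j <- tmp }
    h <- d[i, j]
    merge[step, ] <- sort(c(node[i], node[j]))
    height[step] <- h
    # Lance-Williams average-linkage update into slot i
    others <- which(active); others <- others[!others %in% c(i, j)]
    if (length(others)) {
      d[i, others] <- (size[i] * d[i, others] + size[j] * d[j, others]) /
        (size[i] + size[j])
      d[others, i] <- d[i, others]
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    d[j, ] <- Inf; d[, j] <- Inf
    rowMin[j] <- Inf
    node[i] <- step
    alive <- which(active)
    if (length(alive) > 1L) {
      rowMin[i] <- min(d[i, ])
      rowNN[i] <- which.min(d[i, ])
    } else { rowMin[i] <- Inf; rowNN[i] <- i }
    # only rows whose cached nearest neighbour was i or j can go stale: the
    # averaged value d[k, i] is >= min(old d[k,i], old d[k,j]) >= rowMin[k]
    for (k in alive) {
      if (k == i) next
      if (rowNN[k] == i || rowNN[k] == j) {
        rowMin[k] <- min(d[k, ])
        rowNN[k] <- which.min(d[k, ])
      } else if (d[k, i] < rowMin[k]) {
        rowMin[k] <- d[k, i]
        rowNN[k] <- i
      }
    }
  }
  list(merge = merge, height = height)
}

#' Cluster sites by UPGMA and cut the tree
#'
#' Builds the average-linkage (UPGMA) merge tree on the site distance matrix
#' and cuts it at `cutHeight` to obtain flat clusters. Merging is
#' deterministic: among tied minimal inter-cluster distances the pair with
#' the lexicographically smallest pair of representatives (smallest original
#' site index per cluster) is merged first.
#'
#' @param dmat A [SiteDistanceMatrix-class].
#' @param cutHeight Height at which to cut the tree; merges at exactly this
#'   height are still joined. Defaults to [defaultCutHeight].
#' @return A [SiteClustering-class]; cluster ids are contiguous integers
#'   numbered by first site occurrence.
#' @export
clusterSites <- function(dmat, cutHeight = NULL) {
  stopifnot(is(dmat, "SiteDistanceMatrix"))
  if (is.null(cutHeight)) cutHeight <- defaultCutHeight(dmat)
  if (!is.finite(cutHeight) || cutHeight < 0)
    stop("cutHeight must be a finite non-negative number")
  n <- length(dmat@keys)
  D <- as.matrix(dmat@dist)
  if (any(!is.finite(D))) stop("non-finite distances")
  tree <- upgmaMerge(D)
  # union-find over merges with height <= cutHeight
  parent <- seq_len(n)
  findRoot <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  mergedMembers <- vector("list", max(n - 1L, 0L))
  for (step in seq_len(max(n - 1L, 0L))) {
    getMembers <- function(code)
      if (code < 0L) -code else mergedMembers[[code]]
    a <- getMembers(tree$merge[step, 1]); b <- getMembers(tree$merge[step, 2])
    mergedMembers[[step]] <- c(a, b)
    if (tree$height[step] <= cutHeight) {
      ra <- findRoot(a[1]); rb <- findRoot(b[1])
      parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  ids <- as.integer(factor(roots, levels = unique(roots)))
  new("SiteClustering", keys = dmat@keys, cluster = ids,
      merge = tree$merge, height = tree$height, cutHeight = cutHeight)
}

#' Convert a site clustering to a base-R hclust object
#'
#' Useful for plotting the dendrogram or exporting the merge tree (e.g. via
#' \pkg{ape}).
#'
#' @param clustering A [SiteClustering-class].
#' @return An object of class `hclust`.
#' @export
asHclust <- function(clustering) {
  stopifnot(is(clustering, "SiteClustering"))
  n <- length(clustering@keys)
  ord <- integer(0)
  if (n >= 2L) {
    members <- vector("list", n - 1L)
    for (step in seq_len(n - 1L)) {
      getMembers <- function(code)
        if (code < 0L) -code else members[[code]]
      members[[step]] <- c(getMembers(clustering@merge[step, 1]),
                           getMembers(clustering@merge[step, 2]))
    }
    ord <- members[[n - 1L]]
  } else ord <- seq_len(n)
  structure(list(merge = clustering@merge, height = clustering@height,
                 order = ord, labels = clustering@keys,
                 method = "average", call = match.call(),
                 dist.method = "Smax - score"),
            class = "hclust")
}

#' Dump a condensed distance matrix as TSV
#'
#' @param dmat A [SiteDistanceMatrix-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeDistanceTSV <- function(dmat, path) {
  m <- as.matrix(dmat@dist)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  write.table(data.frame(site_a = dmat@keys[idx[, 1]],
                         site_b = dmat@keys[idx[, 2]],
                         distance = m[idx]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
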