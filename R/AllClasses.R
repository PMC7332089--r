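#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
#' @importFrom stats rbinom runif rbeta rpois sd quantile setNames
#' @importFrom utils read.delim write.table head
NULL

#' Proteome: sequences, collagen flags and per-residue feature tracks
#'
#' Container for a set of protein sequences together with the metadata the
#' benchmark needs: a per-protein collagen flag (standing in for recognition
#' of the collagen triple-helix repeat domain) and optional per-residue binary
#' feature tracks (disorder, helix, sheet, low complexity).
#'
#' @slot sequences An [Biostrings::AAStringSet] with unique names.
#' @slot collagen Named logical vector, one entry per protein.
#' @slot tracks Named list (one element per feature); each element is a named
#'   list of 0/1 integer vectors, one per protein carrying that track, each of
#'   the same length as the protein sequence.
#' @export
setClass("Proteome",
  representation(sequences = "AAStringSet", collagen = "logical",
                 tracks = "list"))

setValidity("Proteome", function(object) {
  ids <- names(object@sequences)
  if (is.null(ids) || anyDuplicated(ids))
    return("protein ids must be present and unique")
  if (any(Biostrings::width(object@sequences) < 1L))
    return("all sequences must have length >= 1")
  if (!identical(sort(names(object@collagen)), sort(ids)))
    return("collagen flags must be named by protein id, one per protein")
  for (feat in names(object@tracks)) {
    tr <- object@tracks[[feat]]
    bad <- names(tr)[!names(tr) %in% ids]
    if (length(bad))
      return(sprintf("track '%s' refers to unknown protein '%s'", feat, bad[1]))
    for (id in names(tr)) {
      if (length(tr[[id]]) != Biostrings::width(object@sequences)[match(id, ids)])
        return(sprintf("track '%s' for '%s' has wrong length", feat, id))
      if (!all(tr[[id]] %in% c(0L, 1L)))
        return(sprintf("track '%s' for '%s' is not binary", feat, id))
    }
  }
  TRUE
})

#' Fixed-length gapped site windows
#'
#' Each window is a string of length `W` over the 20 canonical amino-acid
#' letters plus the gap character `-`, centred on a candidate residue.
#' Gaps substitute non-canonical letters and pad windows at sequence ends.
#'
#' @slot windows Character vector of window strings, all of length `W`.
#' @slot proteinID Character vector of originating protein ids.
#' @slot position Integer vector of 1-based centre positions.
#' @slot W Odd integer window length.
#' @export
setClass("SiteWindowSet",
  representation(windows = "character", proteinID = "character",
                 position = "integer", W = "integer"))

setValidity("SiteWindowSet", function(object) {
  n <- length(object@windows)
  if (length(object@proteinID) != n || length(object@position) != n)
    return("windows, proteinID and position must have equal length")
  if (length(object@W) != 1L || object@W %% 2L != 1L)
    return("W must be a single odd integer")
  if (n && any(nchar(object@windows) != object@W))
    return("every window must have exactly W characters")
  if (n) {
    centre <- substr(object@windows, (object@W + 1L) %/% 2L,
                     (object@W + 1L) %/% 2L)
    if (any(centre == "-"))
      return("the centre character of a window can never be a gap")
  }
  TRUE
})

#' Pairwise site distance matrix
#'
#' Distances are `Smax - score`, where `Smax` is the maximum pairwise
#' similarity score observed (including self comparisons), so that identical
#' windows sit at distance 0 from each other only when they attain `Smax`,
#' and every self-distance is the row minimum.
#'
#' @slot keys Character vector of site keys (`protein:position`).
#' @slot dist A [stats::dist] object of pairwise distances.
#' @slot Smax Maximum similarity score observed over all pairs.
#' @slot selfScores Named numeric vector of self-similarity scores.
#' @export
setClass("SiteDistanceMatrix",
  representation(keys = "character", dist = "dist", Smax = "numeric",
                 selfScores = "numeric"))

setValidity("SiteDistanceMatrix", function(object) {
  n <- length(object@keys)
  if (attr(object@dist, "Size") != n)
    return("dist size does not match number of keys")
  if (anyDuplicated(object@keys)) return("site keys must be unique")
  if (n > 1 && any(!is.finite(object@dist)))
    return("distances must be finite")
  if (n > 1 && any(object@dist < -1e-9))
    return("distances must be non-negative")
  TRUE
})

#' UPGMA clustering of sites
#'
#' @slot keys Site keys in input order.
#' @slot cluster Integer cluster ids (contiguous from 1), one per key.
#' @slot merge,height hclust-style merge matrix and merge heights.
#' @slot cutHeight The height at which the tree was cut.
#' @export
setClass("SiteClustering",
  representation(keys = "character", cluster = "integer", merge = "matrix",
                 height = "numeric", cutHeight = "numeric"))

setValidity("SiteClustering", function(object) {
  if (length(object@cluster) != length(object@keys))
    return("one cluster id per site key required")
  k <- max(object@cluster, 0L)
  if (k && !identical(sort(unique(object@cluster)), seq_len(k)))
    return("cluster ids must be contiguous integers from 1")
  TRUE
})

#' Named benchmark splits sharing one filtered negative pool
#'
#' @slot positives Named list; each element is the character vector of
#'   positive site keys of one split.
#' @slot negativePool Character vector of filtered negative site keys shared
#'   by every split.
#' @slot meta List of provenance values (cut height, seed, config).
#' @export
setClass("BenchmarkSplits",
  representation(positives = "list", negativePool = "character",
                 meta = "list"))

setValidity("BenchmarkSplits", function(object) {
  for (nm in names(object@positives)) {
    if (any(object@positives[[nm]] %in% object@negativePool))
      return(sprintf("split '%s' has keys in both positives and negatives", nm))
  }
  TRUE
})

#' Balanced replica subsamples of one split
#'
#' Each replica holds `floor(frac * P)` positives sampled without replacement
#' and the same number of negatives, re-drawn independently for every replica.
#'
#' @slot splitName Name of the split the replicas were drawn from.
#' @slot positives,negatives Character matrices (replicas in rows).
#' @slot seeds Integer vector of per-replica RNG seeds.
#' @slot frac Fraction of available positives drawn per replica.
#' @export
setClass("ReplicaCollection",
  representation(splitName = "character", positives = "matrix",
                 negatives = "matrix", seeds = "integer", frac = "numeric"))

setValidity("ReplicaCollection", function(object) {
  if (!identical(dim(object@positives), dim(object@negatives)))
    return("replicas must be exactly balanced (|positives| = |negatives|)")
  if (nrow(object@positives) != length(object@seeds))
    return("one seed per replica required")
  TRUE
})

#' Cluster-seeded positional profile database
#'
#' One profile per positive cluster: a `W x 21` log-odds matrix over the 20
#' canonical residues plus the gap symbol, built from all member windows of
#' the cluster with pseudocount smoothing against background frequencies.
#'
#' @slot profiles List of `W x 21` numeric matrices, named by cluster id.
#' @slot seedKeys List of character vectors: the member site keys per profile.
#' @slot background Numeric vector of 21 background symbol frequencies.
#' @slot W Window length.
#' @slot nullLocation,nullScale Gumbel parameters of the calibrated null
#'   score distribution (NA before calibration).
#' @slot evalueMax E-value threshold for a positive call.
#' @export
setClass("ProfileDB",
  representation(profiles = "list", seedKeys = "list", background = "numeric",
                 W = "integer", nullLocation = "numeric", nullScale = "numeric",
                 evalueMax = "numeric"))

setValidity("ProfileDB", function(object) {
  if (!length(object@profiles)) return("profile database is empty")
  ok <- vapply(object@profiles, function(p)
    is.matrix(p) && nrow(p) == object@W && ncol(p) == 21L && all(is.finite(p)),
    logical(1))
  if (!all(ok)) return("every profile must be a finite W x 21 matrix")
  if (any(!lengths(object@seedKeys))) return("seed membership must be non-empty")
  if (object@evalueMax <= 0) return("evalueMax must be > 0")
  TRUE
})
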