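#' @rdname Proteome-class
#' @export
setMethod("proteinIDs", "Proteome", function(object) names(object@sequences))

#' @rdname Proteome-class
#' @export
setMethod("proteinSequences", "Proteome", function(object) object@sequences)

#' @rdname Proteome-class
#' @export
setMethod("collagenFlags", "Proteome",
          function(object) object@collagen[names(object@sequences)])

#' @rdname Proteome-class
#' @export
setMethod("featureTracks", "Proteome", function(object, feature) {
  if (missing(feature)) return(object@tracks)
  if (!feature %in% names(object@tracks))
    stop("no track named '", feature, "' in this proteome")
  object@tracks[[feature]]
})

#' @rdname Proteome-class
#' @export
setMethod("length", "Proteome", function(x) length(x@sequences))

setMethod("show", "Proteome", function(object) {
  cat(sprintf("Proteome with %d proteins (%d collagen-flagged)\n",
              length(object@sequences), sum(object@collagen)))
  if (length(object@tracks))
    cat("  feature tracks:", paste(names(object@tracks), collapse = ", "), "\n")
})

#' @rdname SiteWindowSet-class
#' @export
setMethod("windowStrings", "SiteWindowSet", function(object) {
  setNames(object@windows, siteKeys(object))
})

#' @rdname SiteWindowSet-class
#' @export
setMethod("windowWidth", "SiteWindowSet", function(object) object@W)

#' @rdname SiteWindowSet-class
#' @export
setMethod("siteKeys", "SiteWindowSet", function(object) {
  makeSiteKey(object@proteinID, object@position)
})

#' @rdname SiteWindowSet-class
#' @export
setMethod("length", "SiteWindowSet", function(x) length(x@windows))

setMethod("show", "SiteWindowSet", function(object) {
  cat(sprintf("SiteWindowSet: %d windows of width %d\n",
              length(object@windows), object@W))
  if (length(object@windows)) {
    ex <- head(seq_along(object@windows), 3L)
    for (i in ex)
      cat(sprintf("  %s:%d  %s\n", object@proteinID[i], object@position[i],
                  object@windows[i]))
    if (length(object@windows) > 3L) cat("  ...\n")
  }
})

#' @rdname SiteDistanceMatrix-class
#' @export
setMethod("siteKeys", "SiteDistanceMatrix", function(object) object@keys)

setMethod("show", "SiteDistanceMatrix", function(object) {
  cat(sprintf("SiteDistanceMatrix over %d sites (Smax = %g)\n",
              length(object@keys), object@Smax))
})

#' @rdname SiteClustering-class
#' @export
setMethod("clusterIDs", "SiteClustering",
          function(object) setNames(object@cluster, object@keys))

#' @rdname SiteClustering-class
#' @export
setMethod("cutHeight", "SiteClustering", function(object) object@cutHeight)

#' @rdname SiteClustering-class
#' @export
setMethod("siteKeys", "SiteClustering", function(object) object@keys)

setMethod("show", "SiteClustering", function(object) {
  cat(sprintf("SiteClustering: %d sites in %d clusters (cut height %.3f)\n",
              length(object@keys), max(object@cluster, 0L), object@cutHeight))
})

#' @rdname BenchmarkSplits-class
#' @export
setMethod("splitNames", "BenchmarkSplits",
          function(object) names(object@positives))

#' @rdname BenchmarkSplits-class
#' @export
setMethod("splitPositives", "BenchmarkSplits", function(object, split) {
  if (!split %in% names(object@positives))
    stop("unknown split '", split, "'")
  object@positives[[split]]
})

#' @rdname BenchmarkSplits-class
#' @export
setMethod("negativePool", "BenchmarkSplits",
          function(object) object@negativePool)

setMethod("show", "BenchmarkSplits", function(object) {
  cat(sprintf("BenchmarkSplits: %d splits, shared negative pool of %d sites\n",
              length(object@positives), length(object@negativePool)))
  for (nm in names(object@positives))
    cat(sprintf("  %-24s %5d positives\n", nm, length(object@positives[[nm]])))
})

#' @rdname ReplicaCollection-class
#' @export
setMethod("nReplicas", "ReplicaCollection",
          function(object) nrow(object@positives))

#' @rdname ReplicaCollection-class
#' @export
setMethod("replicaPositives", "ReplicaCollection",
          function(object, i) object@positives[i, ])

#' @rdname ReplicaCollection-class
#' @export
setMethod("replicaNegatives", "ReplicaCollection",
          function(object, i) object@negatives[i, ])

setMethod("show", "ReplicaCollection", function(object) {
  cat(sprintf(
    "ReplicaCollection: %d replicas of split '%s' (%d + %d sites each)\n",
    nrow(object@positives), object@splitName, ncol(object@positives),
    ncol(object@negatives)))
})

#' @rdname ProfileDB-class
#' @export
setMethod("profileCount", "ProfileDB", function(object) length(object@profiles))

#' @rdname ProfileDB-class
#' @export
setMethod("isCalibrated", "ProfileDB", function(object) {
  is.finite(object@nullLocation) && is.finite(object@nullScale)
})

setMethod("show", "ProfileDB", function(object) {
  cat(sprintf("ProfileDB: %d positional profiles (W = %d), %s\n",
              length(object@profiles), object@W,
              if (isCalibrated(object))
                sprintf("calibrated null (Gumbel loc %.2f, scale %.2f)",
                        object@nullLocation, object@nullScale)
              else "uncalibrated"))
})
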