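#' @rdname Proteome-class
#' @param object,x An object.
#' @export
setGeneric("proteinIDs", function(object) standardGeneric("proteinIDs"))

#' @rdname Proteome-class
#' @export
setGeneric("proteinSequences",
           function(object) standardGeneric("proteinSequences"))

#' @rdname Proteome-class
#' @export
setGeneric("collagenFlags", function(object) standardGeneric("collagenFlags"))

#' @rdname Proteome-class
#' @param feature Feature track name.
#' @export
setGeneric("featureTracks",
           function(object, feature) standardGeneric("featureTracks"))

#' @rdname SiteWindowSet-class
#' @export
setGeneric("windowStrings", function(object) standardGeneric("windowStrings"))

#' @rdname SiteWindowSet-class
#' @export
setGeneric("windowWidth", function(object) standardGeneric("windowWidth"))

#' @rdname SiteWindowSet-class
#' @export
setGeneric("siteKeys", function(object) standardGeneric("siteKeys"))

#' @rdname SiteClustering-class
#' @export
setGeneric("clusterIDs", function(object) standardGeneric("clusterIDs"))

#' @rdname SiteClustering-class
#' @export
setGeneric("cutHeight", function(object) standardGeneric("cutHeight"))

#' @rdname BenchmarkSplits-class
#' @export
setGeneric("splitNames", function(object) standardGeneric("splitNames"))

#' @rdname BenchmarkSplits-class
#' @param split Split name.
#' @export
setGeneric("splitPositives",
           function(object, split) standardGeneric("splitPositives"))

#' @rdname BenchmarkSplits-class
#' @export
setGeneric("negativePool", function(object) standardGeneric("negativePool"))

#' @rdname ReplicaCollection-class
#' @export
setGeneric("nReplicas", function(object) standardGeneric("nReplicas"))

#' @rdname ReplicaCollection-class
#' @param i Replica index.
#' @export
setGeneric("replicaPositives",
           function(object, i) standardGeneric("replicaPositives"))

#' @rdname ReplicaCollection-class
#' @export
setGeneric("replicaNegatives",
           function(object, i) standardGeneric("replicaNegatives"))

#' @rdname ProfileDB-class
#' @export
setGeneric("profileCount", function(object) standardGeneric("profileCount"))

#' @rdname ProfileDB-class
#' @export
setGeneric("isCalibrated", function(object) standardGeneric("isCalibrated"))
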