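#' Accessors for CRISPR data classes
#'
#' Small accessor family used instead of direct slot access.
#'
#' @param x an object of one of the package's S4 classes.
#' @return the corresponding slot value; see the individual class pages.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("contigId", function(x) standardGeneric("contigId"))
#' @rdname accessors
#' @export
setGeneric("repeatRanges", function(x) standardGeneric("repeatRanges"))
#' @rdname accessors
#' @export
setGeneric("spacerRanges", function(x) standardGeneric("spacerRanges"))
#' @rdname accessors
#' @export
setGeneric("consensus", function(x) standardGeneric("consensus"))
#' @rdname accessors
#' @export
setGeneric("avgMismatch", function(x) standardGeneric("avgMismatch"))
#' @rdname accessors
#' @export
setGeneric("nRepeats", function(x) standardGeneric("nRepeats"))
#' @rdname accessors
#' @export
setGeneric("nSpacers", function(x) standardGeneric("nSpacers"))
#' @rdname accessors
#' @export
setGeneric("recruitedReads", function(x) standardGeneric("recruitedReads"))
#' @rdname accessors
#' @export
setGeneric("readHits", function(x) standardGeneric("readHits"))
#' @rdname accessors
#' @export
setGeneric("kmerCounts", function(x) standardGeneric("kmerCounts"))
#' @rdname accessors
#' @export
setGeneric("kmerLength", function(x) standardGeneric("kmerLength"))
#' @rdname accessors
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))
#' @rdname accessors
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("incidence", function(x) standardGeneric("incidence"))
#' @rdname accessors
#' @export
setGeneric("sharingSummary", function(x) standardGeneric("sharingSummary"))

#' @rdname accessors
#' @export
setMethod("contigId", "CrisprArray", function(x) x@contigId)
#' @rdname accessors
#' @export
setMethod("repeatRanges", "CrisprArray", function(x) x@repeats)
#' @rdname accessors
#' @export
setMethod("spacerRanges", "CrisprArray", function(x) x@spacers)
#' @rdname accessors
#' @export
setMethod("consensus", "CrisprArray", function(x) x@consensus)
#' @rdname accessors
#' @export
setMethod("avgMismatch", "CrisprArray", function(x) x@avgMismatch)
#' @rdname accessors
#' @export
setMethod("nRepeats", "CrisprArray", function(x) length(x@repeats))
#' @rdname accessors
#' @export
setMethod("nSpacers", "CrisprArray", function(x) length(x@spacers))

#' @rdname accessors
#' @export
setMethod("recruitedReads", "RecruitedReadSet", function(x) x@reads)
#' @rdname accessors
#' @export
setMethod("readHits", "RecruitedReadSet", function(x) x@hits)

#' @rdname accessors
#' @export
setMethod("kmerCounts", "DeBruijnGraph", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("kmerLength", "DeBruijnGraph", function(x) x@k)

#' @rdname accessors
#' @export
setMethod("clusterMembers", "ClusterSet", function(x) x@members)
#' @rdname accessors
#' @export
setMethod("representatives", "ClusterSet", function(x) x@representatives)

#' @rdname accessors
#' @export
setMethod("networkEdges", "RepeatNetwork", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("networkNodes", "RepeatNetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("incidence", "SharingMatrix", function(x) x@incidence)
#' @rdname accessors
#' @export
setMethod("sharingSummary", "SharingMatrix", function(x) x@summary)

setMethod("show", "CrisprArray", function(object) {
  tr <- mcols(object@repeats)$truncated
  cat(sprintf(
    "CrisprArray on %s: %d repeats (%d truncated), %d spacers\n",
    object@contigId, length(object@repeats), sum(tr != "none"),
    length(object@spacers)))
  cat(sprintf("  span %d-%d, consensus (%d nt) %s\n",
              min(start(object@repeats)), max(end(object@repeats)),
              nchar(object@consensus), object@consensus))
  cat(sprintf("  avg mismatch vs consensus: %.2f\n", object@avgMismatch))
})

setMethod("show", "RecruitedReadSet", function(object) {
  cat(sprintf(
    "RecruitedReadSet: query %s, sample %s: %d/%d reads recruited (%d too short)\n",
    object@queryId, object@sampleId, length(object@reads),
    object@nInput, object@nTooShort))
})

setMethod("show", "DeBruijnGraph", function(object) {
  cat(sprintf("DeBruijnGraph: k=%d, %d canonical k-mers (total count %d)\n",
              object@k, length(object@counts), sum(object@counts)))
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf(
    "ClusterSet: %d sequences in %d clusters at identity >= %.2f (%d dropped as revcomp duplicates)\n",
    nrow(object@members), length(object@representatives),
    object@threshold, length(object@dropped)))
})

setMethod("show", "RepeatNetwork", function(object) {
  cat(sprintf("RepeatNetwork: %d nodes, %d edges (distance <= %d)\n",
              nrow(object@nodes), nrow(object@edges), object@maxDist))
})

setMethod("show", "SharingMatrix", function(object) {
  cat(sprintf("SharingMatrix: %d spacer clusters x %d samples\n",
              nrow(object@incidence), ncol(object@incidence)))
})
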