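#' Detection parameters
#'
#' Tunable parameters for de novo CRISPR array detection. Defaults follow the
#' usual structural expectations for CRISPR loci: repeats of 19-48 bp,
#' spacers of 18-72 bp, at least 3 repeat copies, spacers mutually dissimilar
#' and of comparable size.
#'
#' @slot seedLen exact k-mer seed length used to find candidate repeats.
#' @slot minRepeatLen,maxRepeatLen accepted repeat-consensus length range.
#' @slot minSpacerLen,maxSpacerLen accepted spacer length range.
#' @slot minCopies minimum number of repeat copies in a reported array.
#' @slot spacerIdentityMax spacer pairs (and spacer-vs-repeat) at or above
#'   this identity cause rejection (identity = 1 - editDist/max length).
#' @slot spacerLenRatioMax maximum allowed ratio of longest to shortest
#'   spacer in an array.
#' @slot columnAgreement minimum fraction of copies agreeing with the column
#'   majority for repeat-boundary extension.
#' @export
setClass("DetectParams", representation(
  seedLen = "integer",
  minRepeatLen = "integer", maxRepeatLen = "integer",
  minSpacerLen = "integer", maxSpacerLen = "integer",
  minCopies = "integer",
  spacerIdentityMax = "numeric",
  spacerLenRatioMax = "numeric",
  columnAgreement = "numeric"
))

setValidity("DetectParams", function(object) {
  msg <- character(0)
  if (object@seedLen < 1L || object@seedLen > object@minRepeatLen)
    msg <- c(msg, "seedLen must satisfy 0 < seedLen <= minRepeatLen")
  if (object@minRepeatLen > object@maxRepeatLen)
    msg <- c(msg, "minRepeatLen > maxRepeatLen")
  if (object@minSpacerLen > object@maxSpacerLen)
    msg <- c(msg, "minSpacerLen > maxSpacerLen")
  if (object@minCopies < 2L) msg <- c(msg, "minCopies must be >= 2")
  if (object@spacerIdentityMax <= 0 || object@spacerIdentityMax > 1)
    msg <- c(msg, "spacerIdentityMax must be in (0, 1]")
  if (object@columnAgreement <= 0 || object@columnAgreement > 1)
    msg <- c(msg, "columnAgreement must be in (0, 1]")
  if (object@spacerLenRatioMax < 1)
    msg <- c(msg, "spacerLenRatioMax must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param seedLen,minRepeatLen,maxRepeatLen,minSpacerLen,maxSpacerLen
#'   integer parameters, see slots.
#' @param minCopies,spacerIdentityMax,spacerLenRatioMax,columnAgreement
#'   see slots.
#' @return \code{detectParams()} returns a \code{DetectParams} object.
#' @rdname DetectParams-class
#' @export
detectParams <- function(seedLen = 8L, minRepeatLen = 19L, maxRepeatLen = 48L,
                         minSpacerLen = 18L, maxSpacerLen = 72L,
                         minCopies = 3L, spacerIdentityMax = 0.80,
                         spacerLenRatioMax = 2.5, columnAgreement = 0.75) {
  new("DetectParams", seedLen = as.integer(seedLen),
      minRepeatLen = as.integer(minRepeatLen),
      maxRepeatLen = as.integer(maxRepeatLen),
      minSpacerLen = as.integer(minSpacerLen),
      maxSpacerLen = as.integer(maxSpacerLen),
      minCopies = as.integer(minCopies),
      spacerIdentityMax = spacerIdentityMax,
      spacerLenRatioMax = spacerLenRatioMax,
      columnAgreement = columnAgreement)
}

#' Selection parameters for the CRISPR catalog
#'
#' The filter applied when promoting detected arrays into the catalog of
#' trusted CRISPRs: repeats of 24-40 bp, at least 4 complete copies, and
#' copies differing from the consensus by at most one nucleotide on average.
#'
#' @slot minRepeatLen,maxRepeatLen accepted consensus length range.
#' @slot minCopies minimum number of complete (non-truncated) repeat copies.
#' @slot maxAvgMismatch maximum mean mismatches of complete copies vs the
#'   consensus.
#' @slot redundancyIdentity identity threshold for redundancy clustering.
#' @export
setClass("SelectionParams", representation(
  minRepeatLen = "integer", maxRepeatLen = "integer",
  minCopies = "integer", maxAvgMismatch = "numeric",
  redundancyIdentity = "numeric"
))

setValidity("SelectionParams", function(object) {
  msg <- character(0)
  if (object@minRepeatLen > object@maxRepeatLen)
    msg <- c(msg, "minRepeatLen > maxRepeatLen")
  if (object@redundancyIdentity <= 0 || object@redundancyIdentity > 1)
    msg <- c(msg, "redundancyIdentity must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param minRepeatLen,maxRepeatLen,minCopies,maxAvgMismatch,redundancyIdentity
#'   see slots.
#' @return \code{selectionParams()} returns a \code{SelectionParams} object.
#' @rdname SelectionParams-class
#' @export
selectionParams <- function(minRepeatLen = 24L, maxRepeatLen = 40L,
                            minCopies = 4L, maxAvgMismatch = 1.0,
                            redundancyIdentity = 0.90) {
  new("SelectionParams", minRepeatLen = as.integer(minRepeatLen),
      maxRepeatLen = as.integer(maxRepeatLen),
      minCopies = as.integer(minCopies),
      maxAvgMismatch = maxAvgMismatch,
      redundancyIdentity = redundancyIdentity)
}

#' CRISPR array
#'
#' An ordered run of direct-repeat matches and the spacers between them on
#' one contig. Repeat ranges carry per-copy metadata (strand, mismatches to
#' the consensus, truncation flag); there is exactly one spacer between each
#' adjacent repeat pair.
#'
#' @slot contigId contig the array lies on.
#' @slot repeats \code{IRanges} of repeat copies with mcols \code{strand}
#'   (\code{"+"}/\code{"-"}), \code{mismatches} (vs consensus; NA for
#'   truncated copies is not used, partial copies are scored over the
#'   matched bases) and \code{truncated} (\code{"none"}, \code{"left"},
#'   \code{"right"}).
#' @slot spacers \code{IRanges} of the spacers, one between each adjacent
#'   repeat pair.
#' @slot consensus repeat consensus in array orientation.
#' @slot avgMismatch mean mismatches of complete copies vs the consensus.
#' @export
setClass("CrisprArray", representation(
  contigId = "character",
  repeats = "IRanges",
  spacers = "IRanges",
  consensus = "character",
  avgMismatch = "numeric"
))

setValidity("CrisprArray", function(object) {
  msg <- character(0)
  r <- object@repeats
  s <- object@spacers
  if (length(r) < 1L) msg <- c(msg, "array must contain at least one repeat")
  if (length(s) != max(0L, length(r) - 1L))
    msg <- c(msg, "must have exactly one spacer between adjacent repeats")
  if (length(r) > 1L) {
    if (is.unsorted(start(r), strictly = TRUE))
      msg <- c(msg, "repeats must be sorted by start")
    if (any(start(r)[-1L] <= end(r)[-length(r)]))
      msg <- c(msg, "repeats must not overlap")
    if (length(s) == length(r) - 1L &&
        (any(start(s) != end(r)[-length(r)] + 1L) ||
         any(end(s) != start(r)[-1L] - 1L)))
      msg <- c(msg, "spacers must tile the gaps between adjacent repeats")
  }
  mc <- mcols(r)
  need <- c("strand", "mismatches", "truncated")
  if (!all(need %in% colnames(mc)))
    msg <- c(msg, "repeat mcols must contain strand, mismatches, truncated")
  else if (!all(mc$truncated %in% c("none", "left", "right")))
    msg <- c(msg, "truncated flags must be none/left/right")
  if (length(object@consensus) != 1L || nchar(object@consensus) < 1L)
    msg <- c(msg, "consensus must be a single non-empty string")
  if (length(msg)) msg else TRUE
})

.newCrisprArray <- function(contigId, repeats, spacers, consensus,
                            avgMismatch) {
  new("CrisprArray", contigId = contigId, repeats = repeats,
      spacers = spacers, consensus = consensus,
      avgMismatch = as.numeric(avgMismatch))
}

#' Recruited read set
#'
#' Reads from one sample that contain a full-length window of a query repeat
#' within the mismatch budget, with the best match per read.
#'
#' @slot queryId id of the query repeat.
#' @slot sampleId id of the read set.
#' @slot reads the recruited reads (\code{DNAStringSet}).
#' @slot hits per-read best match: \code{DataFrame} with \code{pos},
#'   \code{strand}, \code{mismatches}.
#' @slot nInput number of reads scanned.
#' @slot nTooShort number of reads skipped for being shorter than the query.
#' @export
setClass("RecruitedReadSet", representation(
  queryId = "character", sampleId = "character",
  reads = "DNAStringSet", hits = "DataFrame",
  nInput = "integer", nTooShort = "integer"
))

setValidity("RecruitedReadSet", function(object) {
  if (length(object@reads) != nrow(object@hits))
    return("hits must have one row per recruited read")
  TRUE
})

#' de Bruijn graph over canonical k-mers
#'
#' Node-centric de Bruijn graph: nodes are canonical k-mers (lexicographic
#' minimum of a k-mer and its reverse complement) with multiplicities;
#' adjacency is implied by (k-1)-overlap.
#'
#' @slot k k-mer length.
#' @slot counts named integer vector; names are canonical k-mers.
#' @export
setClass("DeBruijnGraph", representation(
  k = "integer", counts = "integer"
))

setValidity("DeBruijnGraph", function(object) {
  if (length(object@counts) && is.null(names(object@counts)))
    return("counts must be named by k-mer")
  if (length(object@counts) && any(nchar(names(object@counts)) != object@k))
    return("all k-mers must have length k")
  if (any(object@counts < 1L)) return("counts must be >= 1")
  TRUE
})

#' Greedy identity cluster set
#'
#' Result of greedy, orientation-aware identity clustering (CD-HIT style):
#' sequences sorted by decreasing length join the first representative they
#' match at or above the identity threshold.
#'
#' @slot threshold identity threshold in (0, 1].
#' @slot members data.frame with columns \code{id}, \code{seq},
#'   \code{cluster} (representative id), \code{identity} (to the
#'   representative).
#' @slot representatives ids of cluster representatives, in cluster order.
#' @slot dropped representative ids of clusters removed as reverse-complement
#'   duplicates of a surviving cluster.
#' @export
setClass("ClusterSet", representation(
  threshold = "numeric", members = "data.frame",
  representatives = "character", dropped = "character"
))

setValidity("ClusterSet", function(object) {
  m <- object@members
  if (!all(c("id", "seq", "cluster", "identity") %in% colnames(m)))
    return("members must have id, seq, cluster, identity columns")
  if (anyDuplicated(m$id)) return("member ids must be unique")
  if (!all(m$cluster %in% c(object@representatives, object@dropped)))
    return("every member must belong to a known cluster")
  TRUE
})

#' Repeat similarity network
#'
#' Nodes are repeat consensuses; weighted edges connect pairs whose
#' orientation-aware edit distance is within the threshold.
#'
#' @slot nodes data.frame with columns \code{id}, \code{seq} and optionally
#'   \code{siteClass}.
#' @slot edges data.frame with columns \code{idA}, \code{idB},
#'   \code{distance}; each unordered pair appears once with
#'   \code{idA < idB}.
#' @slot maxDist edge threshold (inclusive).
#' @export
setClass("RepeatNetwork", representation(
  nodes = "data.frame", edges = "data.frame", maxDist = "integer"
))

setValidity("RepeatNetwork", function(object) {
  e <- object@edges
  if (nrow(e)) {
    if (any(e$idA == e$idB)) return("self-edges are not allowed")
    if (any(e$idA >= e$idB)) return("edges must be stored with idA < idB")
    if (any(e$distance > object@maxDist))
      return("all edge distances must be <= maxDist")
  }
  TRUE
})

#' Spacer sharing matrix
#'
#' Binary incidence of spacer clusters across samples, with per-cluster
#' sample and subject counts.
#'
#' @slot incidence binary matrix, rows = spacer clusters, cols = samples.
#' @slot summary data.frame with \code{cluster}, \code{nSamples},
#'   \code{nSubjects}, sorted by \code{nSubjects} decreasing.
#' @slot metadata data.frame mapping \code{sample} to \code{subject} and
#'   \code{site}.
#' @export
setClass("SharingMatrix", representation(
  incidence = "matrix", summary = "data.frame", metadata = "data.frame"
))
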