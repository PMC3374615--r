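# Catalog construction: selection filter for trusted CRISPRs, greedy
# orientation-aware identity clustering (CD-HIT style) with
# reverse-complement redundancy removal, the edit-distance repeat network,
# and body-site classification of repeats.

# orientation-aware identity: 1 - min(lev(a,b), lev(a, rc(b))) / max length
.orientedIdentity <- function(a, b) {
  1 - orientedDist(a, b)$oriented / max(nchar(a), nchar(b))
}

#' Select trusted CRISPR arrays
#'
#' Applies the catalog filter to detected arrays: the repeat consensus must
#' be 24-40 bp, there must be at least 4 complete (non-truncated) repeat
#' copies, and the complete copies must differ from the consensus by at most
#' one nucleotide on average. The bounds are inclusive.
#'
#' @param arrays list of \code{\link{CrisprArray}} objects.
#' @param params a \code{\link{selectionParams}} object.
#' @return list with \code{accepted} (the passing arrays) and \code{reasons}
#'   (character vector over all inputs: \code{"ok"}, \code{"repeat_length"},
#'   \code{"too_few_copies"}, \code{"avg_mismatch"}).
#' @export
selectCrisprs <- function(arrays, params = selectionParams()) {
  reasons <- vapply(arrays, function(a) {
    cl <- nchar(consensus(a))
    if (cl < params@minRepeatLen || cl > params@maxRepeatLen)
      return("repeat_length")
    complete <- sum(mcols(repeatRanges(a))$truncated == "none")
    if (complete < params@minCopies) return("too_few_copies")
    if (avgMismatch(a) > params@maxAvgMismatch) return("avg_mismatch")
    "ok"
  }, character(1))
  list(accepted = arrays[reasons == "ok"], reasons = reasons)
}

#' Greedy orientation-aware identity clustering
#'
#' CD-HIT-style greedy clustering of repeat (or spacer) sequences:
#' sequences sorted by decreasing length (ties: alphabetical) join the first
#' representative whose orientation-aware identity (1 - minimum-orientation
#' edit distance / longer length) is at or above the threshold; otherwise
#' they found a new cluster. Afterwards, any pair of surviving clusters
#' whose representatives are reverse complements of each other (at or above
#' the threshold) is collapsed by dropping the cluster with the
#' lexicographically larger representative, so a repeat and its reverse
#' complement never both head clusters.
#'
#' @param seqs named character vector of sequences (names are ids).
#' @param identity identity threshold in (0, 1], default 0.90.
#' @return a \code{\link{ClusterSet}}.
#' @export
clusterRepeats <- function(seqs, identity = 0.90) {
  if (!length(seqs)) stop("need at least one sequence")
  seqs <- normalizeSeq(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ord <- order(-nchar(seqs), seqs)
  seqs <- seqs[ord]
  repIds <- character(0)
  cluster <- character(length(seqs))
  ident <- numeric(length(seqs))
  for (i in seq_along(seqs)) {
    assigned <- FALSE
    for (r in repIds) {
      idt <- .orientedIdentity(seqs[[i]], seqs[[r]])
      if (idt >= identity - 1e-9) {
        cluster[i] <- r; ident[i] <- idt; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      repIds <- c(repIds, names(seqs)[i])
      cluster[i] <- names(seqs)[i]; ident[i] <- 1
    }
  }
  # reverse-complement redundancy removal between cluster representatives
  dropped <- character(0)
  if (length(repIds) > 1L) {
    for (i in seq_along(repIds)[-length(repIds)]) {
      if (repIds[i] %in% dropped) next
      for (j in (i + 1L):length(repIds)) {
        if (repIds[j] %in% dropped) next
        a <- seqs[[repIds[i]]]; b <- seqs[[repIds[j]]]
        rcIdent <- 1 - editDist(a, revComp(b)) / max(nchar(a), nchar(b))
        if (rcIdent >= identity - 1e-9)
          dropped <- c(dropped, if (a > b) repIds[i] else repIds[j])
      }
    }
  }
  members <- data.frame(id = names(seqs), seq = unname(seqs),
                        cluster = cluster, identity = ident,
                        stringsAsFactors = FALSE)
  new("ClusterSet", threshold = identity, members = members,
      representatives = setdiff(repIds, dropped), dropped = dropped)
}

#' Build the repeat similarity network
#'
#' All-pairs orientation-aware edit distances between repeat consensuses;
#' pairs within \code{maxDist} operations (mutations, insertions, deletions;
#' inclusive threshold) become weighted edges.
#'
#' @param seqs named character vector of repeat consensuses (>= 2).
#' @param maxDist edge threshold (default 10, inclusive; use
#'   \code{maxDist = 9} for a strict interpretation).
#' @return a \code{\link{RepeatNetwork}}.
#' @export
buildNetwork <- function(seqs, maxDist = 10L) {
  seqs <- normalizeSeq(seqs)
  if (length(seqs) < 2L) stop("need at least two repeats")
  if (is.null(names(seqs))) names(seqs) <- paste0("rep", seq_along(seqs))
  ids <- names(seqs)
  pairs <- utils::combn(length(seqs), 2L)
  d <- vapply(seq_len(ncol(pairs)), function(j) {
    orientedDist(seqs[[pairs[1L, j]]], seqs[[pairs[2L, j]]])$oriented
  }, integer(1))
  keep <- d <= maxDist
  a <- ids[pairs[1L, keep]]; b <- ids[pairs[2L, keep]]
  swap <- a > b
  edges <- data.frame(idA = ifelse(swap, b, a), idB = ifelse(swap, a, b),
                      distance = d[keep], stringsAsFactors = FALSE)
  edges <- edges[order(edges$idA, edges$idB), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(id = ids, seq = unname(seqs),
                      siteClass = NA_character_, stringsAsFactors = FALSE)
  new("RepeatNetwork", nodes = nodes, edges = edges,
      maxDist = as.integer(maxDist))
}

#' Classify repeats by body site
#'
#' A CRISPR found in fewer than \code{minSamples} samples overall is
#' \code{"rare"}; otherwise it is assigned to every body site in which it
#' occurs in more than \code{minFraction} of that site's samples (several
#' sites are joined with \code{"+"}); with no qualifying site it is
#' \code{"unassigned"}.
#'
#' @param counts matrix of per-site sample hits: rows = CRISPRs,
#'   columns = body sites.
#' @param siteTotals named vector of total samples per site (names matching
#'   the columns of \code{counts}).
#' @param minSamples rare threshold on the total (default 5, exclusive).
#' @param minFraction site-assignment fraction (default 0.10, exclusive).
#' @return character vector of classes, one per row of \code{counts}.
#' @export
classifyBySite <- function(counts, siteTotals, minSamples = 5L,
                           minFraction = 0.10) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts must have site column names")
  siteTotals <- siteTotals[colnames(counts)]
  if (any(is.na(siteTotals)) || any(siteTotals <= 0))
    stop("every site needs a positive sample total")
  apply(counts, 1L, function(row) {
    if (sum(row) < minSamples) return("rare")
    sites <- colnames(counts)[row / siteTotals > minFraction]
    if (!length(sites)) "unassigned" else paste(sort(sites), collapse = "+")
  })
}

#' Write a repeat network as TSV and GraphML
#'
#' @param network a \code{\link{RepeatNetwork}}.
#' @param tsv path for the edge-list TSV (columns idA, idB, distance);
#'   \code{NULL} to skip.
#' @param graphml path for a GraphML export (with siteClass node attribute);
#'   \code{NULL} to skip.
#' @return invisibly, the paths written.
#' @export
writeNetwork <- function(network, tsv = NULL, graphml = NULL) {
  written <- character(0)
  if (!is.null(tsv)) {
    utils::write.table(networkEdges(network), tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- c(written, tsv)
  }
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(
      networkEdges(network), directed = FALSE,
      vertices = networkNodes(network))
    igraph::write_graph(g, graphml, format = "graphml")
    written <- c(written, graphml)
  }
  invisible(written)
}
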