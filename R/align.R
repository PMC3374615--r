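# Similarity-search array detection: find windows of a target matching a
# query repeat consensus within a mismatch budget on either strand, chain
# them into arrays, and test repeat novelty against reference genomes.

#' Scan a target for a query repeat
#'
#' Reports every full-length window of the target (both strands) matching
#' the query within \code{maxMm} mismatches, equivalent to a brute-force
#' sliding scan. Overlapping same-strand hits whose starts lie within half a
#' query length of each other are reduced to the lowest-mismatch one (ties:
#' leftmost).
#'
#' @param target target sequence (single string or \code{DNAStringSet} of
#'   length 1).
#' @param query query repeat sequence (single string).
#' @param maxMm maximum number of mismatches.
#' @param targetId name used in the output.
#' @return data.frame with columns \code{targetId}, \code{start}, \code{end}
#'   (1-based inclusive), \code{strand}, \code{mismatches}, sorted by start.
#' @export
scanRepeat <- function(target, query, maxMm = 4L, targetId = "target") {
  target <- .asSingleSeq(target)
  query <- normalizeSeq(query)
  m <- nchar(query)
  if (nchar(target) < m) {
    message("target shorter than query; no hits")
    return(.emptyHits())
  }
  hitRows <- function(q, strand) {
    mm <- mismatchScan(target, q)
    i <- which(mm <= maxMm)
    if (!length(i)) return(NULL)
    data.frame(targetId = targetId, start = i, end = i + m - 1L,
               strand = strand, mismatches = mm[i],
               stringsAsFactors = FALSE)
  }
  hits <- rbind(hitRows(query, "+"), hitRows(revComp(query), "-"))
  if (is.null(hits) || !nrow(hits)) return(.emptyHits())
  hits <- do.call(rbind, lapply(split(hits, hits$strand), .reduceOverlaps,
                                qlen = m))
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

.emptyHits <- function() {
  data.frame(targetId = character(0), start = integer(0), end = integer(0),
             strand = character(0), mismatches = integer(0),
             stringsAsFactors = FALSE)
}

# greedy same-strand reduction: cluster hits whose consecutive starts differ
# by less than qlen/2, keep the lowest-mismatch hit (ties: leftmost)
.reduceOverlaps <- function(hits, qlen) {
  if (nrow(hits) < 2L) return(hits)
  hits <- hits[order(hits$start), , drop = FALSE]
  grp <- cumsum(c(1L, as.integer(diff(hits$start) >= qlen / 2)))
  keep <- vapply(split(seq_len(nrow(hits)), grp), function(ix) {
    ix[which.min(hits$mismatches[ix])]
  }, integer(1))
  hits[sort(keep), , drop = FALSE]
}

#' Chain repeat hits into CRISPR arrays
#'
#' Consecutive same-strand hits whose gaps (the spacers) lie within the
#' configured spacer length bounds are chained; chains of at least two
#' repeat elements become arrays. Spacer similarity/size rules from
#' \code{\link{validateArray}} are applied, and truncated boundary copies
#' are recovered as in de novo detection.
#'
#' @param hits data.frame from \code{\link{scanRepeat}} on one target.
#' @param target the target sequence.
#' @param params a \code{\link{detectParams}} object.
#' @param queryLen query length (inferred from hits when omitted).
#' @param attachTruncated recover truncated boundary copies (default TRUE).
#' @param targetId contig id for the resulting arrays.
#' @return list of \code{\link{CrisprArray}} objects.
#' @export
hitsToArrays <- function(hits, target, params = detectParams(),
                         queryLen = NULL, attachTruncated = TRUE,
                         targetId = "target") {
  target <- .asSingleSeq(target)
  if (!nrow(hits)) return(list())
  if (is.null(queryLen)) queryLen <- hits$end[1L] - hits$start[1L] + 1L
  out <- list()
  for (strand in unique(hits$strand)) {
    h <- hits[hits$strand == strand, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    gaps <- h$start[-1L] - h$end[-nrow(h)] - 1L
    ok <- gaps >= params@minSpacerLen & gaps <= params@maxSpacerLen
    brk <- c(0L, which(!ok), nrow(h))
    for (i in seq_len(length(brk) - 1L)) {
      ix <- (brk[i] + 1L):brk[i + 1L]
      if (length(ix) < 2L) next
      hh <- h[ix, , drop = FALSE]
      copies <- substring(target, hh$start, hh$end)
      if (strand == "-") copies <- revComp(copies)
      cons <- columnConsensus(copies)
      mism <- vapply(copies, hammingDist, integer(1), b = cons,
                     USE.NAMES = FALSE)
      rep <- IRanges(hh$start, hh$end)
      mcols(rep) <- DataFrame(strand = rep(strand, nrow(hh)),
                              mismatches = mism,
                              truncated = rep("none", nrow(hh)))
      sp <- IRanges(head(hh$end, -1L) + 1L, tail(hh$start, -1L) - 1L)
      arr <- .newCrisprArray(targetId, rep, sp, cons, mean(mism))
      if (!validateArray(arr, target, params, checkCopies = FALSE)$accept)
        next
      if (attachTruncated)
        arr <- attachTruncatedEnds(arr, target, params)
      out[[length(out) + 1L]] <- arr
    }
  }
  starts <- vapply(out, function(a) min(start(repeatRanges(a))), numeric(1))
  out[order(starts)]
}

#' Test whether a query repeat is novel
#'
#' A repeat is novel with respect to a reference collection if no reference
#' contains an array of that repeat (a chain of at least two repeat
#' elements) within the mismatch budget. Isolated single hits do not count
#' as instances.
#'
#' @param query query repeat sequence (single string).
#' @param references named character vector or \code{DNAStringSet} of
#'   reference sequences.
#' @param maxMm mismatch budget (default 4).
#' @param params a \code{\link{detectParams}} object for chaining.
#' @return list with \code{novel} (logical) and \code{witness} (a
#'   single-row hit data.frame when not novel, otherwise \code{NULL}).
#' @export
isNovel <- function(query, references, maxMm = 4L, params = detectParams()) {
  if (is(references, "DNAStringSet"))
    references <- setNames(as.character(references), names(references))
  if (!length(references)) stop("references must be non-empty")
  if (is.null(names(references)))
    names(references) <- paste0("ref", seq_along(references))
  for (id in names(references)) {
    hits <- scanRepeat(references[[id]], query, maxMm = maxMm,
                       targetId = id)
    if (nrow(hits) < 2L) next
    arrays <- hitsToArrays(hits, references[[id]], params,
                           queryLen = nchar(query),
                           attachTruncated = FALSE, targetId = id)
    if (length(arrays)) {
      a <- arrays[[1L]]
      r <- repeatRanges(a)[1L]
      witness <- data.frame(targetId = id, start = start(r), end = end(r),
                            strand = mcols(r)$strand,
                            mismatches = mcols(r)$mismatches,
                            stringsAsFactors = FALSE)
      return(list(novel = FALSE, witness = witness))
    }
  }
  list(novel = TRUE, witness = NULL)
}
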