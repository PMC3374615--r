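# De novo CRISPR array detection on contigs, CRT-style: exact k-mer seeds
# recurring at spacer-like intervals, column-consensus boundary extension,
# structural validation, and recovery of incomplete repeats at contig ends.

# identity between two sequences, forward orientation, denominator = longer
.seqIdentity <- function(a, b) {
  1 - editDist(a, b) / pmax(nchar(a), nchar(b))
}

#' Find seed chains of candidate repeats
#'
#' Locates exact \code{seedLen}-mers that recur along the contig with
#' consecutive gaps inside the window implied by the repeat and spacer length
#' bounds (a repeat-plus-spacer period). Each maximal run with at least
#' \code{minCopies} occurrences becomes a candidate chain.
#'
#' @param contig a single sequence string (or \code{DNAStringSet} of length
#'   1).
#' @param params a \code{\link{detectParams}} object.
#' @return list of chains; each chain is a list with \code{kmer} and
#'   \code{starts} (1-based seed start positions).
#' @export
findSeedChains <- function(contig, params = detectParams()) {
  contig <- .asSingleSeq(contig)
  n <- nchar(contig)
  k <- params@seedLen
  minGap <- params@minRepeatLen + params@minSpacerLen
  maxGap <- params@maxRepeatLen + params@maxSpacerLen
  if (n < 2L * params@minRepeatLen + params@minSpacerLen) {
    message("contig shorter than two repeats plus a spacer; no chains")
    return(list())
  }
  kmers <- substring(contig, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE)
  pos <- seq_len(n - k + 1L)[keep]
  occ <- split(pos, kmers[keep])
  occ <- occ[lengths(occ) >= params@minCopies]
  chains <- list()
  for (km in names(occ)) {
    p <- occ[[km]]
    gaps <- diff(p)
    ok <- gaps >= minGap & gaps <= maxGap
    # split into maximal runs of in-window gaps
    brk <- c(0L, which(!ok), length(p))
    for (i in seq_len(length(brk) - 1L)) {
      run <- p[(brk[i] + 1L):brk[i + 1L]]
      if (length(run) >= params@minCopies)
        chains[[length(chains) + 1L]] <- list(kmer = km, starts = run)
    }
  }
  chains
}

#' Extend a seed chain into a candidate array
#'
#' Repeat boundaries are pushed outward from the exact seed, one column at a
#' time, while the fraction of copies agreeing with the column-majority base
#' stays at or above \code{columnAgreement}, the repeat stays within the
#' length bounds, copies stay inside the contig, and at least one spacer
#' base remains between adjacent copies. The consensus is the column-majority
#' consensus over the copies.
#'
#' @param chain one element of \code{\link{findSeedChains}} output.
#' @param contig the contig the chain was found on.
#' @param params a \code{\link{detectParams}} object.
#' @param contigId contig name used in the resulting array.
#' @return a candidate \code{\link{CrisprArray}} (not yet validated).
#' @export
extendAndRefine <- function(chain, contig, params = detectParams(),
                            contigId = "contig") {
  contig <- .asSingleSeq(contig)
  n <- nchar(contig)
  k <- params@seedLen
  starts <- chain$starts
  nc <- length(starts)
  maxBoth <- min(diff(starts)) - k  # left+right extension budget (>=1 spacer)
  colAgree <- function(positions) {
    bases <- substring(contig, positions, positions)
    bases <- bases[bases != "N"]
    if (!length(bases)) return(FALSE)
    max(table(bases)) / nc >= params@columnAgreement
  }
  L <- 0L; R <- 0L
  # left extension
  while (k + L + R < params@maxRepeatLen && L + R < maxBoth - 1L &&
         starts[1L] - L - 1L >= 1L && colAgree(starts - L - 1L)) {
    L <- L + 1L
  }
  # right extension
  while (k + L + R < params@maxRepeatLen && L + R < maxBoth - 1L &&
         starts[nc] + k + R <= n && colAgree(starts + k + R)) {
    R <- R + 1L
  }
  rstart <- starts - L
  rend <- starts + k - 1L + R
  copies <- substring(contig, rstart, rend)
  cons <- columnConsensus(copies)
  mism <- vapply(copies, hammingDist, integer(1), b = cons, USE.NAMES = FALSE)
  rep <- IRanges(rstart, rend)
  mcols(rep) <- DataFrame(strand = rep("+", nc), mismatches = mism,
                          truncated = rep("none", nc))
  sp <- IRanges(head(rend, -1L) + 1L, tail(rstart, -1L) - 1L)
  .newCrisprArray(contigId, rep, sp, cons, mean(mism))
}

#' Validate a candidate CRISPR array
#'
#' Structural acceptance rules: enough repeat copies; consensus length in
#' bounds; every spacer length in bounds; spacers similarly sized (max/min
#' length ratio within \code{spacerLenRatioMax}); spacers non-repeating (no
#' pair at or above \code{spacerIdentityMax} identity) and dissimilar from
#' the repeat consensus.
#'
#' @param candidate a \code{\link{CrisprArray}}.
#' @param contig the contig sequence the array lies on.
#' @param params a \code{\link{detectParams}} object.
#' @param checkCopies if \code{FALSE} the copy-count rule is skipped (used
#'   when chaining similarity-search hits, where two copies suffice).
#' @return list with \code{accept} (logical) and \code{reason}, one of
#'   \code{"ok"}, \code{"too_few_copies"}, \code{"repeat_length"},
#'   \code{"spacer_length"}, \code{"spacer_size"},
#'   \code{"repeating_spacers"}, \code{"spacer_like_repeat"}.
#' @export
validateArray <- function(candidate, contig, params = detectParams(),
                          checkCopies = TRUE) {
  contig <- .asSingleSeq(contig)
  rej <- function(reason) list(accept = FALSE, reason = reason)
  if (checkCopies && nRepeats(candidate) < params@minCopies)
    return(rej("too_few_copies"))
  cl <- nchar(consensus(candidate))
  if (cl < params@minRepeatLen || cl > params@maxRepeatLen)
    return(rej("repeat_length"))
  sp <- spacerRanges(candidate)
  if (length(sp)) {
    w <- width(sp)
    if (any(w < params@minSpacerLen | w > params@maxSpacerLen))
      return(rej("spacer_length"))
    if (max(w) > params@spacerLenRatioMax * min(w))
      return(rej("spacer_size"))
    sseq <- substring(contig, start(sp), end(sp))
    if (length(sseq) > 1L) {
      pairs <- utils::combn(length(sseq), 2L)
      for (j in seq_len(ncol(pairs))) {
        if (.seqIdentity(sseq[pairs[1L, j]], sseq[pairs[2L, j]]) >=
            params@spacerIdentityMax)
          return(rej("repeating_spacers"))
      }
    }
    if (any(.seqIdentity(sseq, consensus(candidate)) >=
            params@spacerIdentityMax))
      return(rej("spacer_like_repeat"))
  }
  list(accept = TRUE, reason = "ok")
}

#' Recover incomplete repeats at contig ends
#'
#' A CRISPR locus cut by a contig boundary leaves a partial repeat copy at
#' the contig end. If the flank beyond the terminal repeat is short enough to
#' lie within one spacer-plus-repeat period, the contig end is tested for a
#' fragment of the consensus (at least 5 bp, with a mismatch budget prorated
#' from the 3-mismatch full-repeat budget); a matching fragment is attached
#' as a truncated repeat copy.
#'
#' @param array an accepted \code{\link{CrisprArray}}.
#' @param contig the contig sequence.
#' @param params a \code{\link{detectParams}} object.
#' @param minFragment minimum anchored fragment length.
#' @return the array, possibly with a truncated copy attached at either end.
#' @export
attachTruncatedEnds <- function(array, contig, params = detectParams(),
                                minFragment = 5L) {
  contig <- .asSingleSeq(contig)
  n <- nchar(contig)
  rep <- repeatRanges(array)
  sp <- spacerRanges(array)
  cons <- consensus(array)
  replen <- nchar(cons)
  strand <- mcols(rep)$strand[1L]
  tfc <- if (strand == "+") cons else revComp(cons)  # target-forward consensus

  findFragment <- function(avail, takeSuffix) {
    # avail: flank length; fragment length m leaves a spacer of avail - m
    ms <- seq(min(replen - 1L, avail - params@minSpacerLen),
              max(minFragment, avail - params@maxSpacerLen))
    ms <- ms[ms >= minFragment & ms < replen]
    for (m in ms) {
      frag <- if (takeSuffix) substr(contig, 1L, m)
              else substr(contig, n - m + 1L, n)
      ref <- if (takeSuffix) substr(tfc, replen - m + 1L, replen)
             else substr(tfc, 1L, m)
      mm <- hammingDist(frag, ref)
      if (mm <= ceiling(3 * m / replen)) return(c(m = m, mm = mm))
    }
    NULL
  }

  preLen <- min(start(rep)) - 1L
  if (preLen >= params@minSpacerLen + minFragment &&
      preLen < params@maxSpacerLen + replen) {
    hit <- findFragment(preLen, takeSuffix = TRUE)
    if (!is.null(hit)) {
      m <- hit[["m"]]
      newRep <- c(IRanges(1L, m), rep)
      mcols(newRep) <- rbind(
        DataFrame(strand = strand, mismatches = hit[["mm"]],
                  truncated = "left"),
        mcols(rep))
      sp <- c(IRanges(m + 1L, min(start(rep)) - 1L), sp)
      rep <- newRep
    }
  }
  sufLen <- n - max(end(rep))
  if (sufLen >= params@minSpacerLen + minFragment &&
      sufLen < params@maxSpacerLen + replen) {
    hit <- findFragment(sufLen, takeSuffix = FALSE)
    if (!is.null(hit)) {
      m <- hit[["m"]]
      sp <- c(sp, IRanges(max(end(rep)) + 1L, n - m))
      newRep <- c(rep, IRanges(n - m + 1L, n))
      mcols(newRep) <- rbind(
        mcols(rep),
        DataFrame(strand = strand, mismatches = hit[["mm"]],
                  truncated = "right"))
      rep <- newRep
    }
  }
  compl <- mcols(rep)$truncated == "none"
  .newCrisprArray(contigId(array), rep, sp, cons,
                  mean(mcols(rep)$mismatches[compl]))
}

# boundary refinement over the full copy set: drop terminal copies beyond
# the 3-mismatch repeat budget (coincidental seed matches), extend repeat
# edges outward while column agreement holds, then trim terminal columns
# below a stricter agreement bar (with few copies a random spacer column
# reaches 3-of-4 agreement ~20% of the time, so trimming demands more than
# the extension threshold). Contig-coordinate operation; single-strand
# arrays only (which chained arrays always are).
.refineBoundaries <- function(array, contig, params, copyBudget = 3L) {
  rep <- repeatRanges(array)
  n <- length(rep)
  strand <- mcols(rep)$strand[1L]
  rs <- start(rep); re <- end(rep)
  cl <- nchar(contig)
  # prune junk terminal copies
  repeat {
    if (n <= 2L) break
    copies <- substring(contig, rs, re)
    if (strand == "-") copies <- revComp(copies)
    cons <- columnConsensus(copies)
    mism <- vapply(copies, hammingDist, integer(1), b = cons,
                   USE.NAMES = FALSE)
    if (mism[1L] > copyBudget) {
      rs <- rs[-1L]; re <- re[-1L]; n <- n - 1L
    } else if (mism[n] > copyBudget) {
      rs <- rs[-n]; re <- re[-n]; n <- n - 1L
    } else break
  }
  agree <- function(pos) {
    if (any(pos < 1L | pos > cl)) return(0)
    bases <- substring(contig, pos, pos)
    bases <- bases[bases != "N"]
    if (!length(bases)) return(0)
    max(table(bases)) / n
  }
  replen <- function() re[1L] - rs[1L] + 1L
  canLeft <- function() rs[1L] > 1L &&
    (n == 1L || all(rs[-1L] - 1L > re[-n] + 1L))
  canRight <- function() re[n] < cl &&
    (n == 1L || all(re[-n] + 1L < rs[-1L] - 1L))
  while (replen() < params@maxRepeatLen && canLeft() &&
         agree(rs - 1L) >= params@columnAgreement) rs <- rs - 1L
  while (replen() < params@maxRepeatLen && canRight() &&
         agree(re + 1L) >= params@columnAgreement) re <- re + 1L
  trimThr <- min(1, params@columnAgreement + 0.75 / n)
  while (replen() > params@minRepeatLen && agree(rs) < trimThr)
    rs <- rs + 1L
  while (replen() > params@minRepeatLen && agree(re) < trimThr)
    re <- re - 1L
  copies <- substring(contig, rs, re)
  if (strand == "-") copies <- revComp(copies)
  cons <- columnConsensus(copies)
  mism <- vapply(copies, hammingDist, integer(1), b = cons,
                 USE.NAMES = FALSE)
  newRep <- IRanges(rs, re)
  mcols(newRep) <- DataFrame(strand = rep.int(strand, n),
                             mismatches = mism,
                             truncated = rep.int("none", n))
  sp <- if (n > 1L) IRanges(re[-n] + 1L, rs[-1L] - 1L) else IRanges()
  .newCrisprArray(contigId(array), newRep, sp, cons, mean(mism))
}

# a partial repeat copy at a contig edge can join the seed chain and cap
# boundary extension, shortening the consensus; if dropping the edge copy
# lets the consensus grow, the copy was truncated, and attachTruncatedEnds
# will re-attach it with the proper flag
.recoverEdgeTruncation <- function(array, contig, params) {
  dropCopy <- function(a, which) {
    r <- repeatRanges(a)
    n <- length(r)
    keep <- if (which == "first") 2L:n else seq_len(n - 1L)
    spKeep <- if (which == "first") seq_len(n - 1L)[-1L] else
      seq_len(n - 1L)[-(n - 1L)]
    .newCrisprArray(contigId(a), r[keep], spacerRanges(a)[spKeep],
                    consensus(a), avgMismatch(a))
  }
  tryVariant <- function(a, which) {
    if (nRepeats(a) < 3L) return(a)
    b <- .refineBoundaries(dropCopy(a, which), contig, params)
    if (nchar(consensus(b)) > nchar(consensus(a)) &&
        validateArray(b, contig, params, checkCopies = FALSE)$accept) b
    else a
  }
  r <- repeatRanges(array)
  if (start(r)[1L] == 1L)
    array <- tryVariant(array, "first")
  r <- repeatRanges(array)
  if (end(r)[length(r)] == nchar(contig))
    array <- tryVariant(array, "last")
  array
}

#' De novo CRISPR detection on a contig
#'
#' Composition of seed chaining, boundary extension, validation, consensus
#' re-scanning and truncated-end recovery. Candidate arrays from different
#' seeds of the same locus are deduplicated; overlapping candidates are
#' resolved by keeping the one with more copies, then the longer span, then
#' the leftmost. Deterministic for fixed input and parameters.
#'
#' @param contig a single sequence string or \code{DNAStringSet} of length 1;
#'   a name on the input is used as the contig id.
#' @param params a \code{\link{detectParams}} object.
#' @param contigId contig name; defaults to the input's name or "contig".
#' @param rescan if \code{TRUE} (default), each accepted candidate's
#'   consensus is re-scanned against the contig (3-mismatch budget) so that
#'   copies missed by the exact seed are recovered.
#' @return list of \code{\link{CrisprArray}} objects, sorted by start.
#' @export
findCrisprs <- function(contig, params = detectParams(), contigId = NULL,
                        rescan = TRUE) {
  if (is.null(contigId))
    contigId <- if (!is.null(names(contig))) names(contig)[1L] else "contig"
  contig <- .asSingleSeq(contig)
  chains <- findSeedChains(contig, params)
  if (!length(chains)) return(list())
  cands <- lapply(chains, extendAndRefine, contig = contig, params = params,
                  contigId = contigId)
  # dedupe identical candidates (many seeds per locus converge)
  key <- vapply(cands, function(a) {
    paste(min(start(repeatRanges(a))), max(end(repeatRanges(a))),
          consensus(a), sep = ":")
  }, character(1))
  cands <- cands[!duplicated(key)]
  ok <- vapply(cands, function(a)
    validateArray(a, contig, params)$accept, logical(1))
  cands <- cands[ok]
  if (!length(cands)) return(list())
  if (rescan) {
    cands <- lapply(cands, function(a) {
      hits <- scanRepeat(contig, consensus(a), maxMm = 3L,
                         targetId = contigId)
      arrays <- hitsToArrays(hits, contig, params, queryLen =
                               nchar(consensus(a)), attachTruncated = FALSE,
                             targetId = contigId)
      if (!length(arrays)) return(a)
      # keep the re-scanned array overlapping this candidate, if better
      spanA <- c(min(start(repeatRanges(a))), max(end(repeatRanges(a))))
      best <- a
      for (b in arrays) {
        spanB <- c(min(start(repeatRanges(b))), max(end(repeatRanges(b))))
        if (spanB[1L] <= spanA[2L] && spanB[2L] >= spanA[1L] &&
            nRepeats(b) >= nRepeats(best) &&
            validateArray(b, contig, params)$accept)
          best <- b
      }
      best
    })
    cands <- lapply(cands, function(a) {
      b <- .refineBoundaries(a, contig, params)
      if (validateArray(b, contig, params)$accept) b else a
    })
    cands <- lapply(cands, .recoverEdgeTruncation, contig = contig,
                    params = params)
    key <- vapply(cands, function(a) {
      paste(min(start(repeatRanges(a))), max(end(repeatRanges(a))),
            consensus(a), sep = ":")
    }, character(1))
    cands <- cands[!duplicated(key)]
  }
  # overlap resolution: copies desc, span desc, leftmost
  spans <- t(vapply(cands, function(a)
    c(min(start(repeatRanges(a))), max(end(repeatRanges(a)))), numeric(2)))
  ord <- order(-vapply(cands, nRepeats, integer(1)),
               -(spans[, 2L] - spans[, 1L]), spans[, 1L])
  keep <- logical(length(cands))
  for (i in ord) {
    if (!any(keep & spans[, 1L] <= spans[i, 2L] &
             spans[, 2L] >= spans[i, 1L])) keep[i] <- TRUE
  }
  cands <- cands[keep]
  cands <- lapply(cands, attachTruncatedEnds, contig = contig,
                  params = params)
  starts <- vapply(cands, function(a) min(start(repeatRanges(a))), numeric(1))
  cands[order(starts)]
}

.asSingleSeq <- function(x) {
  if (is(x, "DNAStringSet")) x <- as.character(x[[1L]])
  else if (is(x, "DNAString")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L)
    stop("expected a single sequence")
  normalizeSeq(x)
}
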