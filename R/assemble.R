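# Targeted assembly of CRISPR loci: recruit the reads that carry a query
# repeat, assemble them with a long-k de Bruijn graph (long k-mers resolve
# the repeat structure that defeats whole-metagenome assembly), and extract
# arrays and spacers from the resulting contigs.

#' Recruit reads containing a query repeat
#'
#' A read is recruited iff some full-length window on either strand matches
#' the query with at most \code{maxMm} mismatches (equivalent to a
#' brute-force scan). Reads shorter than the query are skipped and counted.
#' Input order is preserved.
#'
#' @param reads \code{DNAStringSet} (or named character vector) of
#'   single-end reads.
#' @param query query repeat sequence (single string).
#' @param maxMm per-read mismatch budget over the entire repeat (default 3).
#' @param queryId,sampleId ids recorded on the result.
#' @return a \code{\link{RecruitedReadSet}}.
#' @export
recruitReads <- function(reads, query, maxMm = 3L, queryId = "query",
                         sampleId = "sample") {
  if (is.character(reads)) reads <- DNAStringSet(normalizeSeq(reads))
  query <- normalizeSeq(query)
  m <- nchar(query)
  longEnough <- width(reads) >= m
  nTooShort <- sum(!longEnough)
  if (nTooShort > 0L)
    warning(nTooShort, " read(s) shorter than the query repeat were skipped")
  cand <- reads[longEnough]
  if (!length(cand)) {
    if (length(reads)) warning("no read long enough to contain the repeat")
    return(new("RecruitedReadSet", queryId = queryId, sampleId = sampleId,
               reads = DNAStringSet(), hits = DataFrame(
                 pos = integer(0), strand = character(0),
                 mismatches = integer(0)),
               nInput = length(reads), nTooShort = nTooShort))
  }
  if (grepl("N", query, fixed = TRUE)) {
    # N in the query never matches; fall back to the explicit scanner
    sel <- vapply(as.character(cand), function(r) {
      any(mismatchScan(r, query) <= maxMm) ||
        any(mismatchScan(r, revComp(query)) <= maxMm)
    }, logical(1), USE.NAMES = FALSE)
  } else {
    sel <- vcountPattern(query, cand, max.mismatch = maxMm) > 0L |
      vcountPattern(revComp(query), cand, max.mismatch = maxMm) > 0L
  }
  rec <- cand[sel]
  best <- lapply(as.character(rec), function(r) {
    fw <- mismatchScan(r, query)
    rv <- mismatchScan(r, revComp(query))
    if (min(fw) <= min(rv))
      c(pos = which.min(fw), strand = 1L, mm = min(fw))
    else c(pos = which.min(rv), strand = 2L, mm = min(rv))
  })
  hits <- DataFrame(
    pos = unname(vapply(best, `[[`, integer(1), "pos")),
    strand = c("+", "-")[unname(vapply(best, `[[`, integer(1), "strand"))],
    mismatches = unname(vapply(best, `[[`, integer(1), "mm")))
  new("RecruitedReadSet", queryId = queryId, sampleId = sampleId,
      reads = rec, hits = hits, nInput = length(reads),
      nTooShort = nTooShort)
}

.canonicalKmers <- function(kmers) {
  rc <- as.character(reverseComplement(DNAStringSet(kmers)))
  ifelse(kmers <= rc, kmers, rc)
}

#' Build a de Bruijn graph from recruited reads
#'
#' Counts canonical k-mers (lexicographic minimum of a k-mer and its
#' reverse complement; recruitment captures both strands) across the reads
#' and drops k-mers below \code{minCount}, the usual guard against
#' sequencing-error k-mers.
#'
#' @param readset a \code{\link{RecruitedReadSet}} or \code{DNAStringSet}.
#' @param k k-mer length (default 45; long k-mers span repeat-spacer
#'   junctions uniquely).
#' @param minCount minimum k-mer multiplicity kept (default 2; use 1 for
#'   very low coverage).
#' @return a \code{\link{DeBruijnGraph}}.
#' @export
buildGraph <- function(readset, k = 45L, minCount = 2L) {
  reads <- if (is(readset, "RecruitedReadSet")) readset@reads else readset
  if (is.character(reads)) reads <- DNAStringSet(normalizeSeq(reads))
  k <- as.integer(k)
  usable <- as.character(reads[width(reads) >= k])
  if (!length(usable))
    stop("no read of length >= k=", k,
         "; use a smaller k for these read lengths")
  kmers <- unlist(lapply(usable, function(r) {
    n <- nchar(r)
    substring(r, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  }), use.names = FALSE)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  tab <- table(.canonicalKmers(kmers))
  counts <- setNames(as.integer(tab), names(tab))
  counts <- counts[counts >= minCount]
  new("DeBruijnGraph", k = k, counts = counts)
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

# unitigs of a node-centric canonical-kmer graph; returns list of
# list(seq, nodes) where nodes indexes into the kmer vector
.unitigs <- function(kmers, k) {
  n <- length(kmers)
  if (!n) return(list())
  rcK <- as.character(reverseComplement(DNAStringSet(kmers)))
  env <- list2env(setNames(as.list(seq_len(n)), kmers), hash = TRUE,
                  size = n * 2L)
  lookup <- function(km) {
    v <- env[[km]]
    if (is.null(v)) NA_integer_ else v
  }
  oriented <- function(i, s) if (s > 0L) kmers[i] else rcK[i]
  # successors of node i in orientation s: list of c(j, s')
  outs <- function(i, s) {
    x <- oriented(i, s)
    xr <- oriented(i, -s)
    suff <- substr(x, 2L, k)
    pre_rc <- substr(xr, 1L, k - 1L)
    res <- list()
    for (b in c("A", "C", "G", "T")) {
      y <- paste0(suff, b)
      yr <- paste0(.COMP[[b]], pre_rc)
      cy <- if (y <= yr) y else yr
      j <- lookup(cy)
      if (!is.na(j)) res[[length(res) + 1L]] <- c(j, if (y <= yr) 1L else -1L)
    }
    res
  }
  visited <- logical(n)
  unitigs <- list()
  for (seed in seq_len(n)) {
    if (visited[seed]) next
    nodes <- seed; ors <- 1L
    visited[seed] <- TRUE
    # extend right
    repeat {
      cur <- nodes[length(nodes)]; s <- ors[length(ors)]
      nx <- outs(cur, s)
      if (length(nx) != 1L) break
      j <- nx[[1L]][1L]; s2 <- nx[[1L]][2L]
      if (visited[j]) break
      back <- outs(j, -s2)
      if (length(back) != 1L) break
      nodes <- c(nodes, j); ors <- c(ors, s2)
      visited[j] <- TRUE
    }
    # extend left
    repeat {
      cur <- nodes[1L]; s <- ors[1L]
      pv <- outs(cur, -s)  # in-neighbors, flipped
      if (length(pv) != 1L) break
      j <- pv[[1L]][1L]; s2 <- -pv[[1L]][2L]
      if (visited[j]) break
      fwd <- outs(j, s2)
      if (length(fwd) != 1L) break
      nodes <- c(j, nodes); ors <- c(s2, ors)
      visited[j] <- TRUE
    }
    seq <- oriented(nodes[1L], ors[1L])
    if (length(nodes) > 1L)
      seq <- paste0(seq, paste(vapply(seq_along(nodes)[-1L], function(t)
        substr(oriented(nodes[t], ors[t]), k, k), character(1)),
        collapse = ""))
    ends <- list(left = list(node = nodes[1L], s = ors[1L]),
                 right = list(node = nodes[length(nodes)],
                              s = ors[length(ors)]))
    unitigs[[length(unitigs) + 1L]] <- list(seq = seq, nodes = nodes,
                                            ends = ends)
  }
  attr(unitigs, "outs") <- outs
  unitigs
}

#' Assemble contigs from a de Bruijn graph
#'
#' Contigs are maximal non-branching paths (unitigs). Tips -- unitigs with a
#' dead end on exactly one side -- shorter than \code{2k} are clipped and the
#' graph recompacted. Contigs are reported in canonical orientation
#' (lexicographic minimum of the sequence and its reverse complement),
#' ordered by decreasing length then sequence, which makes the assembly
#' deterministic.
#'
#' @param graph a \code{\link{DeBruijnGraph}}.
#' @param clipTips clip short dead-end unitigs (default TRUE).
#' @param maxRounds maximum tip-clipping rounds.
#' @return \code{DNAStringSet} of contigs with
#'   \code{mcols()$meanKmerCoverage}.
#' @export
assembleContigs <- function(graph, clipTips = TRUE, maxRounds = 3L) {
  counts <- graph@counts
  k <- graph@k
  if (!length(counts)) stop("empty graph")
  round <- 0L
  repeat {
    uni <- .unitigs(names(counts), k)
    round <- round + 1L
    if (!clipTips || round > maxRounds || length(uni) < 2L) break
    outs <- attr(uni, "outs")
    tip <- vapply(uni, function(u) {
      degL <- length(outs(u$ends$left$node, -u$ends$left$s))
      degR <- length(outs(u$ends$right$node, u$ends$right$s))
      xor(degL == 0L, degR == 0L) && nchar(u$seq) < 2L * k
    }, logical(1))
    if (!any(tip)) break
    drop <- unlist(lapply(uni[tip], `[[`, "nodes"))
    counts <- counts[-drop]
    if (!length(counts)) break
  }
  if (!length(counts)) return(DNAStringSet())
  seqs <- vapply(uni, `[[`, character(1), "seq")
  cov <- vapply(uni, function(u) mean(counts[u$nodes]), numeric(1))
  rc <- revComp(seqs)
  canon <- ifelse(seqs <= rc, seqs, rc)
  ord <- order(-nchar(canon), canon)
  out <- DNAStringSet(canon[ord])
  names(out) <- paste0("contig", seq_along(out))
  mcols(out)$meanKmerCoverage <- cov[ord]
  out
}

#' Extract spacer sequences from an array
#'
#' @param array a \code{\link{CrisprArray}} located on \code{contig}.
#' @param contig the contig sequence the array lies on.
#' @param prefix id prefix for the spacer names.
#' @return \code{DNAStringSet} of spacers in array order, named
#'   \code{<prefix>_s<i>}.
#' @export
extractSpacers <- function(array, contig, prefix = contigId(array)) {
  contig <- .asSingleSeq(contig)
  sp <- spacerRanges(array)
  if (length(sp) && max(end(sp)) > nchar(contig))
    stop("internal consistency error: spacer extends beyond the contig")
  seqs <- substring(contig, start(sp), end(sp))
  out <- DNAStringSet(seqs)
  if (length(out)) names(out) <- paste0(prefix, "_s", seq_along(out))
  out
}

#' Targeted assembly pipeline for one query repeat and one sample
#'
#' Recruits reads containing the query repeat, assembles them, re-orients
#' each contig so the query matches the forward strand, locates arrays by
#' similarity search and extracts the spacers. Contigs without a repeat hit
#' are suppressed and counted.
#'
#' @param reads \code{DNAStringSet} of single-end reads.
#' @param query query repeat sequence.
#' @param params a \code{\link{detectParams}} object for array chaining.
#' @param k,minCount assembler parameters, see \code{\link{buildGraph}}.
#' @param maxMm recruitment and scanning mismatch budget (default 3).
#' @param queryId,sampleId ids used in outputs.
#' @return list with \code{readset}, \code{contigs} (\code{DNAStringSet},
#'   re-oriented), \code{arrays} (list of \code{CrisprArray}),
#'   \code{spacers} (\code{DNAStringSet}), \code{nSuppressedContigs} and
#'   \code{summary} (one-row data.frame: queryId, sampleId,
#'   nReadsRecruited, nContigs, maxSpacersPerContig, totalSpacers).
#' @export
targetedAssembly <- function(reads, query, params = detectParams(),
                             k = 45L, minCount = 2L, maxMm = 3L,
                             queryId = "query", sampleId = "sample") {
  query <- normalizeSeq(query)
  rs <- recruitReads(reads, query, maxMm = maxMm, queryId = queryId,
                     sampleId = sampleId)
  emptyRes <- function() list(
    readset = rs, contigs = DNAStringSet(), arrays = list(),
    spacers = DNAStringSet(), nSuppressedContigs = 0L,
    summary = data.frame(queryId = queryId, sampleId = sampleId,
                         nReadsRecruited = length(rs@reads), nContigs = 0L,
                         maxSpacersPerContig = 0L, totalSpacers = 0L,
                         stringsAsFactors = FALSE))
  if (!length(rs@reads)) return(emptyRes())
  graph <- buildGraph(rs, k = k, minCount = minCount)
  if (!length(graph@counts)) return(emptyRes())
  contigs <- assembleContigs(graph)
  keptSeqs <- character(0)
  keptCov <- numeric(0)
  arrays <- list()
  spacers <- DNAStringSet()
  perContigSpacers <- integer(0)
  suppressed <- 0L
  for (i in seq_along(contigs)) {
    cs <- as.character(contigs[[i]])
    hits <- scanRepeat(cs, query, maxMm = maxMm)
    if (!nrow(hits)) { suppressed <- suppressed + 1L; next }
    # orient the contig so the query matches the forward strand
    if (sum(hits$strand == "-") > sum(hits$strand == "+")) {
      cs <- revComp(cs)
      hits <- scanRepeat(cs, query, maxMm = maxMm)
    }
    cid <- sprintf("%s|%s|contig%d", sampleId, queryId, length(keptSeqs) + 1L)
    keptSeqs <- c(keptSeqs, setNames(cs, cid))
    keptCov <- c(keptCov, mcols(contigs)$meanKmerCoverage[i])
    hits$targetId <- cid
    arrs <- hitsToArrays(hits, cs, params, queryLen = nchar(query),
                         targetId = cid)
    nSp <- 0L
    for (j in seq_along(arrs)) {
      sp <- extractSpacers(arrs[[j]], cs,
                           prefix = sprintf("%s|a%d", cid, j))
      spacers <- c(spacers, sp)
      nSp <- nSp + length(sp)
    }
    perContigSpacers <- c(perContigSpacers, nSp)
    arrays <- c(arrays, arrs)
  }
  contigsOut <- DNAStringSet(keptSeqs)
  if (length(contigsOut)) mcols(contigsOut)$meanKmerCoverage <- keptCov
  list(readset = rs, contigs = contigsOut, arrays = arrays,
       spacers = spacers, nSuppressedContigs = suppressed,
       summary = data.frame(
         queryId = queryId, sampleId = sampleId,
         nReadsRecruited = length(rs@reads),
         nContigs = length(contigsOut),
         maxSpacersPerContig = if (length(perContigSpacers))
           max(perContigSpacers) else 0L,
         totalSpacers = length(spacers), stringsAsFactors = FALSE))
}
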